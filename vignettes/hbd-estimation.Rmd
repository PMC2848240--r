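---
title: "Estimating genome-wide homozygosity-by-descent: models, simulation and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome-wide homozygosity-by-descent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An individual is *homozygous-by-descent* (HBD, or autozygous) at a locus when
both alleles are copies of a single ancestral allele transmitted down both
sides of a consanguineous loop. The genome-wide proportion of HBD loci is the
individual's inbreeding coefficient `f`. Classically `f` is computed from
genealogies, but records are often incomplete and miss remote ("cryptic")
loops, so dense SNP data are attractive. The catch is that observed
homozygosity mixes HBD with *homozygosity-by-state* — chance identity of
alleles without shared descent — and different estimators separate the two
with very different success.

hbdkit implements five measures of individual genome-wide homozygosity and
the machinery to benchmark them against exactly known truth:

* **MLH** — multilocus heterozygosity, the fraction of non-missing loci that
  are heterozygous. Pure homozygosity-by-state; included as the baseline.
* **F_PLINK** — the genome-wide moment estimator behind PLINK's `--het`:
  `(O − E)/(L − E)`, observed versus Hardy-Weinberg-expected homozygote
  counts. With sample-estimated frequencies the per-marker expectation uses
  the small-sample factor `2N/(2N−1)`; with external frequencies it does not
  (both modes are exposed because published analyses rarely say which was
  used).
* **F_ADC** — a per-locus estimator `f_l = (o_l − e_l)/(1 − e_l)` averaged
  with inverse-variance weights `w_l = (1 − e_l)/e_l` (the variance of `f_l`
  under `f = 0`). The original description is for multi-allelic markers; the
  biallelic specialization implemented here reduces to `F_PLINK` when all
  markers share one frequency (the weights cancel), which is also asserted
  in the tests.
* **FEstimSPT** — single-point maximum likelihood: each marker contributes a
  mixture `f·P(g|HBD) + (1−f)·P(g|non-HBD)` and `f` maximises the summed
  log-likelihood. Each term is affine in `f`, so the objective is concave
  and a single bounded Brent search plus explicit boundary checks is exact —
  no multistart is needed for this 1-D problem.
* **FEstim** — the multi-point estimator: a two-state hidden Markov model of
  the HBD indicator along the genetic map, maximised jointly over `f` and a
  rate parameter `a`.

## The hidden Markov model

The hidden state at marker `m` is HBD/non-HBD. Over a genetic distance `d`
Morgans, with `r = exp(−a·d)`:

```
P(HBD -> HBD)  = r + f(1 − r)        P(HBD -> non) = (1 − f)(1 − r)
P(non -> HBD)  = f(1 − r)            P(non -> non) = r + (1 − f)(1 − r)
```

The chain is time-reversible with stationary distribution `(f, 1 − f)`; each
chromosome starts at stationarity and chromosomes are independent, so their
log-likelihoods add. Emissions with allele-1 frequency `p`, `q = 1 − p`, and
error parameter `ε`:

| genotype | HBD | non-HBD |
|---|---|---|
| hom allele 1 | `(1−ε)p + εp²` | `p²` |
| het | `ε·2pq` | `2pq` |
| hom allele 2 | `(1−ε)q + εq²` | `q²` |

Missing genotypes emit probability 1 in both states (they still carry
distance, so they are marginalised, not skipped). The forward pass is scaled
per marker and implemented in C++; long chromosomes underflow otherwise.
Posterior HBD probabilities come from standard forward-backward smoothing
with the same scaling.

Two useful limits anchor the implementation and are asserted in the test
suite against independent oracles: a single marker (or `a → ∞`) reduces the
HMM exactly to the single-point mixture likelihood, and for a dozen markers
the forward sum equals brute-force enumeration of all `2^L` hidden paths.

## Parameters that matter

* `f ∈ [0,1]` — the quantity of interest.
* `a > 0`, per Morgan — the rate of switching between states; `1/a` is the
  expected HBD segment-length scale. The MLE is found by Nelder-Mead on
  `(logit f, logistic a)` from a 3×3 multistart grid, because the likelihood
  can be multimodal near `f = 0`; the `f = 0` and `f = 1` boundaries are
  evaluated in closed form, so exact zeros are reported, matching the hard
  zero minima seen in cohort analyses.
* **Bounds on `a`** (default `[0.01, 10]`). The lower bound prevents the
  degenerate all-one-segment solution on short maps. The upper bound is the
  package's own design choice and deserves a paragraph: with `a` free up to
  very large values the per-individual likelihood frequently drifts to the
  near-single-point regime (`exp(−a·d) ≈ 0` between adjacent markers), where
  the "multi-point" estimator quietly becomes FEstimSPT and inherits its
  inflation on weakly inbred genomes. A cap of 10 per Morgan says: the
  shortest segment scale the estimator will model is 0.1 M, the expected
  segment length for the most remote loop it targets (third cousins, ten
  meioses in the loop; first cousins give ~1/6 M). In our three-scenario
  benchmark this bound is what preserves the multi-point advantage at low
  `f` (rank correlation with truth ~0.74 at the third-cousin scenario versus
  ~0.41 when `a` may reach 100). Both bounds are arguments, not constants.
* `ε ∈ [0, 0.1]` — with `ε = 0` a single heterozygote annihilates an HBD
  stretch; that is correct for the error-free generative model used in
  simulations and is the default. For real data `ε ≈ 0.001` is recommended,
  otherwise genotyping errors fragment long tracts.

## The gene-dropping simulator

`build_cousin_pedigree(degree)` constructs the mating of first, second or
third cousins (path-counting `F` = 1/16, 1/64, 1/256 — verified in code by a
recursive kinship computation, not hard-wired). `gene_drop()` assigns two
unique labels per founder and transmits recombinant mosaics: crossovers are
a homogeneous Poisson process on genetic distance per chromosome (Haldane,
no interference), matching the exponential-distance HMM downstream. A marker
is HBD exactly when the proband's two labels coincide, so the true `f` of
every replicate is known. Alleles are then dropped at linkage equilibrium:
one Bernoulli(`freq_a1`) draw per distinct label per marker, a shared draw
when the labels coincide — hence HBD implies homozygosity (no mutation or
error model), another property the tests assert.

Default map: 4,849 markers on 22 equal-count chromosomes at 0.008 M spacing
(total 38.8 M), emulating a 10K-array map with LD removed. Allele-1
frequencies are i.i.d. Uniform(0.05, 0.95) — equivalently MAF ~
Uniform(0.05, 0.5) — because the original chip's spectrum is not published;
the sampler is a config knob and is recorded in the map's metadata and the
exported `config.txt`. What this generator deliberately does *not* emulate:
linkage disequilibrium between markers, genotyping error, missingness, and
a realistic chromosome-length distribution. Benchmarks passing on these
simulations therefore validate the estimators *under linkage equilibrium
with known frequencies*; they say nothing about residual-LD inflation on
dense real maps, which is exactly why the package also ships the
`select_markers_ld()` pruning stage for real data.

Replicates use L'Ecuyer-CMRG substreams (`parallel::nextRNGStream`), so
replicate `r` is a function of `(seed, r)` alone and runs are reproducible
and mergeable.

## QC and LD pruning

`apply_qc()` applies, in order: individual call rate ≥ 95%, exact
Hardy-Weinberg test at a 1e-7 floor (exact, not chi-square, because only
grossly ill-behaved markers should fail in a population where mild HWE
departure is expected), marker call rate ≥ 95%, MAF ≥ 0.05. The HWE test
uses the stable heterozygote-count recurrence and is tested against a
log-gamma enumeration oracle.

`select_markers_ld()` approximates an information-content-preserving LD
filter with a greedy windowed scan (default window 0.5 cM): whenever a pair
within the window exceeds the r² threshold, the lower-MAF member is dropped
(tie: later position), keeping the more informative marker. Composite
genotypic r² (squared Pearson correlation of allele counts) is used — it is
phase-free and matches common pruning practice; an EM haplotype-frequency
r² would be the natural extension. The scan guarantees no retained pair
within the window exceeds the threshold, which the tests verify
exhaustively on toys.

## The comparison pipeline

`run_simulation_study()` reproduces the benchmark design: per degree it
reports each estimator's mean and the *empirical central 95% interval* of
the replicate distribution (the bracketed interval in the published table is
unlabelled; empirical quantiles are this package's reading, recorded in the
output metadata), plus the full correlation matrix including true HBD.
Spearman rank correlation is the default, matching the stated statistical
analysis, with Pearson available as a sensitivity switch. Negative
`F_PLINK`/`F_ADC` values are truncated to zero inside the comparison (truth
is a non-negative proportion); raw per-cohort output keeps negatives.
Group comparisons use the Mann-Whitney test on neighbouring a-priori-ordered
groups (exact when the smaller group has ≤ 8 members, normal approximation
with tie correction otherwise) and sibling pairs use the Wilcoxon
signed-rank test — all through `stats::wilcox.test`.

## Problem sizes and numerical choices

The shipped benchmarks use 10,000 gene-drop replicates per degree for the
truth-only means and 2,000 replicates per degree when all estimators run
(keeping the Monte-Carlo error of a rank correlation near 0.02); the parameter-recovery check uses 200 replicates simulated from the
HMM's own generative model at `f = 0.0625`, `a = 6.4` (the first-cousin
segment scale; a much smaller rate would make the per-chromosome chain
essentially constant and `f` unrecoverable by any estimator). Optimiser
tolerances: 1e-7 on the 1-D single-point search, Nelder-Mead relative
tolerance 1e-10 with the 3×3 multistart for the joint MLE. Degenerate
inputs are flagged rather than silently dropped: all-missing individuals,
monomorphic markers (excluded uniformly from every estimator so
`n_markers_used` agrees across methods), zero-variance markers in r²
(treated as unlinked), and `L − E ≤ 0` in the moment estimator.

## Known limitations

* The multi-allelic generalization of F_ADC (`e_l = Σ p_a²`) is not
  implemented; SNP data only.
* No X chromosome, no phased data, no VCF ingestion; PLINK text PED/MAP is
  the tested interchange format (binary BED is out of scope).
* The LD filter is a greedy approximation, not a coverage-optimising search;
  equivalence with sophisticated selection tools is not claimed.
* Numerical equivalence with the historical FEstim binary is not claimed —
  its optimizer and `a` bounds are undocumented; equivalence is at the model
  level, which the exhaustive-path and limit tests pin down.
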