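# hbdkit

Estimation of individual genome-wide **homozygosity-by-descent** (HBD,
autozygosity) from SNP genotypes, with a gene-dropping simulator that knows
the truth.

## The problem

Observed homozygosity mixes two things: *homozygosity-by-state* (chance
identity of alleles) and *homozygosity-by-descent* (both alleles copied from
one ancestral allele through a consanguineous loop). The genome-wide HBD
proportion is the individual's inbreeding coefficient `f` — the quantity of
interest in studies of inbreeding depression, homozygosity mapping and
population isolates, where genealogies are incomplete and cryptic loops are
common. hbdkit implements and benchmarks the five standard marker-based
measures:

| measure | idea |
|---|---|
| `MLH` | fraction of heterozygous loci (pure homozygosity-by-state baseline) |
| `F_PLINK` | moment estimator `(O − E)/(L − E)`, observed vs Hardy-Weinberg-expected homozygote counts (PLINK `--het`) |
| `F_ADC` | per-locus `(o_l − e_l)/(1 − e_l)` averaged with inverse-variance weights `(1 − e_l)/e_l` |
| `FEstimSPT` | single-point maximum likelihood of the mixture `f·P(g\|HBD) + (1−f)·P(g\|non-HBD)` |
| `FEstim` | multi-point maximum likelihood: a two-state hidden Markov model of HBD along the genetic map, jointly over `f` and a switch rate `a` per Morgan (transition `exp(−a·d)` toward the stationary `(f, 1−f)`) |

The multi-point model lets long homozygous stretches carry the signal while
isolated homozygous markers are discounted — which is what separates descent
from state.

Alongside the estimators the package provides: PLINK text PED/MAP input and
output, per-marker allele frequencies (sample-estimated or external), QC
filters with an exact Hardy-Weinberg test, greedy r²-threshold LD pruning, a
gene-dropping simulator on first/second/third-cousin pedigrees with exactly
known per-marker HBD, and a comparison pipeline (means, empirical 95%
intervals, Spearman correlation matrices, Mann-Whitney group tests, Wilcoxon
sibling-pair tests).

## Worked example

Simulate offspring of first cousins on a 4,849-SNP linkage-equilibrium map
(22 chromosomes, 0.8 cM spacing), estimate `f` five ways and compare with
the truth:

```r
library(hbdkit)

map   <- make_sim_map(seed = 42)        # 4,849 markers, MAF ~ U(0.05, 0.5)
study <- run_simulation_study(degrees = 1, n_replicates = 50,
                              map = map, seed = 7)
print(study)
```

```
<hbd_simstudy> 50 replicates/degree, spearman correlations, negatives truncated

degree 1 (expected F = 0.0625):
 estimator  mean  q2.5 q97.5 cor_with_truth
  true_hbd 0.067 0.038 0.120           1.00
       MLH 0.338 0.317 0.353          -0.76
   F_PLINK 0.069 0.026 0.125           0.76
     F_ADC 0.069 0.028 0.124           0.78
 FEstimSPT 0.069 0.035 0.119           0.78
    FEstim 0.068 0.035 0.113           0.90
```

Reading the output: each row is one estimator summarised over the 50
simulated first-cousin offspring — its mean, the empirical central 95%
interval of the replicate distribution, and its Spearman correlation with
the true per-replicate HBD proportion. The mean true HBD (0.067) sits at
the pedigree expectation 1/16 up to Monte-Carlo noise; every
frequency-based estimator is centred there too, but the multi-point
`FEstim` correlates with the truth (0.90) well above the single-point
methods (~0.76-0.78). `MLH` is heterozygosity, hence the negative sign.

Per-marker HBD posteriors for one simulated individual:

```r
s   <- simulate_replicates(1, 1, map, seed = 9)
fit <- festim_mle(s$replicates[[1]]$genotypes, map, map$freq_a1)
post <- hbd_posterior(s$replicates[[1]]$genotypes, map, map$freq_a1,
                      hmm_params(fit$f, fit$a))
```

For real data: `read_plink("cohort.ped", "cohort.map")`, then `apply_qc()`,
`select_markers_ld(r2_threshold = 0.05)` (multi-point estimates inflate
under linkage disequilibrium, so prune first), then
`estimate_inbreeding()`.

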