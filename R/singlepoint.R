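# Single-point inbreeding/homozygosity measures: every marker contributes
# independently of its neighbours.

# Markers usable by the frequency-based estimators: non-missing call and an
# informative (0 < p < 1) frequency. Applied uniformly so n_markers_used
# matches across methods.
usable_markers <- function(g, p) !is.na(g) & !is.na(p) & p > 0 & p < 1

#' Multilocus heterozygosity
#'
#' Proportion of an individual's non-missing genotyped loci that are
#' heterozygous. A measure of homozygosity-by-state: `1 - mlh` is the
#' genome-wide homozygous fraction.
#'
#' @param g integer genotype vector (allele-1 counts, `NA` missing).
#' @param mask optional logical vector restricting the markers used (e.g. the
#'   uniform mask shared with the frequency-based estimators).
#' @return Numeric value in \[0, 1\] with attribute `n_markers_used`;
#'   `NA` (flagged) if no marker is usable.
#' @export
mlh <- function(g, mask = NULL) {
  use <- !is.na(g)
  if (!is.null(mask)) use <- use & mask
  n <- sum(use)
  val <- if (n == 0) NA_real_ else sum(g[use] == 1L) / n
  structure(val, n_markers_used = n)
}

#' PLINK-style moment estimator of the inbreeding coefficient
#'
#' The genome-wide method-of-moments estimator behind PLINK's `--het`:
#' `(O - E) / (L - E)` over the individual's usable markers, where `O` is the
#' observed homozygote count, `L` the marker count and
#' `E = sum(1 - 2 p q c)` the homozygosity expected under Hardy-Weinberg.
#' When frequencies are sample-estimated, the small-sample correction
#' `c = 2N/(2N - 1)` (N = non-missing individuals at the marker) is applied;
#' with externally provided frequencies `c = 1`.
#'
#' @param g integer genotype vector.
#' @param freqs an `hbd_freqs` object or numeric frequency vector.
#' @param small_sample_correction override the mode-based default choice of
#'   the `2N/(2N-1)` correction.
#' @return Numeric value (possibly negative) with attribute
#'   `n_markers_used`; `NA` flagged when `L - E <= 0`.
#' @export
f_plink <- function(g, freqs, small_sample_correction = NULL) {
  freqs <- as_freqs(freqs)
  p <- freqs$freq
  use <- usable_markers(g, p)
  L <- sum(use)
  if (L == 0) return(structure(NA_real_, n_markers_used = 0L))
  p <- p[use]
  corr <- if (is.null(small_sample_correction))
    identical(freqs$mode, "sample_estimated") else small_sample_correction
  cc <- if (corr) {
    n_obs <- freqs$n_obs[use]
    2 * n_obs / (2 * n_obs - 1)
  } else 1
  E <- sum(1 - 2 * p * (1 - p) * cc)
  O <- sum(g[use] != 1L)
  denom <- L - E
  val <- if (denom <= 0) NA_real_ else (O - E) / denom
  structure(val, n_markers_used = L)
}

#' Inverse-variance weighted locus-based inbreeding estimator
#'
#' Per usable locus, the single-locus estimate `f_l = (o_l - e_l)/(1 - e_l)`
#' (with `o_l` the 0/1 homozygosity indicator and `e_l = 1 - 2pq` the
#' expected homozygosity) is averaged with weights `w_l = (1 - e_l)/e_l`, the
#' inverse of the variance of `f_l` under f = 0. When all markers share one
#' frequency the weights cancel and the estimator reduces to the unweighted
#' ratio `(O/L - e)/(1 - e)`.
#'
#' @inheritParams f_plink
#' @return Numeric value (possibly negative) with attribute
#'   `n_markers_used`; `NA` flagged when no weight is defined.
#' @export
f_adc <- function(g, freqs) {
  freqs <- as_freqs(freqs)
  p <- freqs$freq
  use <- usable_markers(g, p)
  L <- sum(use)
  if (L == 0) return(structure(NA_real_, n_markers_used = 0L))
  p <- p[use]
  e <- 1 - 2 * p * (1 - p)
  o <- as.numeric(g[use] != 1L)
  fl <- (o - e) / (1 - e)
  w <- (1 - e) / e
  sw <- sum(w)
  val <- if (!is.finite(sw) || sw <= 0) NA_real_ else sum(w * fl) / sw
  structure(val, n_markers_used = L)
}

# Emission probabilities of the autozygosity model, shared by the
# single-point and hidden-Markov likelihoods. Under HBD the genotype is a
# single ancestral allele observed twice, so hom1 has probability p (plus an
# error term epsilon placing an HWE genotype instead); under non-HBD the
# genotype is at Hardy-Weinberg proportions.
emission_probs <- function(g, p, error_rate = 0) {
  q <- 1 - p
  e_hbd <- ifelse(g == 2L, (1 - error_rate) * p + error_rate * p^2,
           ifelse(g == 1L, error_rate * 2 * p * q,
                  (1 - error_rate) * q + error_rate * q^2))
  e_non <- ifelse(g == 2L, p^2, ifelse(g == 1L, 2 * p * q, q^2))
  miss <- is.na(g)
  e_hbd[miss] <- 1
  e_non[miss] <- 1
  list(hbd = e_hbd, non = e_non)
}

# Single-point mixture log-likelihood at inbreeding f (vectorised over
# markers; missing markers contribute 0).
spt_loglik <- function(f, em) sum(log(f * em$hbd + (1 - f) * em$non))

#' Single-point maximum-likelihood inbreeding estimator
#'
#' Maximises over `f` in \[0, 1\] the sum over markers of
#' `log(f P(g|HBD) + (1 - f) P(g|non-HBD))`, using the same emission model as
#' the hidden-Markov estimator but ignoring marker dependencies. Each term is
#' the log of a function affine in `f`, so the log-likelihood is concave and
#' a single bounded Brent search plus an explicit check of both boundaries
#' finds the global maximum.
#'
#' @inheritParams f_plink
#' @param error_rate genotyping-error emission parameter epsilon (default 0).
#' @param tol convergence tolerance of the 1-D search.
#' @return Numeric f-hat in \[0, 1\] with attributes `n_markers_used` and
#'   `loglik`; `NA` flagged if the likelihood is non-finite at both
#'   boundaries.
#' @export
festim_spt <- function(g, freqs, error_rate = 0, tol = 1e-7) {
  freqs <- as_freqs(freqs)
  p <- freqs$freq
  use <- usable_markers(g, p)
  L <- sum(use)
  if (L == 0) return(structure(NA_real_, n_markers_used = 0L, loglik = NA_real_))
  em <- emission_probs(g[use], p[use], error_rate)
  ll0 <- spt_loglik(0, em)
  ll1 <- spt_loglik(1, em)
  if (!is.finite(ll0) && !is.finite(ll1))
    return(structure(NA_real_, n_markers_used = L, loglik = NA_real_))
  opt <- optimize(spt_loglik, c(0, 1), em = em, maximum = TRUE, tol = tol)
  cand_f <- c(0, 1, opt$maximum)
  cand_ll <- c(ll0, ll1, opt$objective)
  best <- which.max(cand_ll)
  structure(cand_f[best], n_markers_used = L, loglik = cand_ll[best])
}

#' Truncate negative inbreeding estimates to zero
#'
#' The moment estimators can go negative in outbred individuals; for
#' comparisons against true HBD (which is a non-negative proportion) negative
#' values are set to zero. Raw per-cohort output is left untruncated.
#'
#' @param values numeric vector.
#' @return The vector with negatives replaced by 0 (`NA`s preserved).
#' @export
truncate_negative <- function(values) {
  values[!is.na(values) & values < 0] <- 0
  values
}
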