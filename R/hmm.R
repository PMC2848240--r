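# Multi-point estimator: maximum likelihood (f, a) under a two-state hidden
# Markov model of HBD along the genetic map, plus per-marker HBD posteriors.

#' Parameters of the HBD hidden Markov model
#'
#' @param f stationary probability of the HBD state, in \[0, 1\].
#' @param a rate of change between HBD and non-HBD states per Morgan, > 0.
#' @param error_rate genotyping-error emission parameter in \[0, 0.1\].
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(f, a, error_rate = 0) {
  stopifnot(f >= 0, f <= 1, a > 0, error_rate >= 0, error_rate <= 0.1)
  structure(list(f = f, a = a, error_rate = error_rate), class = "hmm_params")
}

#' HMM transition matrix over a genetic distance
#'
#' With r = exp(-a*d): stay probabilities `f + (1-f)*r` (HBD) and
#' `(1-f) + f*r` (non-HBD); the chain is time-reversible with stationary
#' distribution `(f, 1-f)`. At `d = 0` the matrix is the identity; as
#' `d -> Inf` both rows tend to the stationary distribution.
#'
#' @param params an [hmm_params()] object.
#' @param distance_morgans genetic distance, >= 0.
#' @return 2x2 row-stochastic matrix with dimnames `HBD`, `nonHBD` (row =
#'   from, column = to).
#' @export
transition_matrix <- function(params, distance_morgans) {
  stopifnot(inherits(params, "hmm_params"), distance_morgans >= 0)
  f <- params$f
  r <- exp(-params$a * distance_morgans)
  m <- matrix(c(r + f * (1 - r),       (1 - f) * (1 - r),
                f * (1 - r),           r + (1 - f) * (1 - r)),
              2, 2, byrow = TRUE,
              dimnames = list(c("HBD", "nonHBD"), c("HBD", "nonHBD")))
  m
}

# Map geometry for the forward pass: per-marker distance to the previous
# marker and a flag marking the first marker of each chromosome.
map_steps <- function(map) {
  chrom <- map$chrom
  pos <- map$pos_m
  newchrom <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  dist <- c(0, diff(pos))
  dist[newchrom] <- 0
  if (any(dist < 0)) stop("map positions must be non-decreasing within chromosome")
  list(dist = dist, newchrom = newchrom)
}

# Prepare emissions + geometry for one individual; markers with undefined or
# monomorphic frequency are dropped (consistently with the single-point
# estimators); missing genotypes stay in with emission 1 in both states.
hmm_inputs <- function(g, map, freqs, error_rate) {
  freqs <- as_freqs(freqs)
  p <- freqs$freq
  stopifnot(length(g) == nrow(map), length(p) == nrow(map))
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[keep]
  submap <- map[keep, , drop = FALSE]
  em <- emission_probs(g, p[keep], error_rate)
  st <- map_steps(submap)
  list(em = em, dist = st$dist, newchrom = st$newchrom,
       n_markers = sum(keep & !is.na(g)), map = submap)
}

#' Forward log-likelihood of the HBD hidden Markov model
#'
#' Scaled forward algorithm run per chromosome (each initialised at the
#' stationary distribution), with chromosome log-likelihoods summed. With a
#' single marker, or in the limit `a -> Inf`, this equals the single-point
#' mixture log-likelihood at the same `f`.
#'
#' @param g integer genotype vector over the markers of `map`.
#' @param map marker map ordered by (chrom, pos_m).
#' @param freqs an `hbd_freqs` object or numeric frequency vector.
#' @param params an [hmm_params()] object.
#' @return Log-likelihood (scalar). `-Inf` with attribute `bad_marker` if an
#'   impossible emission zeroes the forward variable.
#' @export
forward_loglik <- function(g, map, freqs, params) {
  stopifnot(inherits(params, "hmm_params"))
  inp <- hmm_inputs(g, map, freqs, params$error_rate)
  ll <- hmm_forward_loglik_cpp(inp$em$hbd, inp$em$non, inp$dist,
                               inp$newchrom, params$f, params$a)
  if (!is.finite(ll)) {
    fb <- hmm_forward_backward_cpp(inp$em$hbd, inp$em$non, inp$dist,
                                   inp$newchrom, params$f, params$a)
    attr(ll, "bad_marker") <- fb$bad_marker
  }
  ll
}

# Core (f, a) maximisation on precomputed emissions/geometry. Nelder-Mead on
# (logit f, logistic-transformed a in [a_min, a_max]) from a multistart
# grid, with the f = 0 and f = 1 boundary log-likelihoods checked
# explicitly (the transform cannot reach them).
festim_fit_core <- function(em, dist, newchrom,
                            a_min = 0.01, a_max = 10,
                            starts_f = c(0.001, 0.0625, 0.25),
                            starts_a = c(0.5, 2, 8),
                            reltol = 1e-10, maxit = 500) {
  nll <- function(par) {
    f <- plogis(par[1])
    a <- a_min + (a_max - a_min) * plogis(par[2])
    -hmm_forward_loglik_cpp(em$hbd, em$non, dist, newchrom, f, a)
  }
  ta <- function(a) qlogis((a - a_min) / (a_max - a_min))
  best <- NULL
  n_ok <- 0L
  for (f0 in starts_f) for (a0 in starts_a) {
    fit <- tryCatch(
      optim(c(qlogis(f0), ta(a0)), nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ll0 <- sum(log(em$non))   # f = 0: every marker emits from the non-HBD state
  ll1 <- sum(log(em$hbd))   # f = 1
  if (n_ok == 0L && !is.finite(ll0) && !is.finite(ll1))
    stop("all optimizer starts failed and both boundaries are non-finite")
  interior <- if (is.null(best)) -Inf else -best$value
  cands <- c(boundary0 = ll0, boundary1 = ll1, interior = interior)
  top <- names(which.max(cands))
  if (top == "interior") {
    list(f = plogis(best$par[1]),
         a = a_min + (a_max - a_min) * plogis(best$par[2]),
         loglik = interior,
         converged = best$convergence == 0, boundary = FALSE)
  } else {
    list(f = if (top == "boundary0") 0 else 1, a = NA_real_,
         loglik = unname(cands[top]), converged = TRUE, boundary = TRUE)
  }
}

#' Multi-point maximum-likelihood inbreeding estimator
#'
#' Joint maximisation of the hidden-Markov forward log-likelihood over
#' `f` in \[0, 1\] and the state-change rate `a` in `[a_min, a_max]` per
#' Morgan, by Nelder-Mead on transformed coordinates (logit f, logistic a)
#' from a 3x3 multistart grid. Boundary solutions `f = 0` (all-non-HBD) and
#' `f = 1` are evaluated in closed form and reported when they dominate, so
#' exact zeros are possible. `a` is bounded away from 0 to prevent
#' degenerate single-segment solutions on short maps, and bounded above at
#' 10 per Morgan by default: the mean HBD segment length `1/a` is then at
#' least 0.1 Morgan, the segment scale of the most distant consanguineous
#' loop the estimator targets (third cousins, ten meioses in the loop).
#' Without an upper bound the per-individual likelihood can drift to very
#' large `a`, collapsing the estimator onto its single-point version and
#' forfeiting the multi-point information that distinguishes
#' homozygosity-by-descent from chance homozygosity.
#'
#' @inheritParams forward_loglik
#' @param error_rate genotyping-error emission parameter (default 0).
#' @param a_min,a_max box bounds for the rate per Morgan.
#' @param starts_f,starts_a multistart grids.
#' @return List with `f`, `a` (`NA` at an f-boundary), `loglik`, `converged`,
#'   `boundary`, `n_markers_used`.
#' @export
festim_mle <- function(g, map, freqs, error_rate = 0,
                       a_min = 0.01, a_max = 10,
                       starts_f = c(0.001, 0.0625, 0.25),
                       starts_a = c(0.5, 2, 8)) {
  inp <- hmm_inputs(g, map, freqs, error_rate)
  if (sum(!inp$newchrom) < 1 && length(inp$dist) < 2)
    stop("need at least 2 markers")
  fit <- festim_fit_core(inp$em, inp$dist, inp$newchrom,
                         a_min = a_min, a_max = a_max,
                         starts_f = starts_f, starts_a = starts_a)
  fit$n_markers_used <- inp$n_markers
  fit
}

#' Per-marker HBD posterior probabilities
#'
#' Forward-backward smoothing under the HBD hidden Markov model, typically at
#' the maximum-likelihood parameters. At the MLE the mean posterior over
#' markers approximately equals f-hat (stationarity).
#'
#' @inheritParams forward_loglik
#' @return Data.frame with `marker_id` and `p_hbd` in \[0, 1\] (markers with
#'   monomorphic/undefined frequency are excluded).
#' @export
hbd_posterior <- function(g, map, freqs, params) {
  stopifnot(inherits(params, "hmm_params"))
  inp <- hmm_inputs(g, map, freqs, params$error_rate)
  if (params$f == 0)
    return(data.frame(marker_id = inp$map$marker_id,
                      p_hbd = rep(0, nrow(inp$map))))
  fb <- hmm_forward_backward_cpp(inp$em$hbd, inp$em$non, inp$dist,
                                 inp$newchrom, params$f, params$a)
  if (!is.finite(fb$loglik))
    stop("non-finite likelihood at marker ", fb$bad_marker)
  data.frame(marker_id = inp$map$marker_id, p_hbd = fb$posterior)
}
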