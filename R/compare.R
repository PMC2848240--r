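# Comparison pipeline: the simulation study (per-degree means, empirical 95%
# intervals, correlation with true HBD), inter-method correlation matrices,
# and nonparametric group / sibling-pair comparisons.

estimator_columns <- c("MLH", "F_PLINK", "F_ADC", "FEstimSPT", "FEstim")

#' Estimate inbreeding for every individual in a dataset
#'
#' Runs the requested estimators over each individual with one shared marker
#' mask (markers with undefined or monomorphic frequency are skipped
#' uniformly, so `n_markers_used` matches across methods).
#'
#' @param x an `hbd_geno` dataset.
#' @param freqs frequencies (`hbd_freqs`, numeric vector, or `NULL` to
#'   sample-estimate from `x`).
#' @param methods subset of `c("MLH", "F_PLINK", "F_ADC", "FEstimSPT",
#'   "FEstim")`.
#' @param error_rate epsilon for the likelihood-based estimators.
#' @param ... passed to [festim_mle()] (`a_min`, `a_max`, starts).
#' @return Long data.frame: `individual_id`, `method`, `value`,
#'   `n_markers_used`.
#' @export
estimate_inbreeding <- function(x, freqs = NULL, methods = estimator_columns,
                                error_rate = 0, ...) {
  stopifnot(inherits(x, "hbd_geno"))
  methods <- match.arg(methods, estimator_columns, several.ok = TRUE)
  freqs <- as_freqs(freqs, x)
  p <- freqs$freq
  mask <- !is.na(p) & p > 0 & p < 1
  rows <- list()
  for (i in seq_len(nrow(x$calls))) {
    g <- x$calls[i, ]
    id <- x$fam$iid[i]
    for (m in methods) {
      v <- switch(m,
        MLH = mlh(g, mask),
        F_PLINK = f_plink(g, freqs),
        F_ADC = f_adc(g, freqs),
        FEstimSPT = festim_spt(g, freqs, error_rate = error_rate),
        FEstim = {
          fit <- festim_mle(g, x$map, freqs, error_rate = error_rate, ...)
          structure(fit$f, n_markers_used = fit$n_markers_used)
        })
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = id, method = m, value = as.numeric(v),
        n_markers_used = attr(v, "n_markers_used"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise rank-correlation matrix of an estimate table
#'
#' Spearman rank correlation (average ranks for ties) on pairwise-complete
#' rows; Pearson available as a sensitivity switch. Constant columns yield
#' `NA` entries (flagged by attribute `undefined`).
#'
#' @param table data.frame of numeric columns (e.g. an estimate table with
#'   `true_hbd` plus one column per estimator).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- as.matrix(table)
  stopifnot(is.numeric(m), nrow(m) >= 3)
  cm <- suppressWarnings(cor(m, method = method,
                             use = "pairwise.complete.obs"))
  diag(cm) <- 1
  attr(cm, "undefined") <- which(is.na(cm), arr.ind = TRUE)
  cm
}

#' Run the cousin-offspring simulation study
#'
#' For each cousin degree: gene-drop `n_replicates` probands, estimate
#' inbreeding with every requested method using the map's true allele
#' frequencies, truncate negative moment estimates to zero (the comparison
#' convention; raw cohort output keeps negatives), and summarise per
#' estimator the mean and empirical central 95% interval plus the full
#' rank-correlation matrix including true HBD.
#'
#' @param degrees vector of cousin degrees, subset of 1:3.
#' @param n_replicates replicates per degree.
#' @param map [make_sim_map()] map (defaults built with `seed`).
#' @param methods estimators to run (all five by default).
#' @param error_rate epsilon passed to the likelihood estimators.
#' @param truncate set negative `F_PLINK`/`F_ADC` values to zero before
#'   summarising (default TRUE).
#' @param correlation `"spearman"` (default) or `"pearson"`.
#' @param seed master seed; degree d uses sub-seed `seed + d`.
#' @param ... passed to [festim_mle()].
#' @return Object of class `hbd_simstudy`: per degree a list with `table`
#'   (replicate x estimator data.frame including `true_hbd`), `summary`
#'   (mean, `q2.5`, `q97.5` per column), `correlation` matrix, and `n_failed`
#'   (replicates dropped listwise for the correlation matrix).
#' @export
run_simulation_study <- function(degrees = 1:3, n_replicates,
                                 map = NULL, methods = estimator_columns,
                                 error_rate = 0, truncate = TRUE,
                                 correlation = c("spearman", "pearson"),
                                 seed = 1, ...) {
  correlation <- match.arg(correlation)
  methods <- match.arg(methods, estimator_columns, several.ok = TRUE)
  if (is.null(map)) map <- make_sim_map(seed = seed)
  freqs <- provided_frequencies(setNames(map$freq_a1, map$marker_id))
  fit_args <- list(...)
  inp_proto <- NULL
  per_degree <- list()
  for (d in degrees) {
    est_fun <- function(g, trk, r) {
      vals <- c(true_hbd = trk$f_true)
      for (m in methods) {
        v <- switch(m,
          MLH = mlh(g),
          F_PLINK = f_plink(g, freqs),
          F_ADC = f_adc(g, freqs),
          FEstimSPT = festim_spt(g, freqs, error_rate = error_rate),
          FEstim = {
            fit <- do.call(festim_mle,
                           c(list(g, map, freqs, error_rate = error_rate),
                             fit_args))
            fit$f
          })
        vals[m] <- as.numeric(v)
      }
      vals
    }
    sims <- simulate_replicates(d, n_replicates, map, seed = seed + d,
                                genotypes = TRUE, FUN = est_fun)
    tab <- as.data.frame(do.call(rbind, sims$replicates))
    if (truncate) {
      for (cn in intersect(c("F_PLINK", "F_ADC"), names(tab)))
        tab[[cn]] <- truncate_negative(tab[[cn]])
    }
    complete <- stats::complete.cases(tab)
    n_failed <- sum(!complete)
    summ <- data.frame(
      estimator = names(tab),
      mean = vapply(tab, mean, numeric(1), na.rm = TRUE),
      q2.5 = vapply(tab, quantile, numeric(1), probs = 0.025, na.rm = TRUE),
      q97.5 = vapply(tab, quantile, numeric(1), probs = 0.975, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE)
    cm <- correlation_matrix(tab[complete, , drop = FALSE],
                             method = correlation)
    per_degree[[as.character(d)]] <-
      list(degree = d, table = tab, summary = summ, correlation = cm,
           n_failed = n_failed)
  }
  structure(list(degrees = per_degree, map = map, seed = seed,
                 n_replicates = n_replicates, truncated = truncate,
                 correlation = correlation,
                 interval = "empirical central 95% of replicates"),
            class = "hbd_simstudy")
}

#' @export
print.hbd_simstudy <- function(x, digits = 3, ...) {
  cat("<hbd_simstudy> ", x$n_replicates, " replicates/degree, ",
      x$correlation, " correlations, negatives ",
      if (x$truncated) "truncated" else "kept", "\n", sep = "")
  for (d in x$degrees) {
    cat("\ndegree ", d$degree, " (expected F = ",
        format(2^-(2 * d$degree + 2), digits = 4), "):\n", sep = "")
    s <- d$summary
    s$mean <- round(s$mean, digits)
    s$q2.5 <- round(s$q2.5, digits)
    s$q97.5 <- round(s$q97.5, digits)
    s$cor_with_truth <- round(d$correlation["true_hbd", s$estimator], 2)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Mann-Whitney tests between neighbouring groups
#'
#' Compares each adjacent pair of a-priori ordered groups (e.g. birthplace
#' clusters ordered by expected homozygosity) with the two-sided
#' Mann-Whitney test: exact when the smaller group has <= 8 members and
#' there are no ties, normal approximation with tie correction otherwise.
#'
#' @param estimates numeric vector of per-individual estimates, named or
#'   aligned with `grouping`.
#' @param grouping factor or ordered vector of group labels (order of levels
#'   = a-priori ordering).
#' @param all_pairs if `TRUE` test every pair, not only neighbours.
#' @param alpha significance threshold reported alongside (default 0.05).
#' @return Data.frame `group_a`, `group_b`, `n_a`, `n_b`, `p`, `significant`;
#'   pairs with an empty group are skipped with a note column.
#' @export
neighbouring_group_tests <- function(estimates, grouping, all_pairs = FALSE,
                                     alpha = 0.05) {
  grouping <- as.factor(grouping)
  stopifnot(length(estimates) == length(grouping), nlevels(grouping) >= 2)
  lv <- levels(grouping)
  pairs <- if (all_pairs) {
    idx <- utils::combn(seq_along(lv), 2)
    data.frame(a = idx[1, ], b = idx[2, ])
  } else data.frame(a = seq_len(length(lv) - 1), b = seq_len(length(lv) - 1) + 1)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    xa <- estimates[grouping == lv[pairs$a[k]]]
    xb <- estimates[grouping == lv[pairs$b[k]]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) == 0 || length(xb) == 0)
      return(data.frame(group_a = lv[pairs$a[k]], group_b = lv[pairs$b[k]],
                        n_a = length(xa), n_b = length(xb), p = NA_real_,
                        significant = NA, note = "empty group, skipped",
                        stringsAsFactors = FALSE))
    exact <- min(length(xa), length(xb)) <= 8
    p <- suppressWarnings(
      wilcox.test(xa, xb, exact = exact, correct = TRUE)$p.value)
    data.frame(group_a = lv[pairs$a[k]], group_b = lv[pairs$b[k]],
               n_a = length(xa), n_b = length(xb), p = p,
               significant = p < alpha, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test on sibling pairs
#'
#' Tests whether an estimator systematically differs within sibling pairs
#' (it should not: siblings share the pedigree-expected inbreeding
#' coefficient). Zero differences are dropped and ties get average ranks.
#'
#' @param estimates named numeric vector of per-individual estimates.
#' @param sib_pairs two-column matrix or data.frame of individual ids, one
#'   pair per row.
#' @return List with `statistic` (V), `p`, `n_pairs_used`, and `note` (set
#'   when all differences are zero, in which case `p = 1`).
#' @export
sibling_pair_test <- function(estimates, sib_pairs) {
  sib_pairs <- as.matrix(sib_pairs)
  stopifnot(ncol(sib_pairs) == 2, nrow(sib_pairs) >= 1)
  va <- estimates[sib_pairs[, 1]]
  vb <- estimates[sib_pairs[, 2]]
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  if (length(va) == 0) stop("no pair has both members estimated")
  d <- va - vb
  if (all(d == 0))
    return(list(statistic = 0, p = 1, n_pairs_used = 0,
                note = "all within-pair differences zero"))
  wt <- suppressWarnings(wilcox.test(va, vb, paired = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_pairs_used = sum(d != 0), note = "")
}

#' Rank correlation restricted to the informative subset
#'
#' Spearman correlation between two columns computed only on rows where a
#' condition column exceeds a threshold — e.g. dropping individuals whose
#' multi-point estimate is exactly zero to get the correlation among the
#' inbred subset.
#'
#' @param estimates data.frame with numeric columns.
#' @param col_a,col_b names of the two columns to correlate.
#' @param condition_column column whose value must exceed `threshold`.
#' @param threshold default 0.
#' @return List with `rho` (`NA` flagged if fewer than 3 rows remain),
#'   `n_used`, `n_total`.
#' @export
conditional_correlation <- function(estimates, col_a, col_b,
                                    condition_column, threshold = 0) {
  stopifnot(all(c(col_a, col_b, condition_column) %in% names(estimates)))
  keep <- !is.na(estimates[[condition_column]]) &
    estimates[[condition_column]] > threshold
  sub <- estimates[keep, , drop = FALSE]
  if (nrow(sub) < 3)
    return(list(rho = NA_real_, n_used = nrow(sub), n_total = nrow(estimates)))
  list(rho = cor(sub[[col_a]], sub[[col_b]], method = "spearman",
                 use = "pairwise.complete.obs"),
       n_used = nrow(sub), n_total = nrow(estimates))
}

#' Write an estimate table or study summary as TSV
#'
#' @param x a data.frame (or matrix) to write.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
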