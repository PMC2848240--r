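# Marker/individual QC filters and r^2-threshold marker pruning.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count: given the sample size
#' and allele counts, the p-value is the total probability of all
#' heterozygote counts no more probable than the one observed, under the
#' exact distribution of the heterozygote count. Computed with the standard
#' stable recurrence over heterozygote counts (no factorials), so extreme
#' p-value floors such as 1e-7 are reliable where a chi-square test is not.
#'
#' @param n_hom_a1,n_het,n_hom_a2 genotype counts (non-negative, total >= 1).
#' @return Two-sided exact p-value; 1 for a monomorphic marker.
#' @export
hwe_exact_test <- function(n_hom_a1, n_het, n_hom_a2) {
  stopifnot(n_hom_a1 >= 0, n_het >= 0, n_hom_a2 >= 0)
  n <- n_hom_a1 + n_het + n_hom_a2
  stopifnot(n >= 1)
  n_a <- 2 * n_hom_a1 + n_het
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  h_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(h_vals))
  # start near the mode, recurse outward:
  # P(h+2)/P(h) = 4 * naa(h) * nbb(h) / ((h+2)(h+1))
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid <- min(max(mid, min(h_vals)), max(h_vals))
  i_mid <- match(mid, h_vals)
  probs[i_mid] <- 1
  if (i_mid < length(h_vals)) {
    for (i in (i_mid + 1):length(h_vals)) {
      h <- h_vals[i - 1]
      naa <- (rare - h) / 2
      nbb <- n - naa - h
      probs[i] <- probs[i - 1] * 4 * naa * nbb / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in (i_mid - 1):1) {
      h <- h_vals[i + 1]
      naa <- (rare - h) / 2
      nbb <- n - naa - h
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (naa + 1) * (nbb + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' QC threshold set
#'
#' @param max_individual_missing maximum per-individual missing fraction
#'   (default 0.05, i.e. call rate >= 95%).
#' @param min_marker_callrate minimum per-marker call rate (default 0.95).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param hwe_p_floor markers with exact HWE p <= this are removed
#'   (default 1e-7; a floor this low keeps real population structure and
#'   removes only grossly ill-behaved markers).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_individual_missing = 0.05,
                          min_marker_callrate = 0.95,
                          min_maf = 0.05,
                          hwe_p_floor = 1e-7) {
  stopifnot(max_individual_missing > 0 || max_individual_missing == 0,
            min_marker_callrate > 0, min_marker_callrate <= 1,
            min_maf >= 0, min_maf < 1, hwe_p_floor > 0, hwe_p_floor <= 1)
  structure(list(max_individual_missing = max_individual_missing,
                 min_marker_callrate = min_marker_callrate,
                 min_maf = min_maf, hwe_p_floor = hwe_p_floor),
            class = "qc_thresholds")
}

subset_geno <- function(x, ind = NULL, mk = NULL) {
  if (!is.null(ind)) {
    x$calls <- x$calls[ind, , drop = FALSE]
    x$fam <- x$fam[ind, , drop = FALSE]
  }
  if (!is.null(mk)) {
    x$calls <- x$calls[, mk, drop = FALSE]
    x$map <- x$map[mk, , drop = FALSE]
    rownames(x$map) <- NULL
  }
  x
}

#' Apply QC filters to a genotype dataset
#'
#' Filters are applied sequentially, each on the output of the previous:
#' (1) individuals with call rate below `1 - max_individual_missing`;
#' (2) markers failing the exact HWE test at `hwe_p_floor`;
#' (3) markers with call rate below `min_marker_callrate`;
#' (4) markers with MAF below `min_maf`.
#'
#' @param x an `hbd_geno` dataset.
#' @param thresholds a [qc_thresholds()] object.
#' @return List with `dataset` (filtered) and `report`, a data.frame of
#'   per-stage removed/retained counts. A warning (not an error) is raised
#'   if nothing survives.
#' @export
apply_qc <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "hbd_geno"), inherits(thresholds, "qc_thresholds"))
  report <- data.frame(stage = character(), type = character(),
                       removed = integer(), retained = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, type, keep) {
    report <<- rbind(report, data.frame(
      stage = stage, type = type,
      removed = sum(!keep), retained = sum(keep),
      stringsAsFactors = FALSE))
  }

  ind_miss <- rowMeans(is.na(x$calls))
  keep_i <- ind_miss <= thresholds$max_individual_missing
  note("individual_callrate", "individual", keep_i)
  x <- subset_geno(x, ind = keep_i)

  n2 <- colSums(x$calls == 2, na.rm = TRUE)
  n1 <- colSums(x$calls == 1, na.rm = TRUE)
  n0 <- colSums(x$calls == 0, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(x$calls)), function(j) {
    if (n2[j] + n1[j] + n0[j] == 0) return(1)
    hwe_exact_test(n2[j], n1[j], n0[j])
  }, numeric(1))
  keep_m <- hwe_p > thresholds$hwe_p_floor
  note("hwe", "marker", keep_m)
  x <- subset_geno(x, mk = keep_m)

  callrate <- colMeans(!is.na(x$calls))
  keep_m <- callrate >= thresholds$min_marker_callrate
  note("marker_callrate", "marker", keep_m)
  x <- subset_geno(x, mk = keep_m)

  fr <- estimate_frequencies(x)
  maf <- pmin(fr$freq, 1 - fr$freq)
  keep_m <- !is.na(maf) & maf >= thresholds$min_maf
  note("maf", "marker", keep_m)
  x <- subset_geno(x, mk = keep_m)

  if (nrow(x$calls) == 0 || ncol(x$calls) == 0)
    warning("QC removed all individuals or all markers")
  list(dataset = x, report = report)
}

#' Composite genotypic r-squared between two markers
#'
#' Squared Pearson correlation of the 0/1/2 allele-count codings over
#' individuals with both calls non-missing (phase-free composite LD).
#'
#' @param ga,gb integer genotype vectors over the same individuals.
#' @return r-squared in \[0, 1\]; `NA` (treated as 0 by the pruner) if fewer
#'   than 2 complete pairs or either vector is constant.
#' @export
ld_r2 <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) return(NA_real_)
  a <- ga[ok]; b <- gb[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Greedy LD-threshold marker selection
#'
#' Scans each chromosome in map order; for every marker pair closer than
#' `window_cm` whose r-squared exceeds `r2_threshold`, the member with the
#' lower MAF is dropped (tie: the later map position), preferring the most
#' informative markers. After the scan no retained pair within the window
#' exceeds the threshold. r-squared can be computed on an external reference
#' panel matched by marker id.
#'
#' @param x an `hbd_geno` dataset (map-ordered; [hbd_dataset()] guarantees
#'   this).
#' @param r2_threshold retain only pairs with r^2 <= this (e.g. 0.1 or 0.05).
#' @param window_cm window in centiMorgans within which pairs are tested
#'   (default 0.5; `Inf` gives the all-pairs scan used for verification).
#' @param ld_reference optional `hbd_geno` dataset from which r-squared is
#'   estimated instead of `x`.
#' @return List with `selected` (retained marker ids), `dataset` (subset of
#'   `x`) and `report` (per-chromosome removal counts).
#' @export
select_markers_ld <- function(x, r2_threshold, window_cm = 0.5,
                              ld_reference = NULL) {
  stopifnot(inherits(x, "hbd_geno"), r2_threshold >= 0)
  fr <- estimate_frequencies(x)
  maf <- pmin(fr$freq, 1 - fr$freq)
  ld_calls <- x$calls
  if (!is.null(ld_reference)) {
    stopifnot(inherits(ld_reference, "hbd_geno"))
    idx <- match(x$map$marker_id, ld_reference$map$marker_id)
    if (anyNA(idx))
      stop("ld_reference is missing ", sum(is.na(idx)), " marker(s)")
    ld_calls <- ld_reference$calls[, idx, drop = FALSE]
  }
  window_m <- window_cm / 100
  keep <- rep(TRUE, ncol(x$calls))
  for (ch in unique(x$map$chrom)) {
    idx <- which(x$map$chrom == ch)
    pos <- x$map$pos_m[idx]
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!keep[i]) next
      jj <- ii + 1
      while (jj <= length(idx) && pos[jj] - pos[ii] <= window_m) {
        j <- idx[jj]
        if (keep[j]) {
          r2 <- ld_r2(ld_calls[, i], ld_calls[, j])
          if (!is.na(r2) && r2 > r2_threshold) {
            drop <- if (isTRUE(maf[i] < maf[j])) i
                    else if (isTRUE(maf[j] < maf[i])) j
                    else j   # MAF tie: drop the later map position
            keep[drop] <- FALSE
            if (drop == i) break
          }
        }
        jj <- jj + 1
      }
    }
  }
  report <- do.call(rbind, lapply(unique(x$map$chrom), function(ch) {
    m <- x$map$chrom == ch
    data.frame(chrom = ch, removed = sum(m & !keep), retained = sum(m & keep))
  }))
  list(selected = x$map$marker_id[keep],
       dataset = subset_geno(x, mk = keep),
       report = report)
}
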