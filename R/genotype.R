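# Genotype data model: individuals x markers calls, marker map, frequencies.
#
# Genotype coding throughout the package: integer count of allele 1,
#   2 = hom allele 1, 1 = het, 0 = hom allele 2, NA = missing.
# Genetic positions are stored in Morgans everywhere; PLINK MAP column 3 is
# read as centiMorgans and divided by 100 on input.

#' Construct a genotype dataset
#'
#' Bundles a calls matrix with its marker map. This is the container used by
#' the QC, pruning and estimation functions; [read_plink()] returns one.
#'
#' @param calls integer matrix, individuals in rows and markers in columns;
#'   entries are allele-1 counts (2 = hom allele 1, 1 = het, 0 = hom allele 2)
#'   with `NA` for missing.
#' @param map data.frame with columns `marker_id`, `chrom` (autosome number),
#'   `pos_m` (genetic position in Morgans) and optionally `pos_bp`, `allele1`,
#'   `allele2`. Markers must appear in the same order as the columns of
#'   `calls`.
#' @param fam optional data.frame of PED header columns (`fid`, `iid`, `pat`,
#'   `mat`, `sex`, `phe`); a minimal one is built from the row names of
#'   `calls` when absent.
#' @return An object of class `hbd_geno` with elements `calls`, `map`, `fam`.
#' @export
hbd_dataset <- function(calls, map, fam = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(ncol(calls) == nrow(map))
  req <- c("marker_id", "chrom", "pos_m")
  if (!all(req %in% names(map)))
    stop("map must have columns: ", paste(req, collapse = ", "))
  if (!all(map$chrom %in% 1:22))
    stop("only autosomes (chromosomes 1-22) are supported")
  if (is.null(map$pos_bp)) map$pos_bp <- 0L
  if (is.null(map$allele1)) map$allele1 <- "1"
  if (is.null(map$allele2)) map$allele2 <- "2"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  colnames(calls) <- map$marker_id
  if (is.null(fam)) {
    fam <- data.frame(fid = rownames(calls), iid = rownames(calls),
                      pat = "0", mat = "0", sex = "0", phe = "-9",
                      stringsAsFactors = FALSE)
  }
  # stable sort by (chromosome, position); ties keep input order
  o <- order(map$chrom, map$pos_m)
  reordered <- !identical(o, seq_len(nrow(map)))
  map$input_index <- seq_len(nrow(map))
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, o, drop = FALSE]
  structure(list(calls = calls, map = map, fam = fam,
                 map_reordered = reordered),
            class = "hbd_geno")
}

#' @export
print.hbd_geno <- function(x, ...) {
  cat("<hbd_geno> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing calls: ", format(100 * miss, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.hbd_geno <- function(x) dim(x$calls)

#' Read PLINK text PED/MAP files
#'
#' Parses the PLINK text dialect: a 4-column MAP (chromosome, marker id,
#' genetic position in cM, base-pair position) and a PED file with six header
#' columns followed by two allele columns per marker. Allele 1 at each marker
#' is the first non-missing allele observed in file order unless overridden;
#' `0` codes a missing allele and any half-missing genotype is treated as
#' missing.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param allele1 optional named character vector (`marker_id -> allele`)
#'   fixing which allele is counted as allele 1.
#' @return An [hbd_dataset()] object; genetic positions are converted from cM
#'   to Morgans.
#' @export
read_plink <- function(ped_path, map_path, allele1 = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) != 4)
    stop("MAP file must have 4 columns (chrom, id, cM, bp): ", map_path)
  names(mp) <- c("chrom", "marker_id", "cm", "pos_bp")
  mp$chrom <- suppressWarnings(as.integer(mp$chrom))
  if (anyNA(mp$chrom) || !all(mp$chrom %in% 1:22))
    stop("non-autosomal or unparsable chromosome in MAP file")
  m <- nrow(mp)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  expect <- 6L + 2L * m
  if (any(nf != expect))
    stop("ragged PED row: line ", which(nf != expect)[1], " has ",
         nf[nf != expect][1], " fields, expected ", expect)
  fm <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  fam <- data.frame(fid = fm[, 1], iid = fm[, 2], pat = fm[, 3],
                    mat = fm[, 4], sex = fm[, 5], phe = fm[, 6],
                    stringsAsFactors = FALSE)
  alA <- fm[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  alB <- fm[, 6L + 2L * seq_len(m), drop = FALSE]

  calls <- matrix(NA_integer_, nrow(fm), m)
  a1 <- a2 <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    seen <- as.vector(rbind(alA[, j], alB[, j]))  # file order of observation
    u <- setdiff(unique(seen), "0")
    if (length(u) > 2)
      stop("more than 2 alleles at marker ", mp$marker_id[j], ": ",
           paste(u, collapse = ","))
    if (!is.null(allele1) && mp$marker_id[j] %in% names(allele1)) {
      a1[j] <- allele1[[mp$marker_id[j]]]
      a2[j] <- setdiff(u, a1[j])[1]
      if (!a1[j] %in% u && length(u) == 2)
        stop("override allele ", a1[j], " not observed at ", mp$marker_id[j])
    } else {
      a1[j] <- u[1]
      a2[j] <- if (length(u) > 1) u[2] else NA_character_
    }
    miss <- alA[, j] == "0" | alB[, j] == "0"
    g <- (alA[, j] == a1[j]) + (alB[, j] == a1[j])
    g[miss] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  rownames(calls) <- fam$iid
  map <- data.frame(marker_id = mp$marker_id, chrom = mp$chrom,
                    pos_m = mp$cm / 100, pos_bp = mp$pos_bp,
                    allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  hbd_dataset(calls, map, fam)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' @param x an `hbd_geno` object.
#' @param ped_path,map_path output file paths.
#' @return Invisibly, `x`. `read_plink(write_plink(x))` round-trips calls,
#'   ids and map.
#' @export
write_plink <- function(x, ped_path, map_path) {
  stopifnot(inherits(x, "hbd_geno"))
  mp <- x$map
  map_out <- data.frame(mp$chrom, mp$marker_id,
                        format(mp$pos_m * 100, trim = TRUE, scientific = FALSE),
                        mp$pos_bp)
  write.table(map_out, map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  a1 <- ifelse(is.na(mp$allele1), "0", mp$allele1)
  a2 <- ifelse(is.na(mp$allele2), "0", mp$allele2)
  n <- nrow(x$calls)
  ped_lines <- character(n)
  for (i in seq_len(n)) {
    g <- x$calls[i, ]
    A <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    B <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    ped_lines[i] <- paste(c(unlist(x$fam[i, ]), as.vector(rbind(A, B))),
                          collapse = " ")
  }
  writeLines(ped_lines, ped_path)
  invisible(x)
}

#' Estimate allele-1 frequencies from a dataset
#'
#' Per-marker sample frequency of allele 1: (2 * n_hom1 + n_het) /
#' (2 * n_nonmissing). Markers with no non-missing calls, or with frequency
#' exactly 0 or 1, are flagged monomorphic and excluded from likelihood-based
#' estimation downstream.
#'
#' @param x an `hbd_geno` object.
#' @return Object of class `hbd_freqs`: list with `mode = "sample_estimated"`,
#'   `freq`, `n_obs` (non-missing individuals per marker) and `monomorphic`.
#' @export
estimate_frequencies <- function(x) {
  stopifnot(inherits(x, "hbd_geno"))
  g <- x$calls
  n2 <- colSums(g == 2, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  nn <- as.integer(colSums(!is.na(g)))
  freq <- ifelse(nn > 0, (2 * n2 + n1) / (2 * nn), NA_real_)
  structure(list(mode = "sample_estimated",
                 freq = setNames(freq, x$map$marker_id),
                 n_obs = setNames(nn, x$map$marker_id),
                 monomorphic = is.na(freq) | freq <= 0 | freq >= 1),
            class = "hbd_freqs")
}

#' Wrap externally provided allele frequencies
#'
#' @param freq numeric vector of allele-1 frequencies, optionally named by
#'   marker id.
#' @return An `hbd_freqs` object with `mode = "provided"` (no small-sample
#'   correction is applied by [f_plink()] in this mode).
#' @export
provided_frequencies <- function(freq) {
  structure(list(mode = "provided", freq = freq, n_obs = NULL,
                 monomorphic = is.na(freq) | freq <= 0 | freq >= 1),
            class = "hbd_freqs")
}

#' @export
print.hbd_freqs <- function(x, ...) {
  cat("<hbd_freqs> mode=", x$mode, ", ", length(x$freq), " markers, ",
      sum(x$monomorphic), " monomorphic/undefined\n", sep = "")
  invisible(x)
}

#' Write / read a per-marker frequency table
#'
#' Two-column TSV with header `marker_id`, `freq_a1`.
#' @param freqs an `hbd_freqs` object (for writing).
#' @param path file path.
#' @return `read_freq_tsv` returns an `hbd_freqs` object in `provided` mode.
#' @export
write_freq_tsv <- function(freqs, path) {
  stopifnot(inherits(freqs, "hbd_freqs"))
  df <- data.frame(marker_id = names(freqs$freq), freq_a1 = unname(freqs$freq))
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_tsv
#' @export
read_freq_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  provided_frequencies(setNames(df$freq_a1, df$marker_id))
}

# Resolve a freqs argument: NULL -> sample-estimated, numeric -> provided.
as_freqs <- function(freqs, dataset = NULL) {
  if (is.null(freqs)) {
    if (is.null(dataset)) stop("no frequencies given and no dataset to estimate from")
    return(estimate_frequencies(dataset))
  }
  if (inherits(freqs, "hbd_freqs")) return(freqs)
  if (is.numeric(freqs)) return(provided_frequencies(freqs))
  stop("cannot interpret `freqs`")
}
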