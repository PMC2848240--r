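# Gene-dropping simulator: founder-labelled haplotypes transmitted through a
# pedigree with Haldane (Poisson, no-interference) recombination, giving
# proband genotypes with exactly known homozygosity-by-descent.

#' Build a synthetic linkage-equilibrium marker map
#'
#' Lays `n_markers` uniformly spaced markers across `n_chromosomes`
#' equal-count chromosomes. Marker i on a chromosome sits at
#' `(i - 0.5) * spacing` Morgans and the chromosome length is
#' `n_on_chrom * spacing`, so the total genetic length is
#' `n_markers * spacing`. Allele-1 frequencies are drawn i.i.d. from
#' `freq_sampler`; the default Uniform(0.05, 0.95) on the allele-1 frequency
#' is equivalent to a Uniform(0.05, 0.5) minor-allele frequency.
#'
#' @param n_markers total marker count (default 4849).
#' @param spacing_morgans inter-marker spacing in Morgans (default 0.008,
#'   i.e. 0.8 cM).
#' @param n_chromosomes number of chromosomes (default 22).
#' @param freq_sampler function of `n` returning allele-1 frequencies.
#' @param seed optional integer seed for the frequency draw.
#' @return A map data.frame (class `hbd_simmap`) with columns `marker_id`,
#'   `chrom`, `pos_m`, `freq_a1`, and attributes recording the generation
#'   parameters (`spacing`, `chrom_lengths`, `freq_sampler_desc`, `seed`).
#' @export
make_sim_map <- function(n_markers = 4849, spacing_morgans = 0.008,
                         n_chromosomes = 22,
                         freq_sampler = function(n) runif(n, 0.05, 0.95),
                         seed = NULL) {
  stopifnot(n_markers >= 1, spacing_morgans > 0, n_chromosomes >= 1)
  base <- n_markers %/% n_chromosomes
  extra <- n_markers %% n_chromosomes
  counts <- rep(base, n_chromosomes) + c(rep(1L, extra),
                                         rep(0L, n_chromosomes - extra))
  counts <- counts[counts > 0]
  if (!is.null(seed)) set.seed(seed)
  chrom <- rep(seq_along(counts), counts)
  within <- sequence(counts)
  pos <- (within - 0.5) * spacing_morgans
  map <- data.frame(
    marker_id = sprintf("snp_%d_%d", chrom, within),
    chrom = chrom, pos_m = pos,
    freq_a1 = freq_sampler(n_markers),
    stringsAsFactors = FALSE)
  attr(map, "spacing") <- spacing_morgans
  attr(map, "chrom_lengths") <- counts * spacing_morgans
  attr(map, "freq_sampler_desc") <-
    paste(deparse(body(freq_sampler)), collapse = " ")
  attr(map, "seed") <- seed
  class(map) <- c("hbd_simmap", "data.frame")
  map
}

# Precomputed geometry for fast repeated meioses on one map:
# chromosome lengths, global marker coordinates with per-chromosome offsets.
meiosis_plan <- function(map) {
  chrom <- map$chrom
  pos <- map$pos_m
  if (is.unsorted(chrom) || any(stats::ave(pos, chrom, FUN = function(x)
      c(0, diff(x))) < 0))
    stop("map must be ordered by (chrom, pos)")
  uc <- unique(chrom)
  ci <- match(chrom, uc)
  lo <- tapply(pos, ci, min)
  hi <- tapply(pos, ci, max)
  len <- as.numeric(hi - lo)
  if (inherits(map, "hbd_simmap")) {
    cl <- attr(map, "chrom_lengths")
    if (!is.null(cl)) { len <- as.numeric(cl); lo <- lo - lo }  # lengths incl. margins
  }
  # offsets so chromosome intervals are disjoint on a global axis
  off <- cumsum(c(0, head(len, -1) + 1e-9))
  gpos <- off[ci] + (pos - as.numeric(lo)[ci])
  list(n_chrom = length(uc), chrom_index = ci, len = len, off = off,
       gpos = gpos, n_markers = length(pos))
}

# One meiosis: recombinant mosaic of the parent's two haplotypes.
# Crossovers are a homogeneous Poisson process on genetic distance per
# chromosome (Haldane, no interference); the starting haplotype per
# chromosome is a fair coin.
meiosis <- function(h1, h2, plan) {
  starts <- rbinom(plan$n_chrom, 1L, 0.5)
  ncr <- rpois(plan$n_chrom, plan$len)
  tot <- sum(ncr)
  if (tot == 0L) {
    chooser <- starts[plan$chrom_index]
  } else {
    cidx <- rep.int(seq_len(plan$n_chrom), ncr)
    cpos <- plan$off[cidx] + runif(tot) * plan$len[cidx]
    cpos <- sort(cpos)
    cum <- findInterval(plan$gpos, cpos)
    before <- c(0, cumsum(ncr))[plan$chrom_index]
    chooser <- (starts[plan$chrom_index] + cum - before) %% 2L
  }
  ifelse(chooser == 0L, h1, h2)
}

#' Gene-drop founder labels through a pedigree
#'
#' Each founder carries two globally unique haplotype labels; every meiosis
#' transmits a recombinant mosaic of the parent's two label sequences with
#' Haldane crossovers. Returns the proband's two label sequences over the
#' markers of `map`.
#'
#' @param pedigree an [build_cousin_pedigree()] pedigree (or any
#'   `hbd_pedigree`).
#' @param map marker map data.frame ordered by (chrom, pos_m).
#' @param plan optional precomputed internal geometry (reused across
#'   replicates for speed).
#' @return List with integer vectors `h1`, `h2` of founder-haplotype labels,
#'   one per marker.
#' @export
gene_drop <- function(pedigree, map, plan = NULL) {
  validate_pedigree(pedigree)
  if (is.null(plan)) plan <- meiosis_plan(map)
  L <- plan$n_markers
  haps <- new.env(parent = emptyenv())
  lab <- 0L
  for (i in seq_len(nrow(pedigree))) {
    id <- pedigree$id[i]
    if (is.na(pedigree$father[i])) {
      haps[[id]] <- list(rep.int(lab + 1L, L), rep.int(lab + 2L, L))
      lab <- lab + 2L
    } else {
      fh <- haps[[pedigree$father[i]]]
      mh <- haps[[pedigree$mother[i]]]
      haps[[id]] <- list(meiosis(fh[[1]], fh[[2]], plan),
                         meiosis(mh[[1]], mh[[2]], plan))
    }
  }
  pr <- haps[[attr(pedigree, "proband_id")]]
  list(h1 = pr[[1]], h2 = pr[[2]])
}

#' Ground-truth HBD track from a founder-label pair
#'
#' A marker is homozygous-by-descent exactly when the two transmitted founder
#' labels coincide; the true inbreeding coefficient of the replicate is the
#' mean of that indicator over markers.
#'
#' @param label_pair list with `h1`, `h2` as returned by [gene_drop()].
#' @return List (class `hbd_track`) with logical `hbd` and scalar `f_true`.
#' @export
hbd_track <- function(label_pair) {
  stopifnot(length(label_pair$h1) == length(label_pair$h2))
  hbd <- label_pair$h1 == label_pair$h2
  structure(list(hbd = hbd, f_true = mean(hbd)), class = "hbd_track")
}

#' Assign alleles to founder labels at linkage equilibrium
#'
#' Each distinct founder label at each marker receives allele 1 with the
#' map's `freq_a1`, independently across markers and labels; identical labels
#' share one draw, so HBD markers are always homozygous (no mutation or
#' genotyping error in the generative model).
#'
#' @param label_pair list with `h1`, `h2` from [gene_drop()].
#' @param map map with a `freq_a1` column.
#' @return Integer genotype vector (allele-1 counts 0/1/2), one per marker.
#' @export
assign_genotypes <- function(label_pair, map) {
  p <- map$freq_a1
  stopifnot(length(label_pair$h1) == length(p))
  a1 <- rbinom(length(p), 1L, p)
  a2 <- rbinom(length(p), 1L, p)
  shared <- label_pair$h1 == label_pair$h2
  a2[shared] <- a1[shared]
  as.integer(a1 + a2)
}

#' Simulate gene-drop replicates for a cousin-offspring scenario
#'
#' Runs independent gene-dropping replicates of the proband of a
#' first/second/third-cousin mating, each yielding the true HBD track and
#' (optionally) a genotype vector drawn at linkage equilibrium. Replicates
#' use L'Ecuyer-CMRG substreams so replicate r depends only on
#' `(seed, r)`.
#'
#' @param degree cousin degree 1, 2 or 3.
#' @param n_replicates number of replicates.
#' @param map map from [make_sim_map()] (built with defaults when `NULL`).
#' @param seed integer master seed.
#' @param genotypes if `FALSE`, skip allele assignment (truth only).
#' @param keep_tracks if `FALSE`, drop per-marker HBD vectors and keep only
#'   `f_true` (saves memory at large n).
#' @param FUN optional function `(genotypes, track, replicate)` applied to
#'   each replicate; its value is stored in place of the raw replicate, which
#'   keeps memory flat when streaming estimators over many replicates.
#' @return List (class `hbd_replicates`) with elements `f_true` (vector),
#'   `replicates` (list, contents per `keep_tracks`/`genotypes`/`FUN`),
#'   `map`, `degree`, `seed`, and `stream_seeds` (first state word of each
#'   replicate's RNG substream).
#' @export
simulate_replicates <- function(degree, n_replicates, map = NULL, seed = 1,
                                genotypes = TRUE, keep_tracks = TRUE,
                                FUN = NULL) {
  stopifnot(n_replicates >= 1)
  if (is.null(map)) map <- make_sim_map(seed = seed)
  ped <- build_cousin_pedigree(degree)
  plan <- meiosis_plan(map)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind("L'Ecuyer-CMRG")
  on.exit({
    # .Random.seed encodes the RNG kind, so restoring it restores both
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else RNGkind(old_kind[1])
  })
  set.seed(seed)
  stream <- get(".Random.seed", globalenv())
  f_true <- numeric(n_replicates)
  reps <- vector("list", n_replicates)
  stream_seeds <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    assign(".Random.seed", stream, globalenv())
    stream_seeds[r] <- stream[2]
    labs <- gene_drop(ped, map, plan)
    trk <- hbd_track(labs)
    f_true[r] <- trk$f_true
    g <- if (genotypes) assign_genotypes(labs, map) else NULL
    reps[[r]] <- if (!is.null(FUN)) {
      FUN(g, trk, r)
    } else {
      out <- list(f_true = trk$f_true)
      if (keep_tracks) out$hbd <- trk$hbd
      if (genotypes) out$genotypes <- g
      out
    }
    stream <- parallel::nextRNGStream(stream)
  }
  structure(list(f_true = f_true, replicates = reps, map = map,
                 degree = degree, seed = seed, stream_seeds = stream_seeds),
            class = "hbd_replicates")
}

#' @export
print.hbd_replicates <- function(x, ...) {
  cat("<hbd_replicates> degree ", x$degree, ", ", length(x$f_true),
      " replicates, mean true F = ", format(mean(x$f_true), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Export simulated replicates to plain-text files
#'
#' Writes one PLINK PED/MAP pair covering all replicates (each replicate is
#' one PED row), a truth TSV (`replicate`, `marker_id`, `hbd`), a summary TSV
#' (`replicate`, `f_true`) and a flat `key=value` config file recording the
#' simulation parameters.
#'
#' @param sims an `hbd_replicates` object simulated with `genotypes = TRUE`
#'   and `keep_tracks = TRUE`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
export_replicates <- function(sims, dir) {
  stopifnot(inherits(sims, "hbd_replicates"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(sims$f_true)
  gmat <- do.call(rbind, lapply(sims$replicates, `[[`, "genotypes"))
  if (is.null(gmat)) stop("replicates were simulated without genotypes")
  rownames(gmat) <- sprintf("rep%d", seq_len(n))
  map <- sims$map
  map$pos_bp <- round(map$pos_m * 1e8)
  ds <- hbd_dataset(gmat, map)
  paths <- file.path(dir, c("replicates.ped", "replicates.map",
                            "truth.tsv", "summary.tsv", "config.txt"))
  write_plink(ds, paths[1], paths[2])
  truth <- do.call(rbind, lapply(seq_len(n), function(r)
    data.frame(replicate = r, marker_id = map$marker_id,
               hbd = as.integer(sims$replicates[[r]]$hbd))))
  write.table(truth, paths[3], quote = FALSE, sep = "\t", row.names = FALSE)
  write.table(data.frame(replicate = seq_len(n), f_true = sims$f_true),
              paths[4], quote = FALSE, sep = "\t", row.names = FALSE)
  cfg <- c(paste0("degree=", sims$degree),
           paste0("n_replicates=", n),
           paste0("seed=", sims$seed),
           paste0("n_markers=", nrow(map)),
           paste0("spacing_morgans=", attr(map, "spacing")),
           paste0("freq_sampler=", attr(map, "freq_sampler_desc")))
  writeLines(cfg, paths[5])
  invisible(paths)
}
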