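# Pedigrees for consanguineous matings and path-counting inbreeding.

#' Build the canonical cousin-mating pedigree
#'
#' Constructs the pedigree in which the proband's parents are first, second or
#' third cousins. Two founder siblings descend from a shared ancestral couple;
#' each sib line is extended by `degree` generations (each child mating a new
#' unrelated founder), and the two line ends — who are cousins of the given
#' degree — produce the proband. The proband's path-counting inbreeding
#' coefficient is `2^-(2*degree + 2)`: 1/16, 1/64, 1/256.
#'
#' @param degree 1 (first cousins), 2 (second) or 3 (third).
#' @return Object of class `hbd_pedigree`: data.frame `members` with columns
#'   `id`, `father`, `mother` (`NA` for founders) plus attribute `proband_id`.
#' @export
build_cousin_pedigree <- function(degree) {
  if (!degree %in% 1:3) stop("unsupported degree: ", degree)
  add <- function(tab, id, father = NA, mother = NA)
    rbind(tab, data.frame(id = id, father = father, mother = mother,
                          stringsAsFactors = FALSE))
  tab <- data.frame(id = character(), father = character(),
                    mother = character(), stringsAsFactors = FALSE)
  tab <- add(tab, "anc_f"); tab <- add(tab, "anc_m")
  tab <- add(tab, "sib_a", "anc_f", "anc_m")
  tab <- add(tab, "sib_b", "anc_f", "anc_m")
  pa <- "sib_a"; pb <- "sib_b"
  for (k in seq_len(degree)) {
    spa <- sprintf("sp_a%d", k); spb <- sprintf("sp_b%d", k)
    cha <- sprintf("desc_a%d", k); chb <- sprintf("desc_b%d", k)
    tab <- add(tab, spa); tab <- add(tab, spb)
    tab <- add(tab, cha, pa, spa)
    tab <- add(tab, chb, pb, spb)
    pa <- cha; pb <- chb
  }
  tab <- add(tab, "proband", pa, pb)
  ped <- structure(tab, class = c("hbd_pedigree", "data.frame"))
  attr(ped, "proband_id") <- "proband"
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "hbd_pedigree"))
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  both <- is.na(ped$father) == is.na(ped$mother)
  if (!all(both)) stop("individuals must have both or neither parent")
  known <- c(NA, ids)
  if (!all(ped$father %in% known & ped$mother %in% known))
    stop("parent id not in pedigree")
  # parents must precede children (construction order is topological)
  idx <- setNames(seq_along(ids), ids)
  nf <- !is.na(ped$father)
  if (any(idx[ped$father[nf]] >= idx[ped$id[nf]]) ||
      any(idx[ped$mother[nf]] >= idx[ped$id[nf]]))
    stop("pedigree rows must be topologically ordered (parents first)")
  pr <- attr(ped, "proband_id")
  if (!pr %in% ids || is.na(ped$father[ids == pr]))
    stop("proband missing or has no parents")
  invisible(ped)
}

#' Expected (path-counting) inbreeding coefficient of a pedigree member
#'
#' Computed as the kinship coefficient of the individual's parents via the
#' standard recursive kinship algorithm, independent of any simulation.
#'
#' @param ped an `hbd_pedigree`.
#' @param id member id; defaults to the proband.
#' @return The expected inbreeding coefficient F.
#' @export
pedigree_expected_f <- function(ped, id = attr(ped, "proband_id")) {
  validate_pedigree(ped)
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  cache <- new.env(parent = emptyenv())
  depth <- setNames(integer(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    p <- fa[[ped$id[i]]]
    depth[i] <- if (is.na(p)) 0L else max(depth[[p]], depth[[mo[[ped$id[i]]]]]) + 1L
  }
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(fa[[a]], mo[[a]]))
    } else {
      # recurse on the member deeper in the pedigree
      if (depth[[a]] < depth[[b]]) { tmp <- a; a <- b; b <- tmp }
      0.5 * (phi(fa[[a]], b) + phi(mo[[a]], b))
    }
    cache[[key]] <- val
    val
  }
  phi(fa[[id]], mo[[id]])
}

#' @export
print.hbd_pedigree <- function(x, ...) {
  cat("<hbd_pedigree> ", nrow(x), " members, proband = ",
      attr(x, "proband_id"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
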