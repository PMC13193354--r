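#' Diploid multiallelic genotype matrix
#'
#' Container for diploid genotype calls at multiallelic codominant loci
#' (e.g. microsatellites). Each call is an unordered pair of allele labels
#' or missing. Allele labels are opaque nominal classes; after fragment
#' binning they are integers such as repeat-grid sizes in bp.
#'
#' @param ind_id character vector of unique individual labels.
#' @param group character vector (recycled if length 1) of sampling-location
#'   or cluster labels, one per individual.
#' @param loci character vector of unique locus names.
#' @param a1,a2 matrices (individuals x loci) of allele labels; `NA` marks a
#'   missing allele. A call with exactly one missing allele is half-missing:
#'   it is flagged and treated as fully missing by all statistics.
#'
#' @return An object of class `geno_matrix` with elements `ind_id`, `group`,
#'   `loci`, `alleles` (per-locus sorted allele universe) and `tab`, an
#'   `n x 2L` integer matrix of allele indices (columns `2j-1`, `2j` hold the
#'   sorted index pair at locus `j`; `NA` = missing).
#' @export
genotype_matrix <- function(ind_id, group, loci, a1, a2) {
  ind_id <- as.character(ind_id)
  if (anyDuplicated(ind_id)) stop("duplicate individual ids")
  n <- length(ind_id)
  if (length(group) == 1L) group <- rep(group, n)
  group <- as.character(group)
  stopifnot(length(group) == n)
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicate locus names")
  L <- length(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(nrow(a1) == n, ncol(a1) == L, nrow(a2) == n, ncol(a2) == L)

  half <- xor(is.na(a1), is.na(a2))
  # half-missing calls collapse to fully missing downstream
  a1[half] <- NA; a2[half] <- NA

  alleles <- vector("list", L)
  tab <- matrix(NA_integer_, n, 2L * L)
  for (j in seq_len(L)) {
    univ <- sort(unique(c(a1[, j], a2[, j])))
    univ <- univ[!is.na(univ)]
    alleles[[j]] <- univ
    i1 <- match(a1[, j], univ)
    i2 <- match(a2[, j], univ)
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    tab[, 2L * j - 1L] <- lo
    tab[, 2L * j] <- hi
  }
  names(alleles) <- loci
  structure(
    list(ind_id = ind_id, group = group, loci = loci,
         alleles = alleles, tab = tab, half_missing = half),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d loci, %d groups\n",
              n_ind(x), n_loci(x), length(unique(x$group))))
  na <- vapply(x$alleles, length, 1L)
  cat(sprintf("  alleles/locus: %d-%d (mean %.1f)\n",
              min(na), max(na), mean(na)))
  miss <- mean(is.na(x$tab[, seq(1, ncol(x$tab), 2), drop = FALSE]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param gm a `geno_matrix`.
#' @return integer count.
#' @export
n_ind <- function(gm) length(gm$ind_id)

#' @rdname n_ind
#' @export
n_loci <- function(gm) length(gm$loci)

#' Logical matrix of missing calls (individuals x loci)
#' @param gm a `geno_matrix`.
#' @return logical matrix, TRUE where the call is missing.
#' @export
missing_calls <- function(gm) {
  m <- is.na(gm$tab[, seq(1L, 2L * n_loci(gm), by = 2L), drop = FALSE])
  dimnames(m) <- list(gm$ind_id, gm$loci)
  m
}

#' Subset a genotype matrix by individuals
#'
#' Pure row subset: surviving genotypes, locus order and allele universes
#' are untouched.
#'
#' @param gm a `geno_matrix`.
#' @param keep logical or integer index over individuals.
#' @param group optional replacement group labels for the kept individuals.
#' @return a `geno_matrix`.
#' @export
subset_ind <- function(gm, keep, group = NULL) {
  idx <- seq_len(n_ind(gm))[keep]
  out <- gm
  out$ind_id <- gm$ind_id[idx]
  out$group <- if (is.null(group)) gm$group[idx] else as.character(group)
  out$tab <- gm$tab[idx, , drop = FALSE]
  out$half_missing <- gm$half_missing[idx, , drop = FALSE]
  out
}

#' Allele count table per (group, locus)
#'
#' Tabulates gene copies by group and locus; the substrate of every
#' diversity and differentiation statistic.
#'
#' @param gm a `geno_matrix`.
#' @param group grouping vector (defaults to `gm$group`).
#' @return class `allele_counts`: list with `groups`, `loci`, `counts`
#'   (`counts[[g]][[l]]` = integer vector over the locus allele universe),
#'   and `n_ind` (groups x loci matrix of genotyped individuals; gene copies
#'   are `2 * n_ind`).
#' @export
allele_counts <- function(gm, group = gm$group) {
  stopifnot(length(group) == n_ind(gm))
  groups <- unique(group)
  L <- n_loci(gm)
  counts <- vector("list", length(groups))
  names(counts) <- groups
  nmat <- matrix(0L, length(groups), L, dimnames = list(groups, gm$loci))
  for (g in seq_along(groups)) {
    rows <- which(group == groups[g])
    cl <- vector("list", L)
    for (j in seq_len(L)) {
      A <- length(gm$alleles[[j]])
      v <- c(gm$tab[rows, 2L * j - 1L], gm$tab[rows, 2L * j])
      v <- v[!is.na(v)]
      cnt <- tabulate(v, nbins = A)
      names(cnt) <- as.character(gm$alleles[[j]])
      cl[[j]] <- cnt
      nmat[g, j] <- length(v) %/% 2L
    }
    names(cl) <- gm$loci
    counts[[g]] <- cl
  }
  structure(list(groups = groups, loci = gm$loci, counts = counts,
                 n_ind = nmat),
            class = "allele_counts")
}

#' Remove individuals with too many missing genotypes
#'
#' Individuals failing to amplify at strictly more than `max_missing_loci`
#' loci are dropped, mirroring the standard quality filter for partially
#' amplified DNA samples.
#'
#' @param gm a `geno_matrix`.
#' @param max_missing_loci integer in `[0, n_loci]`; individuals with more
#'   missing calls than this are removed.
#' @return list with `genotypes` (filtered `geno_matrix`, original order
#'   preserved) and `removed` (data frame of dropped ids and their missing
#'   counts).
#' @export
filter_missing <- function(gm, max_missing_loci) {
  stopifnot(length(max_missing_loci) == 1L,
            max_missing_loci >= 0, max_missing_loci <= n_loci(gm))
  nmiss <- rowSums(missing_calls(gm))
  drop <- nmiss > max_missing_loci
  if (all(drop)) stop("filter removed every individual")
  removed <- data.frame(ind_id = gm$ind_id[drop],
                        n_missing = as.integer(nmiss[drop]),
                        stringsAsFactors = FALSE)
  list(genotypes = subset_ind(gm, !drop), removed = removed)
}

# internal: allele labels (not indices) for locus j, n x 2 matrix
.allele_labels <- function(gm, j) {
  lab <- gm$alleles[[j]]
  cbind(lab[gm$tab[, 2L * j - 1L]], lab[gm$tab[, 2L * j]])
}
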