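#' Within-group diversity statistics per locus
#'
#' For every (group, locus) cell with at least one genotyped individual:
#' sample size `N` (genotyped individuals), allele count `N_A`, observed
#' heterozygosity `H_O`, plug-in expected heterozygosity
#' `H_E = 1 - sum(p^2)`, unbiased `uH_E = H_E * 2N/(2N - 1)`, inbreeding
#' coefficient `F = 1 - H_O / H_E` (NA-flagged when `H_E = 0`),
#' polymorphic information content
#' `PIC = 1 - sum(p^2) - sum_{a<b} 2 p_a^2 p_b^2`, and the number of
#' private alleles (present in this group, absent from all others).
#' A final `"over loci"` row per group holds arithmetic means.
#'
#' @param gm a `geno_matrix`.
#' @param group grouping vector; defaults to the stored labels.
#' @return data frame, one row per (group, locus) plus per-group mean rows.
#' @export
diversity_stats <- function(gm, group = gm$group) {
  ac <- allele_counts(gm, group)
  miss <- missing_calls(gm)
  L <- n_loci(gm)
  rows <- list()
  for (g in ac$groups) {
    gi <- which(group == g)
    per <- data.frame(group = g, locus = gm$loci, N = NA_real_,
                      N_A = NA_real_, H_O = NA_real_, H_E = NA_real_,
                      uH_E = NA_real_, F = NA_real_, PIC = NA_real_,
                      n_private = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_len(L)) {
      cnt <- ac$counts[[g]][[j]]
      nind <- ac$n_ind[g, j]
      if (nind == 0L) {
        warning(sprintf("no genotyped individuals for %s at %s; skipped",
                        g, gm$loci[j]))
        next
      }
      p <- cnt / sum(cnt)
      he <- 1 - sum(p^2)
      geno_rows <- gi[!miss[gi, j]]
      ho <- mean(gm$tab[geno_rows, 2L * j - 1L] != gm$tab[geno_rows, 2L * j])
      pic <- he - sum((outer(p^2, p^2))[upper.tri(diag(length(p)))]) * 2
      others <- Reduce(`+`, lapply(ac$counts[setdiff(ac$groups, g)],
                                   function(x) x[[j]]),
                       accumulate = FALSE, init = numeric(length(cnt)))
      per$N[j] <- nind
      per$N_A[j] <- sum(cnt > 0)
      per$H_O[j] <- ho
      per$H_E[j] <- he
      per$uH_E[j] <- he * 2 * nind / (2 * nind - 1)
      per$F[j] <- if (he > 0) 1 - ho / he else NA_real_
      per$PIC[j] <- pic
      per$n_private[j] <- sum(cnt > 0 & others == 0)
    }
    keep <- !is.na(per$N)
    per <- per[keep, , drop = FALSE]
    mean_row <- per[1, , drop = FALSE]
    mean_row$locus <- "over loci"
    for (cn in c("N", "N_A", "H_O", "H_E", "uH_E", "F", "PIC", "n_private"))
      mean_row[[cn]] <- mean(per[[cn]], na.rm = TRUE)
    rows[[g]] <- rbind(per, mean_row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by the hypergeometric closed form
#' `E[A_g] = sum_a (1 - choose(N - N_a, g) / choose(N, g))`.
#'
#' @param counts integer vector of allele copy counts at one locus in one
#'   group.
#' @param g gene copies to rarefy to, `1 <= g <= sum(counts)`.
#' @return expected allele count (numeric scalar).
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must be in [1, total gene copies]")
  # lchoose for stability; choose(N - Na, g) = 0 when g > N - Na
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' First-order jackknife allelic richness
#'
#' Treats individuals as sampling units: `S_jack1 = S_obs + Q1 (m-1)/m`
#' where `m` is the number of genotyped individuals and `Q1` the number of
#' alleles observed in exactly one individual. The standard error follows
#' the Heltshe-Forrester variance
#' `var = (m-1)/m * (sum_j j^2 f_j - Q1^2 / m)` with `f_j` the number of
#' individuals carrying exactly `j` singleton alleles.
#'
#' @param gm a `geno_matrix`.
#' @param group group label.
#' @param locus locus name.
#' @return list with `S_jack1`, `SE`, `S_obs`, `Q1`, `m`.
#' @export
jackknife_richness <- function(gm, group, locus) {
  j <- match(locus, gm$loci)
  if (is.na(j)) stop("unknown locus ", locus)
  rows <- which(gm$group == group & !missing_calls(gm)[, j])
  m <- length(rows)
  if (m < 2L) stop("need at least 2 genotyped individuals")
  # presence of each allele per individual
  pairs <- cbind(gm$tab[rows, 2L * j - 1L], gm$tab[rows, 2L * j])
  A <- length(gm$alleles[[j]])
  pres <- matrix(FALSE, m, A)
  pres[cbind(seq_len(m), pairs[, 1])] <- TRUE
  pres[cbind(seq_len(m), pairs[, 2])] <- TRUE
  n_carriers <- colSums(pres)
  S_obs <- sum(n_carriers > 0)
  singles <- which(n_carriers == 1L)
  Q1 <- length(singles)
  S_jack1 <- S_obs + Q1 * (m - 1) / m
  per_ind_singletons <- rowSums(pres[, singles, drop = FALSE])
  f <- tabulate(per_ind_singletons + 1L)   # f[j+1] = #ind with j singletons
  jj <- seq_along(f) - 1L
  v <- (m - 1) / m * (sum(jj^2 * f) - Q1^2 / m)
  list(S_jack1 = S_jack1, SE = sqrt(max(v, 0)), S_obs = S_obs,
       Q1 = Q1, m = m)
}
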