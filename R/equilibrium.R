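# internal: C++-ready encoding (0 = missing allele index)
.gmat <- function(gm) {
  G <- gm$tab
  G[is.na(G)] <- 0L
  list(G = G, A = vapply(gm$alleles, length, 1L))
}

# log conditional probability of a genotype array given allele counts:
# log P = log n! - sum log n_ab! + sum log n_a! - log (2n)! + h log 2
.hwe_logP <- function(tab_counts, n, allele_counts) {
  h <- sum(tab_counts[attr(tab_counts, "het")])
  lgamma(n + 1) - sum(lgamma(tab_counts + 1)) +
    sum(lgamma(allele_counts + 1)) - lgamma(2 * n + 1) + h * log(2)
}

# enumerate all genotype arrays compatible with the allele counts; calls
# fn(counts_vector, score) for each, where score = h*log2 - sum(log n_ab!)
.hwe_enumerate <- function(allele_counts, fn) {
  k <- length(allele_counts)
  cats <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cats <- cats[order(cats[, 1], cats[, 2]), , drop = FALSE]
  ncat <- nrow(cats)
  counts <- integer(ncat)
  rec <- function(ci, rem) {
    if (ci > ncat) {
      if (all(rem == 0L)) {
        het <- cats[, 1] != cats[, 2]
        s <- sum(counts[het]) * log(2) - sum(lgamma(counts + 1))
        fn(counts, s)
      }
      return(invisible())
    }
    a <- cats[ci, 1]; b <- cats[ci, 2]
    hi <- if (a == b) rem[a] %/% 2L else min(rem[a], rem[b])
    for (v in 0:hi) {
      counts[ci] <<- v
      r2 <- rem
      if (a == b) r2[a] <- r2[a] - 2L * v
      else { r2[a] <- r2[a] - v; r2[b] <- r2[b] - v }
      rec(ci + 1L, r2)
    }
    counts[ci] <<- 0L
  }
  rec(1L, as.integer(allele_counts))
  invisible()
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional probability test: the probability of the observed genotype
#' array given its allele counts is
#' `P = n! / prod(n_ab!) * prod(n_a!) / (2n)! * 2^h` (with `h`
#' heterozygotes), and the p-value is `Pr[P(array) <= P(observed)]` under
#' the conditional null. The null is enumerated exhaustively when the
#' array space is small (at most `enum_limit` arrays), otherwise sampled
#' by `B` random pairings of the `2n` gene copies with the add-one
#' estimator `(1 + hits) / (1 + B)`.
#'
#' @param gm a `geno_matrix`.
#' @param group group label.
#' @param locus locus name.
#' @param B Monte-Carlo resamples (>= 100).
#' @param seed integer seed for the pairing draws.
#' @param enum_limit switch to full enumeration when the upper bound on
#'   the number of genotype arrays is below this.
#' @return list with `p`, `logP_obs`, `method` (`"enumeration"` or
#'   `"monte-carlo"`), `B`, `monomorphic` flag and `F` (the plug-in
#'   inbreeding coefficient, whose sign diagnoses the deviation
#'   direction).
#' @export
hwe_test <- function(gm, group, locus, B = 10000L, seed = 1L,
                     enum_limit = 1e5) {
  if (B < 100) stop("B must be >= 100")
  j <- match(locus, gm$loci)
  if (is.na(j)) stop("unknown locus ", locus)
  rows <- which(gm$group == group & !missing_calls(gm)[, j])
  n <- length(rows)
  if (n < 2L) stop("need >= 2 genotyped individuals")
  pairs <- cbind(gm$tab[rows, 2L * j - 1L], gm$tab[rows, 2L * j])
  copies <- as.integer(c(pairs))
  ka <- tabulate(copies, nbins = length(gm$alleles[[j]]))
  present <- which(ka > 0)
  if (length(present) < 2L)
    return(list(p = 1, logP_obs = 0, method = "monomorphic", B = 0L,
                monomorphic = TRUE, F = NA_real_))
  # re-index to present alleles
  remap <- match(seq_along(ka), present)
  pairs2 <- matrix(remap[pairs], ncol = 2)
  k <- length(present)
  nab <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    a <- min(pairs2[i, ]); b <- max(pairs2[i, ])
    nab[a, b] <- nab[a, b] + 1L
  }
  het_mask <- upper.tri(nab)
  h_obs <- sum(nab[het_mask])
  cnt_obs <- nab[upper.tri(nab, diag = TRUE)]
  s_obs <- h_obs * log(2) - sum(lgamma(nab[upper.tri(nab, diag = TRUE)] + 1))
  ho <- h_obs / n
  p_freq <- ka[present] / (2 * n)
  he <- 1 - sum(p_freq^2)
  Fhat <- if (he > 0) 1 - ho / he else NA_real_
  logP_obs <- lgamma(n + 1) - sum(lgamma(cnt_obs + 1)) +
    sum(lgamma(ka[present] + 1)) - lgamma(2 * n + 1) + h_obs * log(2)

  n_arrays_bound <- choose(n + k * (k + 1) / 2 - 1, k * (k + 1) / 2 - 1)
  if (is.finite(n_arrays_bound) && n_arrays_bound <= enum_limit) {
    const <- lgamma(n + 1) + sum(lgamma(ka[present] + 1)) - lgamma(2 * n + 1)
    tot <- 0; le <- 0
    .hwe_enumerate(ka[present], function(counts, s) {
      pr <- exp(const + s)
      tot <<- tot + pr
      if (s <= s_obs + 1e-9) le <<- le + pr
    })
    return(list(p = le / tot, logP_obs = logP_obs, method = "enumeration",
                B = 0L, monomorphic = FALSE, F = Fhat,
                total_prob = tot))
  }
  hits <- cpp_hwe_mc(as.integer(remap[copies]), k, s_obs, as.integer(B),
                     as.integer(seed))
  list(p = (1 + hits) / (1 + B), logP_obs = logP_obs,
       method = "monte-carlo", B = as.integer(B), monomorphic = FALSE,
       F = Fhat)
}

#' HWE p-values for every (group, locus) cell
#'
#' @inheritParams hwe_test
#' @param alpha family-wise level for the per-group sequential Bonferroni
#'   (Holm) correction across loci.
#' @return data frame with columns `group`, `locus`, `p`, `F`, `method`
#'   and `significant` (Holm-corrected within group).
#' @export
hwe_matrix <- function(gm, B = 10000L, seed = 1L, alpha = 0.05) {
  out <- list()
  i <- 0L
  for (g in unique(gm$group)) for (lc in gm$loci) {
    i <- i + 1L
    rows <- which(gm$group == g & !missing_calls(gm)[, match(lc, gm$loci)])
    if (length(rows) < 2L) next
    r <- hwe_test(gm, g, lc, B = B, seed = seed + i)
    out[[i]] <- data.frame(group = g, locus = lc, p = r$p, F = r$F,
                           method = r$method, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df$significant <- FALSE
  for (g in unique(df$group)) {
    sel <- df$group == g
    df$significant[sel] <- holm_adjust(df$p[sel], alpha)$reject
  }
  rownames(df) <- NULL
  df
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio (G) test of independence on the genotype-class
#' contingency table of two loci, using individuals scored at both;
#' significance by `B` permutations of one locus's genotype column with
#' the add-one p estimator.
#'
#' @param gm a `geno_matrix`.
#' @param group group label.
#' @param loci character vector of two locus names.
#' @param B permutations (>= 100).
#' @param seed integer seed.
#' @return list with `G`, `p`, `B`, `skipped` flag (fewer than 2 genotype
#'   classes at either locus).
#' @export
ld_test <- function(gm, group, loci, B = 999L, seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  stopifnot(length(loci) == 2L)
  j1 <- match(loci[1], gm$loci); j2 <- match(loci[2], gm$loci)
  if (anyNA(c(j1, j2))) stop("unknown locus name")
  mc <- missing_calls(gm)
  rows <- which(gm$group == group & !mc[, j1] & !mc[, j2])
  if (length(rows) < 2L)
    return(list(G = NA_real_, p = NA_real_, B = 0L, skipped = TRUE))
  code <- function(j) {
    x <- paste(gm$tab[rows, 2L * j - 1L], gm$tab[rows, 2L * j])
    as.integer(factor(x))
  }
  x <- code(j1); y <- code(j2)
  nx <- max(x); ny <- max(y)
  if (nx < 2L || ny < 2L)
    return(list(G = NA_real_, p = NA_real_, B = 0L, skipped = TRUE))
  r <- cpp_ld_perm(x, y, nx, ny, as.integer(B), as.integer(seed))
  list(G = r[1], p = (1 + r[2]) / (1 + B), B = as.integer(B),
       skipped = FALSE)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down control of the family-wise error rate: p-values are sorted
#' ascending and `p_(i)` is rejected while `p_(i) <= alpha / (m - i + 1)`;
#' the first failure accepts all larger p-values.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param alpha family-wise level in (0, 1).
#' @return data frame (input order) with `p`, `threshold` (the step-down
#'   bound each p was compared against), `reject` and `p_adj` (Holm
#'   adjusted p-value).
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value list")
  stopifnot(all(pvals > 0 & pvals <= 1), alpha > 0, alpha < 1)
  m <- length(pvals)
  o <- order(pvals)
  thr <- alpha / (m - seq_len(m) + 1)
  rej_sorted <- logical(m)
  ok <- TRUE
  for (i in seq_len(m)) {
    ok <- ok && pvals[o[i]] <= thr[i]
    rej_sorted[i] <- ok
  }
  padj_sorted <- cummax(pmin((m - seq_len(m) + 1) * pvals[o], 1))
  out <- data.frame(p = pvals, threshold = NA_real_, reject = NA,
                    p_adj = NA_real_)
  out$threshold[o] <- thr
  out$reject[o] <- rej_sorted
  out$p_adj[o] <- padj_sorted
  out
}
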