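# build a geno_matrix from per-locus genotype strings, e.g.
# make_gm(list(L1 = c("AB", "AA", NA)), group = c("g1","g1","g1"))
# letters map to allele labels 1, 2, ...
make_gm <- function(loci, group = "g", ids = NULL) {
  n <- length(loci[[1]])
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  a1 <- sapply(loci, function(gs)
    ifelse(is.na(gs), NA_integer_,
           match(substr(gs, 1, 1), LETTERS)))
  a2 <- sapply(loci, function(gs)
    ifelse(is.na(gs), NA_integer_,
           match(substr(gs, 2, 2), LETTERS)))
  if (n == 1L) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  genotype_matrix(ids, group, names(loci), a1, a2)
}

# two drifted demes under the Balding-Nichols construction
two_deme_sim <- function(F = 0.10, n_per_leaf = 50L, n_loci = 15L,
                         alleles = c(15L, 15L), seed = 1L,
                         missing_rate = 0) {
  simulate_demes(sim_config(depth = 1L, F_levels = F, n_loci = n_loci,
                            alleles_per_locus = alleles,
                            n_per_leaf = n_per_leaf,
                            missing_rate = missing_rate, seed = seed))
}

# genotype calls as allele-label matrices (round-trip comparisons must be
# label-based: re-reading a file rebuilds the allele universe from what is
# observed, so indices can shift while calls are identical)
labels_of <- function(gm) {
  do.call(cbind, lapply(seq_len(n_loci(gm)),
                        function(j) hierstock:::.allele_labels(gm, j)))
}

# independent brute-force HWE enumeration oracle: enumerate all ways to
# partition the gene copies into ordered pairs is infeasible; instead
# enumerate genotype arrays by composition search over a small grid.
hwe_enum_oracle <- function(pairs) {
  # pairs: n x 2 matrix of allele indices
  n <- nrow(pairs)
  k <- max(pairs)
  na <- tabulate(as.vector(pairs), nbins = k)
  cats <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cats <- cats[order(cats[, 1], cats[, 2]), , drop = FALSE]
  arrays <- list()
  rec <- function(ci, rem, acc) {
    if (ci > nrow(cats)) {
      if (all(rem == 0)) arrays[[length(arrays) + 1L]] <<- acc
      return()
    }
    a <- cats[ci, 1]; b <- cats[ci, 2]
    hi <- if (a == b) rem[a] %/% 2 else min(rem[a], rem[b])
    for (v in 0:hi) {
      r2 <- rem
      if (a == b) r2[a] <- r2[a] - 2 * v else {
        r2[a] <- r2[a] - v; r2[b] <- r2[b] - v
      }
      rec(ci + 1, r2, c(acc, v))
    }
  }
  rec(1, na, integer(0))
  probs <- vapply(arrays, function(cnt) {
    h <- sum(cnt[cats[, 1] != cats[, 2]])
    exp(lgamma(n + 1) - sum(lgamma(cnt + 1)) + sum(lgamma(na + 1)) -
          lgamma(2 * n + 1) + h * log(2))
  }, 0)
  obs <- integer(nrow(cats))
  for (i in seq_len(n)) {
    a <- min(pairs[i, ]); b <- max(pairs[i, ])
    ci <- which(cats[, 1] == a & cats[, 2] == b)
    obs[ci] <- obs[ci] + 1L
  }
  p_obs <- probs[vapply(arrays, function(x) all(x == obs), TRUE)]
  list(p = sum(probs[probs <= p_obs + 1e-12]), total = sum(probs),
       probs = probs)
}
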