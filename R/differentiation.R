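# per-locus heterozygosity components for a grouping
# returns, for each locus: K (groups with data), harmonic-mean sample size,
# plug-in and Nei-Chesser-corrected H_S / H_T, mean observed heterozygosity
.locus_components <- function(gm, group) {
  L <- n_loci(gm)
  miss <- missing_calls(gm)
  groups <- unique(group)
  out <- vector("list", L)
  for (j in seq_len(L)) {
    A <- length(gm$alleles[[j]])
    hs_k <- ho_k <- n_k <- numeric(0)
    psum <- numeric(A)
    for (g in groups) {
      rows <- which(group == g & !miss[, j])
      if (length(rows) == 0L) next
      v <- c(gm$tab[rows, 2L * j - 1L], gm$tab[rows, 2L * j])
      p <- tabulate(v, nbins = A) / length(v)
      hs_k <- c(hs_k, 1 - sum(p^2))
      ho_k <- c(ho_k, mean(gm$tab[rows, 2L * j - 1L] != gm$tab[rows, 2L * j]))
      n_k <- c(n_k, length(rows))
      psum <- psum + p
    }
    K <- length(n_k)
    if (K < 2L) { out[[j]] <- NULL; next }
    pbar <- psum / K
    Hs <- mean(hs_k)
    Ht <- 1 - sum(pbar^2)
    Ho <- mean(ho_k)
    nh <- K / sum(1 / n_k)
    Hs_hat <- if (nh > 1) nh / (nh - 1) * (Hs - Ho / (2 * nh)) else Hs
    Ht_hat <- Ht + Hs_hat / (nh * K) - Ho / (2 * nh * K)
    out[[j]] <- list(K = K, n_harm = nh, Hs = Hs, Ht = Ht, Ho = Ho,
                     Hs_hat = Hs_hat, Ht_hat = Ht_hat)
  }
  out
}

# D and G''ST from heterozygosity components
.dg_from_h <- function(Hs, Ht, K) {
  D <- if (1 - Hs > 0) (K / (K - 1)) * (Ht - Hs) / (1 - Hs) else 0
  denom <- (K * Ht - Hs) * (1 - Hs)
  G <- if (denom != 0) K * (Ht - Hs) / denom else 0
  c(D = D, Gppst = G)
}

# multi-locus D/G''ST for a grouping over a subset of loci (index resample)
.multilocus_dg <- function(comp, loci_idx, mode) {
  comp <- comp[loci_idx]
  comp <- comp[!vapply(comp, is.null, TRUE)]
  if (length(comp) == 0L) return(c(D = NA_real_, Gppst = NA_real_))
  Hs <- mean(vapply(comp, function(x)
    if (mode == "nei_chesser") x$Hs_hat else x$Hs, 0))
  Ht <- mean(vapply(comp, function(x)
    if (mode == "nei_chesser") x$Ht_hat else x$Ht, 0))
  K <- max(vapply(comp, function(x) x$K, 0))
  .dg_from_h(Hs, Ht, K)
}

#' Among-group differentiation: Jost's D and Hedrick's G''ST
#'
#' Per-locus and multi-locus differentiation with resampling uncertainty.
#' With `K` groups and within/total heterozygosity components `H_S`,
#' `H_T`: `D = (K/(K-1)) (H_T - H_S) / (1 - H_S)` and
#' `G''ST = K (H_T - H_S) / ((K H_T - H_S)(1 - H_S))`. The default
#' estimator applies the Nei-Chesser small-sample correction with the
#' harmonic-mean sample size; `mode = "plugin"` uses raw frequency
#' estimates (useful for closed-form checks). Multi-locus values combine
#' across-locus mean `H_S` and `H_T`. Uncertainty: delete-one-locus
#' jackknife SE, percentile bootstrap CI over loci, and a permutation test
#' shuffling group labels of individuals.
#'
#' @param gm a `geno_matrix`.
#' @param group grouping vector (defaults to stored labels).
#' @param mode `"nei_chesser"` (default) or `"plugin"`.
#' @param n_perm label permutations for the p-value (0 disables).
#' @param n_boot bootstrap resamples of loci for the 95% CI (0 disables).
#' @param seed integer seed.
#' @return list of class `diff_stats`: `per_locus` data frame, `multilocus`
#'   named vector, `jackknife_se`, `boot_ci` (2 x 2), `perm_p`, `K`,
#'   `mode`.
#' @export
diff_stats <- function(gm, group = gm$group, mode = c("nei_chesser", "plugin"),
                       n_perm = 999L, n_boot = 999L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(group) == n_ind(gm))
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  set.seed(seed)
  L <- n_loci(gm)
  comp <- .locus_components(gm, group)
  usable <- which(!vapply(comp, is.null, TRUE))
  if (length(usable) == 0L) stop("no locus has data in >= 2 groups")
  per <- t(vapply(usable, function(j) {
    x <- comp[[j]]
    if (mode == "nei_chesser") .dg_from_h(x$Hs_hat, x$Ht_hat, x$K)
    else .dg_from_h(x$Hs, x$Ht, x$K)
  }, c(D = 0, Gppst = 0)))
  per_df <- data.frame(locus = gm$loci[usable], D = per[, "D"],
                       Gppst = per[, "Gppst"])
  multi <- .multilocus_dg(comp, usable, mode)

  # delete-one-locus jackknife
  jk <- if (length(usable) > 1L) {
    mat <- t(vapply(seq_along(usable), function(d)
      .multilocus_dg(comp, usable[-d], mode), c(D = 0, Gppst = 0)))
    nl <- length(usable)
    apply(mat, 2, function(v) sqrt((nl - 1) / nl * sum((v - mean(v))^2)))
  } else c(D = 0, Gppst = 0)

  boot_ci <- NULL
  if (n_boot > 0 && length(usable) > 1L) {
    bs <- t(vapply(seq_len(n_boot), function(b)
      .multilocus_dg(comp, sample(usable, length(usable), replace = TRUE),
                     mode), c(D = 0, Gppst = 0)))
    boot_ci <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975),
                     na.rm = TRUE)
  }

  perm_p <- NULL
  if (n_perm > 0) {
    hits <- c(D = 0, Gppst = 0)
    for (b in seq_len(n_perm)) {
      gperm <- sample(group)
      mp <- .multilocus_dg(.locus_components(gm, gperm),
                           seq_len(L), mode)
      hits <- hits + (mp >= multi - 1e-12)
    }
    perm_p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(per_locus = per_df, multilocus = multi,
                 jackknife_se = jk, boot_ci = boot_ci, perm_p = perm_p,
                 K = length(unique(group)), mode = mode),
            class = "diff_stats")
}

#' @export
print.diff_stats <- function(x, ...) {
  cat(sprintf("Differentiation over %d loci, K = %d groups (%s estimator)\n",
              nrow(x$per_locus), x$K, x$mode))
  cat(sprintf("  Jost's D = %.4f (jackknife SE %.4f)\n",
              x$multilocus["D"], x$jackknife_se["D"]))
  cat(sprintf("  G''ST    = %.4f (jackknife SE %.4f)\n",
              x$multilocus["Gppst"], x$jackknife_se["Gppst"]))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation p: D %.4g, G''ST %.4g\n",
                x$perm_p["D"], x$perm_p["Gppst"]))
  invisible(x)
}

#' Pairwise squared genotype distances
#'
#' Codominant allele-count metric: per locus
#' `d^2 = 0.5 * sum_a (c1_a - c2_a)^2` with `c` the 0/1/2 allele-count
#' vector of a call, giving the familiar 0/1/2/3/4 values; the multi-locus
#' distance sums observed loci and rescales by `L / L_obs` for
#' pairwise-complete loci.
#'
#' @param gm a `geno_matrix`.
#' @return n x n numeric matrix of squared distances.
#' @export
genotype_dist <- function(gm) {
  enc <- .gmat(gm)
  D <- cpp_pair_dist(enc$G, enc$A)
  if (any(D < 0)) {
    bad <- which(D < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("individuals %s and %s share no scored locus",
                 gm$ind_id[bad[1]], gm$ind_id[bad[2]]))
  }
  dimnames(D) <- list(gm$ind_id, gm$ind_id)
  D
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared genotype distances within and among groups:
#' `SS_total = sum_{i<j} d2_ij / N`, `SS_within = sum_g sum_{i<j in g}
#' d2_ij / n_g`, mean squares from `df_among = P - 1`,
#' `df_within = N - P`, variance components
#' `sigma2_within = MS_within`,
#' `sigma2_among = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum n_g^2 / N) / (P - 1)`, and
#' `phi_ST = sigma2_among / (sigma2_among + sigma2_within)` (raw value
#' reported; flooring at 0 only affects the percent display).
#' Significance by permutation of group labels.
#'
#' @param gm a `geno_matrix`.
#' @param group grouping vector.
#' @param n_perm label permutations (0 disables the test).
#' @param seed integer seed.
#' @return list of class `amova`: `phi_st`, `sigma2` (among/within),
#'   `ss`, `ms`, `df`, `percent`, `p`.
#' @export
amova <- function(gm, group = gm$group, n_perm = 999L, seed = 1L) {
  stopifnot(length(group) == n_ind(gm))
  sizes <- table(group)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 individuals")
  N <- n_ind(gm)
  P <- length(sizes)
  D <- genotype_dist(gm)

  phi_of <- function(grp) {
    ss_total <- sum(D[upper.tri(D)]) / N
    ss_within <- 0
    for (g in unique(grp)) {
      idx <- which(grp == g)
      ss_within <- ss_within +
        sum(D[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    ms_among <- ss_among / (P - 1)
    ms_within <- ss_within / (N - P)
    n0 <- (N - sum(table(grp)^2) / N) / (P - 1)
    s2w <- ms_within
    s2a <- (ms_among - ms_within) / n0
    phi <- if (abs(s2a) + abs(s2w) < 1e-300) 0 else s2a / (s2a + s2w)
    list(phi = phi, s2a = s2a, s2w = s2w,
         ss = c(among = ss_among, within = ss_within, total = ss_total),
         ms = c(among = ms_among, within = ms_within))
  }
  obs <- phi_of(group)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0
    for (b in seq_len(n_perm))
      if (phi_of(sample(group))$phi >= obs$phi - 1e-12) hits <- hits + 1
    p <- (1 + hits) / (1 + n_perm)
  }
  s2a_disp <- max(obs$s2a, 0)
  pct <- c(among = 100 * s2a_disp / (s2a_disp + obs$s2w),
           within = 100 * obs$s2w / (s2a_disp + obs$s2w))
  structure(list(phi_st = obs$phi,
                 sigma2 = c(among = obs$s2a, within = obs$s2w),
                 ss = obs$ss, ms = obs$ms,
                 df = c(among = P - 1L, within = N - P),
                 percent = pct, p = p, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("Two-level AMOVA on squared genotype distances\n")
  cat(sprintf("  phi_ST = %.4f  (p = %s, %d permutations)\n", x$phi_st,
              format(x$p, digits = 3), x$n_perm))
  cat(sprintf("  variance among %.4f (%.1f%%), within %.4f (%.1f%%)\n",
              x$sigma2["among"], x$percent["among"],
              x$sigma2["within"], x$percent["within"]))
  invisible(x)
}
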