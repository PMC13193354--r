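test_that("plug-in D and G''ST hit their closed-form limits", {
  # complete differentiation: groups fixed for different alleles
  gm <- make_gm(list(L1 = c("AA", "AA", "BB", "BB")),
                group = c("g1", "g1", "g2", "g2"))
  d <- diff_stats(gm, mode = "plugin", n_perm = 0, n_boot = 0)
  expect_equal(unname(d$multilocus["D"]), 1)
  expect_equal(unname(d$multilocus["Gppst"]), 1)

  # identical frequencies: zero differentiation
  gm0 <- make_gm(list(L1 = c("AB", "AB", "AB", "AB")),
                 group = c("g1", "g1", "g2", "g2"))
  d0 <- diff_stats(gm0, mode = "plugin", n_perm = 0, n_boot = 0)
  expect_equal(unname(d0$multilocus["D"]), 0)
  expect_equal(unname(d0$multilocus["Gppst"]), 0)
})

test_that("the 0.8/0.2 two-group worked example reproduces by hand", {
  # 5 individuals per group: p = (0.8, 0.2) vs (0.2, 0.8)
  gm <- make_gm(list(L1 = c("AA", "AA", "AA", "AB", "AB",
                            "BB", "BB", "BB", "AB", "AB")),
                group = rep(c("g1", "g2"), each = 5))
  d <- diff_stats(gm, mode = "plugin", n_perm = 0, n_boot = 0)
  # H_S = 0.32, H_T = 0.5
  expect_equal(unname(d$multilocus["D"]), 0.36 / 0.68, tolerance = 1e-9)
  expect_equal(unname(d$multilocus["Gppst"]),
               2 * 0.18 / ((2 * 0.5 - 0.32) * 0.68), tolerance = 1e-9)
  expect_equal(unname(d$multilocus["D"]), 0.5294, tolerance = 1e-4)
  expect_equal(unname(d$multilocus["Gppst"]), 0.7785, tolerance = 1e-4)
})

test_that("squared genotype distances reproduce the codominant table", {
  gm <- make_gm(list(L1 = c("AB", "AB", "AA", "BB", "BC", "CD", "AC")))
  D <- genotype_dist(gm)
  expect_equal(D["i1", "i2"], 0)   # AB vs AB
  expect_equal(D["i3", "i4"], 4)   # AA vs BB
  expect_equal(D["i3", "i5"], 3)   # AA vs BC
  expect_equal(D["i1", "i6"], 2)   # AB vs CD
  expect_equal(D["i3", "i1"], 1)   # AA vs AB
  expect_equal(D["i1", "i7"], 1)   # AB vs AC
  expect_equal(D["i3", "i3"], 0)   # AA vs AA
})

test_that("pairs without shared loci are rejected, others rescaled", {
  a1 <- matrix(c(1, NA, 1, NA), 2, 2)
  gm <- genotype_matrix(c("x", "y"), "g", c("L1", "L2"), a1, a1)
  expect_error(genotype_dist(gm), "share no scored locus")

  # one shared locus of two: distance rescaled by L / L_obs = 2
  a1 <- matrix(c(1, 1, 1, NA), 2, 2)
  a2 <- matrix(c(1, 2, 1, NA), 2, 2)
  gm2 <- genotype_matrix(c("x", "y"), "g", c("L1", "L2"), a1, a2)
  expect_equal(unname(genotype_dist(gm2)["x", "y"]), 1 * 2)
})

test_that("AMOVA matches the hand-worked fixed-group example", {
  gm <- make_gm(list(L1 = c("AA", "AA", "BB", "BB")),
                group = c("g1", "g1", "g2", "g2"))
  a <- amova(gm, n_perm = 0)
  expect_equal(unname(a$ss["total"]), 4)
  expect_equal(unname(a$ss["within"]), 0)
  expect_equal(a$phi_st, 1)
  expect_equal(unname(a$df), c(1L, 2L))

  # all individuals identical: no variance anywhere
  gm0 <- make_gm(list(L1 = rep("AB", 6)), group = rep(c("a", "b"), 3))
  a0 <- amova(gm0, n_perm = 99)
  expect_equal(a0$phi_st, 0)
  expect_gt(a0$p, 0.5)
})

test_that("AMOVA equals brute-force variance components to 1e-10", {
  # oracle route: embed genotypes as allele-count vectors x = c / sqrt(2),
  # where squared Euclidean distance equals the codominant d2, and compute
  # sums of squares from group means instead of pairwise distances
  brute <- function(gm, group) {
    X <- NULL
    for (j in seq_len(n_loci(gm))) {
      A <- length(gm$alleles[[j]])
      M <- matrix(0, n_ind(gm), A)
      for (i in seq_len(n_ind(gm))) {
        M[i, gm$tab[i, 2 * j - 1]] <- M[i, gm$tab[i, 2 * j - 1]] + 1
        M[i, gm$tab[i, 2 * j]] <- M[i, gm$tab[i, 2 * j]] + 1
      }
      X <- cbind(X, M / sqrt(2))
    }
    N <- nrow(X); P <- length(unique(group))
    ss_t <- sum(sweep(X, 2, colMeans(X))^2)
    ss_w <- 0
    for (g in unique(group)) {
      Xi <- X[group == g, , drop = FALSE]
      ss_w <- ss_w + sum(sweep(Xi, 2, colMeans(Xi))^2)
    }
    ms_a <- (ss_t - ss_w) / (P - 1); ms_w <- ss_w / (N - P)
    n0 <- (N - sum(table(group)^2) / N) / (P - 1)
    s2a <- (ms_a - ms_w) / n0
    s2a / (s2a + ms_w)
  }
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    grp <- sample(c("a", "b", "c"), n, TRUE)
    while (min(table(grp)) < 2 || length(unique(grp)) < 2)
      grp <- sample(c("a", "b", "c"), n, TRUE)
    L <- sample(2:4, 1)
    a1 <- matrix(sample.int(4, n * L, TRUE), n, L)
    a2 <- matrix(sample.int(4, n * L, TRUE), n, L)
    gm <- genotype_matrix(paste0("i", 1:n), grp, paste0("L", 1:L), a1, a2)
    got <- amova(gm, n_perm = 0)
    expect_equal(got$phi_st, brute(gm, grp), tolerance = 1e-10)
  }
})

test_that("AMOVA permutation p is well calibrated under panmixia", {
  set.seed(14)
  rej <- 0L
  ntrial <- 60L
  for (s in seq_len(ntrial)) {
    sim <- simulate_demes(sim_config(depth = 0, F_levels = numeric(0),
                                     n_loci = 5L, n_per_leaf = 24L,
                                     alleles_per_locus = c(5L, 8L),
                                     missing_rate = 0, seed = 7000 + s))
    grp <- rep(c("x", "y"), each = 12)
    a <- amova(sim$genotypes, group = grp, n_perm = 99, seed = s)
    if (a$p <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej, qbinom(0.999, ntrial, 0.05) + 1L)
})

test_that("D and G''ST ignore allele labels and group order", {
  sim <- two_deme_sim(n_per_leaf = 20L, n_loci = 5L, seed = 44)
  gm <- sim$genotypes
  d1 <- diff_stats(gm, n_perm = 0, n_boot = 0)
  # relabel alleles (reverse each locus universe)
  gm2 <- gm
  for (j in seq_len(n_loci(gm))) {
    A <- length(gm$alleles[[j]])
    newidx <- A + 1L - gm$tab[, c(2 * j - 1, 2 * j)]
    gm2$tab[, 2 * j - 1] <- pmin(newidx[, 1], newidx[, 2])
    gm2$tab[, 2 * j] <- pmax(newidx[, 1], newidx[, 2])
  }
  d2 <- diff_stats(gm2, n_perm = 0, n_boot = 0)
  expect_equal(d1$multilocus, d2$multilocus)
  # reverse individual order (groups swap order too)
  gm3 <- subset_ind(gm, rev(seq_len(n_ind(gm))))
  d3 <- diff_stats(gm3, n_perm = 0, n_boot = 0)
  expect_equal(d1$multilocus, d3$multilocus)
})

test_that("locus resampling gives positive SE and covering CIs", {
  sim <- two_deme_sim(F = 0.08, n_per_leaf = 25L, seed = 55)
  d <- diff_stats(sim$genotypes, n_perm = 0, n_boot = 499, seed = 2)
  expect_true(all(d$jackknife_se > 0))
  # point estimate inside its own bootstrap CI here
  expect_true(d$boot_ci[1, "D"] <= d$multilocus["D"] &&
                d$multilocus["D"] <= d$boot_ci[2, "D"])
  covered <- 0L
  for (s in 1:15) {
    si <- two_deme_sim(F = 0.08, n_per_leaf = 15L, n_loci = 10L,
                       seed = 600 + s)
    di <- diff_stats(si$genotypes, n_perm = 0, n_boot = 199, seed = s)
    if (di$boot_ci[1, "Gppst"] <= di$multilocus["Gppst"] &&
        di$multilocus["Gppst"] <= di$boot_ci[2, "Gppst"])
      covered <- covered + 1L
  }
  expect_gte(covered, 13L)
})

test_that("plug-in GST rises with the generating drift level", {
  means <- vapply(c(0.02, 0.05, 0.10, 0.20), function(Fd) {
    mean(vapply(1:12, function(s) {
      sim <- two_deme_sim(F = Fd, n_per_leaf = 30L, n_loci = 8L,
                          seed = round(1000 * Fd) + s)
      comp <- hierstock:::.locus_components(sim$genotypes,
                                            sim$genotypes$group)
      mean(vapply(comp, function(x) (x$Ht - x$Hs) / x$Ht, 0))
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})
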