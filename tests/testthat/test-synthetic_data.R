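test_that("the generator is deterministic and its truth is coherent", {
  cfg <- sim_config(n_per_leaf = 8L, seed = 11L)
  s1 <- simulate_demes(cfg)
  s2 <- simulate_demes(cfg)
  expect_identical(s1$genotypes$tab, s2$genotypes$tab)
  expect_identical(s1$truth$leaf, s2$truth$leaf)

  expect_equal(unname(rowSums(s1$truth$Q)), rep(1, n_ind(s1$genotypes)))
  expect_equal(ncol(s1$truth$Q), 8L)                 # 2^depth leaves
  # pure mode: one-hot Q consistent with leaf labels
  expect_true(all(s1$truth$Q %in% c(0, 1)))
  expect_equal(colnames(s1$truth$Q)[apply(s1$truth$Q, 1, which.max)],
               s1$truth$leaf)
})

test_that("depth 0 gives a panmictic deme with near-zero inbreeding", {
  sim <- simulate_demes(sim_config(depth = 0, F_levels = numeric(0),
                                   n_per_leaf = 200L, missing_rate = 0,
                                   seed = 21))
  div <- diversity_stats(sim$genotypes)
  fhat <- div$F[div$locus == "over loci"]
  expect_lt(abs(fhat), 0.05)
})

test_that("vanishing drift keeps leaf frequencies at the ancestor", {
  # F -> 0 limit: expected per-allele deviation scales with sqrt(F), so
  # the mean L1 sibling distance must shrink by ~sqrt(F_hi/F_lo) and be
  # small in absolute terms at F = 0.001
  dist_at <- function(F, seed) {
    sim <- simulate_demes(sim_config(depth = 1, F_levels = F,
                                     dirichlet_theta = 1, n_per_leaf = 2L,
                                     alleles_per_locus = c(15L, 15L),
                                     missing_rate = 0, seed = seed))
    lf <- sim$truth$leaf_freq
    mean(vapply(seq_along(lf[[1]]), function(j)
      sum(abs(lf[[1]][[j]] - lf[[2]][[j]])), 0))
  }
  lo <- mean(vapply(1:10, function(s) dist_at(0.001, 30 + s), 0))
  hi <- mean(vapply(1:10, function(s) dist_at(0.1, 30 + s), 0))
  expect_lt(lo, 0.15)
  expect_lt(lo, hi / 4)   # ~sqrt(100)-fold F drop, allow wide slack
})

test_that("realised two-deme GST matches a Monte-Carlo drift oracle", {
  # oracle: draw ancestral p ~ Dir(1), two children by the same Dirichlet
  # drift construction, and compute the plug-in GST of the true
  # frequencies; average over many replicate draws
  Fd <- 0.10
  set.seed(99)
  oracle <- replicate(300, {
    g <- 0
    for (j in 1:5) {
      p <- rgamma(15, 1); p <- p / sum(p)
      c1 <- rgamma(15, p * (1 - Fd) / Fd); c1 <- c1 / sum(c1)
      c2 <- rgamma(15, p * (1 - Fd) / Fd); c2 <- c2 / sum(c2)
      Hs <- mean(c(1 - sum(c1^2), 1 - sum(c2^2)))
      Ht <- 1 - sum(((c1 + c2) / 2)^2)
      g <- g + (Ht - Hs) / Ht / 5
    }
    g
  })
  # implementation: replicate simulations at n = 500/leaf, plug-in GST of
  # sample frequencies via the differentiation module's components
  got <- vapply(1:50, function(s) {
    sim <- two_deme_sim(F = Fd, n_per_leaf = 500L, n_loci = 5L, seed = s)
    comp <- hierstock:::.locus_components(sim$genotypes, sim$genotypes$group)
    mean(vapply(comp, function(x) (x$Ht - x$Hs) / x$Ht, 0))
  }, 0)
  expect_lt(abs(mean(got) - mean(oracle)), 0.03)
})

test_that("siblings are less differentiated than cousins (nestedness)", {
  wins <- 0L
  for (s in 1:30) {
    sim <- simulate_demes(sim_config(depth = 2, F_levels = c(0.08, 0.08),
                                     n_loci = 8L, n_per_leaf = 5L,
                                     missing_rate = 0, seed = 400 + s))
    lf <- sim$truth$leaf_freq
    gst <- function(i, j) {
      v <- vapply(seq_along(lf[[i]]), function(l) {
        c1 <- lf[[i]][[l]]; c2 <- lf[[j]][[l]]
        Hs <- mean(c(1 - sum(c1^2), 1 - sum(c2^2)))
        Ht <- 1 - sum(((c1 + c2) / 2)^2)
        (Ht - Hs) / Ht
      }, 0)
      mean(v)
    }
    sib <- mean(c(gst(1, 2), gst(3, 4)))
    cousin <- mean(c(gst(1, 3), gst(1, 4), gst(2, 3), gst(2, 4)))
    if (sib < cousin) wins <- wins + 1L
  }
  expect_gt(wins, 20L)   # clear majority over 30 replicates
})

test_that("missing-data injection hits the target rate and is seeded", {
  sim <- simulate_demes(sim_config(n_per_leaf = 18L, missing_rate = 0,
                                   seed = 5))
  gm <- sim$genotypes
  expect_identical(inject_missing(gm, 0), gm)
  rate <- 0.186
  out <- inject_missing(gm, rate, seed = 8)
  ncalls <- n_ind(gm) * n_loci(gm)
  obs <- mean(missing_calls(out))
  sd3 <- 3 * sqrt(rate * (1 - rate) / ncalls)
  expect_lt(abs(obs - rate), sd3)
  expect_identical(inject_missing(gm, rate, seed = 8)$tab, out$tab)
  expect_error(inject_missing(gm, 1), "< 1")
})

test_that("pooling locations relabels without touching genotypes", {
  sim <- two_deme_sim(F = 0.15, n_per_leaf = 30L, seed = 17)
  leaves <- unique(sim$truth$leaf)
  # one location covering one leaf: labels change, genotypes unchanged
  mp1 <- list(locX = list(leaves = leaves[1], weights = 1))
  out <- pool_locations(sim$genotypes, sim$truth, mp1, seed = 2)
  expect_identical(out$tab, sim$genotypes$tab)
  expect_true(all(out$group[sim$truth$leaf == leaves[1]] == "locX"))
  expect_true(all(out$group[sim$truth$leaf == leaves[2]] == leaves[2]))

  # pooling two copies of the same leaf: no substructure, F stays near 0
  mpsame <- list(locA = list(leaves = leaves[1], weights = 1),
                 locB = list(leaves = leaves[1], weights = 1))
  gm1 <- subset_ind(sim$genotypes, sim$truth$leaf == leaves[1])
  tr1 <- sim$truth; keep <- tr1$leaf == leaves[1]
  tr1$ind_id <- tr1$ind_id[keep]; tr1$leaf <- tr1$leaf[keep]
  pooled_same <- pool_locations(gm1, tr1, mpsame, seed = 3)
  div <- diversity_stats(pooled_same, group = rep("all", n_ind(pooled_same)))
  expect_lt(abs(div$F[div$locus == "over loci"]), 0.06)

  expect_error(pool_locations(sim$genotypes, sim$truth,
                              list(l = list(leaves = "nope", weights = 1))),
               "unknown leaf")
})

test_that("pooling differentiated demes produces a Wahlund deficit", {
  sim <- two_deme_sim(F = 0.15, n_per_leaf = 40L, seed = 23)
  pooled <- subset_ind(sim$genotypes, TRUE,
                       group = rep("pool", n_ind(sim$genotypes)))
  div <- diversity_stats(pooled)
  # Balding-Nichols pooling: E[F-hat] = (F/2)/(1 - F/2) ~ 0.08
  expect_gt(div$F[div$locus == "over loci"], 0.03)
  hw <- hwe_matrix(pooled, B = 2000L, seed = 5)
  # rejection far above the 5% null rate; deficits dominate the hits
  expect_gte(mean(hw$p < 0.05), 0.4)
  expect_gte(mean(hw$F[hw$significant] > 0), 0.75)
})
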