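test_that("K = 1 mixture likelihood equals the closed form", {
  sim <- two_deme_sim(n_per_leaf = 12L, n_loci = 4L, seed = 3,
                      missing_rate = 0.1)
  gm <- sim$genotypes
  fit <- fit_mixture(gm, 1L, seed = 1)
  # independent closed form: global smoothed frequencies
  beta <- 0.5
  ll <- 0
  for (j in seq_len(n_loci(gm))) {
    v <- c(gm$tab[, 2 * j - 1], gm$tab[, 2 * j])
    v <- v[!is.na(v)]
    cnt <- tabulate(v, nbins = length(gm$alleles[[j]]))
    ll <- ll + sum(cnt * (log(cnt + beta) -
                            log(length(v) + beta * length(cnt))))
  }
  expect_equal(fit$logL, ll, tolerance = 1e-9)
  expect_true(all(fit$Q == 1))
})

test_that("fixed-difference groups split perfectly at K = 2", {
  # every locus fixed A in group1, B in group2
  n <- 20L
  loci <- lapply(1:5, function(j) rep(c("AA", "BB"), each = n))
  names(loci) <- paste0("L", 1:5)
  gm <- make_gm(loci, group = rep(c("g1", "g2"), each = n))
  mix <- fit_mixture(gm, 2L, seed = 7)
  expect_equal(length(unique(mix$z[1:n])), 1L)
  expect_equal(length(unique(mix$z[(n + 1):(2 * n)])), 1L)
  expect_true(mix$z[1] != mix$z[n + 1])
  # with beta -> 0 the profiled likelihood approaches 0 at fixation
  tiny <- fit_mixture(gm, 2L, seed = 7, beta = 1e-8)
  expect_gt(tiny$logL, -1e-4)

  adm <- fit_admixture(gm, 2L, init = mix, tol = 1e-10, max_iter = 2000L)
  expect_true(all(abs(apply(adm$Q, 1, max) - 1) < 1e-3))
})

test_that("fit_mixture validates K and flags empty clusters", {
  gm <- make_gm(list(L1 = c("AB", "AB", "AA")))
  expect_error(fit_mixture(gm, 4L), "exceeds")
  fit <- fit_mixture(gm, 3L, seed = 2)
  expect_true(is.integer(attr(fit, "empty_clusters")))
})

test_that("admixture likelihood evaluates the textbook single-call case", {
  # one individual, one locus, genotype AA, K = 1, p_A = 0.25
  G <- matrix(c(1L, 1L), 1, 2)
  Q <- matrix(1, 1, 1)
  P <- matrix(c(0.25, 0.75), 2, 1)
  ll <- hierstock:::cpp_admix_loglik(G, 2L, Q, P)
  expect_equal(ll, 2 * log(0.25), tolerance = 1e-9)
})

test_that("EM is monotone and keeps Q and P on their simplices", {
  set.seed(8)
  worst <- 0
  for (rep in 1:25) {
    n <- sample(8:25, 1)
    L <- sample(2:6, 1)
    K <- sample(2:3, 1)
    a1 <- matrix(sample.int(5, n * L, TRUE), n, L)
    a2 <- matrix(sample.int(5, n * L, TRUE), n, L)
    if (runif(1) < 0.3) a1[sample(n * L, 3)] <- NA
    gm <- genotype_matrix(paste0("i", 1:n), "g", paste0("L", 1:L), a1, a2)
    fit <- fit_admixture(gm, K, init = "random", tol = 1e-9,
                         max_iter = 150L, seed = rep)
    worst <- min(worst, min(diff(fit$trace)))
    expect_equal(unname(rowSums(fit$Q)), rep(1, n), tolerance = 1e-9)
    off <- c(0L, cumsum(vapply(gm$alleles, length, 1L)))
    for (l in seq_len(L)) {
      blk <- fit$P[(off[l] + 1):off[l + 1], , drop = FALSE]
      expect_equal(unname(colSums(blk)), rep(1, K), tolerance = 1e-9)
    }
    expect_lte(fit$logL, 0)
  }
  expect_gte(worst, -1e-8)
})

test_that("cluster labels are exchangeable", {
  sim <- two_deme_sim(n_per_leaf = 15L, seed = 10)
  gm <- sim$genotypes
  fit <- fit_admixture(gm, 3L, init = "random", seed = 5)
  enc <- hierstock:::.gmat(gm)
  perm <- c(3L, 1L, 2L)
  ll1 <- hierstock:::cpp_admix_loglik(enc$G, enc$A, fit$Q, fit$P)
  ll2 <- hierstock:::cpp_admix_loglik(enc$G, enc$A,
                                      fit$Q[, perm], fit$P[, perm])
  expect_equal(ll1, ll2, tolerance = 1e-10)
  expect_equal(ll1, fit$logL, tolerance = 1e-6)
})

test_that("annealing never ends below its initial state", {
  sim <- two_deme_sim(n_per_leaf = 10L, seed = 20, missing_rate = 0.15)
  enc <- hierstock:::.gmat(sim$genotypes)
  for (s in 1:5) {
    set.seed(s)
    z0 <- sample.int(3L, n_ind(sim$genotypes), TRUE)
    init_ll <- hierstock:::.profile_loglik(enc, z0, 3L)
    r <- hierstock:::cpp_mix_anneal(enc$G, enc$A, 3L, as.integer(z0),
                                    50L, 0.9, 0.5, 5L, s)
    expect_gte(r$logL, init_ll - 1e-9)
  }
})

test_that("the curvature criterion picks K from the worked arithmetic", {
  # replicate log-likelihood families with zero spread
  L <- c(-1000, -900, -890, -885)
  scan <- structure(list(logL = rbind(L, L), best_fits = vector("list", 4),
                         k_max = 4L, R = 2L, seed = 1L),
                    class = "k_scan")
  sel <- select_k(scan)
  # unnormalised curvatures: K2 -> 90, K3 -> 5; zero SD floored at 1e-3
  expect_equal(sel$table$D_LK2[2], 90 / 1e-3)
  expect_equal(sel$table$D_LK2[3], 5 / 1e-3)
  expect_equal(sel$chosen_k, 2L)
  expect_equal(sel$flag, "ok")

  # strictly linear likelihood: no curvature, fall back with a flag
  Lin <- c(-1000, -900, -800, -700)
  scan2 <- structure(list(logL = rbind(Lin, Lin),
                          best_fits = vector("list", 4),
                          k_max = 4L, R = 2L, seed = 1L),
                     class = "k_scan")
  sel2 <- select_k(scan2)
  expect_equal(sel2$flag, "no_curvature")
  expect_equal(sel2$chosen_k, 1L)
})

test_that("panmixia test: maximal separation and degenerate data", {
  n <- 20L
  loci <- lapply(1:5, function(j) rep(c("AA", "BB"), each = n))
  names(loci) <- paste0("L", 1:5)
  gm <- make_gm(loci, group = "g")
  r <- panmixia_test(gm, R = 2L, B = 19L, seed = 1)
  expect_equal(r$p, 1 / 20)

  # identical genotypes for everyone: no clustering gain at all
  gm0 <- make_gm(list(L1 = rep("AB", 12), L2 = rep("AA", 12)))
  r0 <- panmixia_test(gm0, R = 2L, B = 19L, seed = 2)
  expect_lt(abs(r0$delta_logL), 1e-6)
  expect_gt(r0$p, 0.9)

  expect_error(panmixia_test(make_gm(list(L1 = rep("AB", 5))), B = 19L),
               "at least 10")
  expect_error(panmixia_test(gm, B = 5L), "B must")
})

test_that("admixed individuals are distinguishable from pure ones", {
  # pure members of two demes at F = 0.15 plus exact 50/50 (F1) hybrids
  # drawn from the same leaf frequencies; fit jointly at K = 2
  hi_pure <- hi_adm <- numeric(0)
  for (s in 1:6) {
    sim <- two_deme_sim(F = 0.15, n_per_leaf = 30L, seed = 3000 + s)
    lf <- sim$truth$leaf_freq
    L <- 15L
    set.seed(s)
    n_hyb <- 15L
    h1 <- h2 <- matrix(NA_integer_, n_hyb, L)
    for (j in seq_len(L)) {
      h1[, j] <- sample.int(length(lf[[1]][[j]]), n_hyb, TRUE,
                            prob = lf[[1]][[j]])
      h2[, j] <- sample.int(length(lf[[2]][[j]]), n_hyb, TRUE,
                            prob = lf[[2]][[j]])
    }
    gm0 <- sim$genotypes
    a1 <- rbind(do.call(cbind, lapply(seq_len(L), function(j)
      gm0$alleles[[j]][gm0$tab[, 2 * j - 1]])), h1)
    a2 <- rbind(do.call(cbind, lapply(seq_len(L), function(j)
      gm0$alleles[[j]][gm0$tab[, 2 * j]])), h2)
    ids <- c(gm0$ind_id, paste0("hyb", seq_len(n_hyb)))
    grp <- c(gm0$group, rep("hyb", n_hyb))
    gm <- genotype_matrix(ids, grp, gm0$loci, a1, a2)
    fit <- fit_admixture(gm, 2L, init = fit_mixture(gm, 2L, seed = s),
                         seed = s, tol = 1e-6, max_iter = 1000L)
    mx <- apply(fit$Q, 1, max)
    hi_pure <- c(hi_pure, mean(mx[grp != "hyb"]))
    hi_adm <- c(hi_adm, mean(mx[grp == "hyb"]))
  }
  expect_gte(mean(hi_pure), 0.95)
  expect_lte(mean(hi_adm), 0.8)
})
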