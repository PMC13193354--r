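# assemble an admix_fit object; P is a totA x K matrix in per-locus blocks
.new_admix_fit <- function(gm, K, Q, P, logL, model, seed, iterations,
                           converged, z = NULL) {
  rownames(Q) <- gm$ind_id
  colnames(Q) <- paste0("cluster", seq_len(K))
  structure(list(K = K, Q = Q, P = P, logL = logL, model = model,
                 seed = seed, iterations = iterations,
                 converged = converged, z = z,
                 loci = gm$loci, alleles = gm$alleles),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit (%s model): K = %d, n = %d, logL = %.2f\n",
              x$model, x$K, nrow(x$Q), x$logL))
  if (!is.null(x$z))
    cat("  cluster sizes:", paste(tabulate(x$z, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$logL, df = NA, class = "logLik")
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
plot.admix_fit <- function(x, ...) {
  graphics::barplot(t(x$Q), col = grDevices::grey.colors(x$K),
                    border = NA, space = 0, las = 2,
                    cex.names = 0.5, ylab = "ancestry fraction", ...)
  invisible(x)
}

# cluster-wise frequency MLE with pseudo-count beta, as totA x K matrix
.profile_freqs <- function(enc, z, K, beta = 0.5) {
  A <- enc$A
  off <- c(0L, cumsum(A))
  P <- matrix(0, sum(A), K)
  n <- nrow(enc$G)
  for (k in seq_len(K)) {
    rows <- which(z == k)
    for (l in seq_along(A)) {
      v <- c(enc$G[rows, 2L * l - 1L], enc$G[rows, 2L * l])
      v <- v[v > 0L]
      cnt <- tabulate(v, nbins = A[l]) + beta
      P[(off[l] + 1L):off[l + 1L], k] <- cnt / sum(cnt)
    }
  }
  P
}

# profile log-likelihood of a hard assignment (beta-smoothed frequencies)
.profile_loglik <- function(enc, z, K, beta = 0.5) {
  A <- enc$A
  off <- c(0L, cumsum(A))
  s <- 0
  for (k in seq_len(K)) {
    rows <- which(z == k)
    for (l in seq_along(A)) {
      v <- c(enc$G[rows, 2L * l - 1L], enc$G[rows, 2L * l])
      v <- v[v > 0L]
      if (!length(v)) next
      cnt <- tabulate(v, nbins = A[l])
      s <- s + sum(cnt * (log(cnt + beta) - log(length(v) + beta * A[l])))
    }
  }
  s
}

#' Maximum-likelihood mixture clustering by simulated annealing
#'
#' Fits the strict mixture (no-admixture) model: each individual belongs
#' to exactly one of `K` ancestral demes. The hard assignment maximises
#' the profile log-likelihood `sum_k sum_l sum_a n_kla log p_kla` with
#' within-cluster frequency MLEs smoothed by a Jeffreys pseudo-count
#' (`beta = 0.5` per allele). Optimisation is Metropolis annealing over
#' single-individual reassignments: initial temperature equal to the SD
#' of per-individual log-likelihood contributions, geometric cooling per
#' sweep, stopping after a fixed number of acceptance-free sweeps. The
#' best state visited is returned, so the result is never worse than the
#' initial state.
#'
#' @param gm a `geno_matrix`.
#' @param K number of clusters, `1 <= K <= n`.
#' @param seed integer seed (controls the random initial assignment and
#'   the proposal stream).
#' @param n_sweeps maximum annealing sweeps.
#' @param cool geometric cooling factor per sweep.
#' @param stop_sweeps stop after this many consecutive acceptance-free
#'   sweeps.
#' @param beta frequency pseudo-count per allele.
#' @return an `admix_fit` (model `"mixture"`, one-hot `Q`); empty clusters
#'   at the optimum are allowed but flagged via `attr(, "empty_clusters")`.
#' @export
fit_mixture <- function(gm, K, seed = 1L, n_sweeps = 200L, cool = 0.95,
                        stop_sweeps = 5L, beta = 0.5) {
  n <- n_ind(gm)
  if (K > n) stop("K exceeds the number of individuals")
  if (K < 1) stop("K must be >= 1")
  enc <- .gmat(gm)
  set.seed(seed)
  z0 <- if (K == 1L) rep(1L, n) else
    as.integer(sample(c(seq_len(K), sample.int(K, n - K, replace = TRUE))))
  r <- cpp_mix_anneal(enc$G, enc$A, as.integer(K), z0,
                      as.integer(n_sweeps), cool, beta,
                      as.integer(stop_sweeps), as.integer(seed))
  z <- r$z
  Q <- matrix(0, n, K)
  Q[cbind(seq_len(n), z)] <- 1
  P <- .profile_freqs(enc, z, K, beta)
  fit <- .new_admix_fit(gm, K, Q, P, r$logL, "mixture", seed,
                        iterations = n_sweeps, converged = TRUE, z = z)
  attr(fit, "empty_clusters") <- which(tabulate(z, K) == 0L)
  fit
}

#' Maximum-likelihood admixture coefficients by EM
#'
#' Fits the admixture model: every gene copy of individual `i` is drawn
#' from cluster `k` with probability `q_ik`, so
#' `logL = sum_i sum_l sum_copies log(sum_k q_ik p_kla)`. EM alternates
#' copy responsibilities with closed-form updates of `Q` and `P`; the
#' log-likelihood is non-decreasing at every iteration. Initialised from a
#' mixture fit with its one-hot rows softened to 0.9 (the remaining mass
#' spread over the other clusters), or from random Dirichlet rows.
#'
#' @param gm a `geno_matrix`.
#' @param K number of clusters.
#' @param init an `admix_fit` to start from, or `"random"`.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap.
#' @param seed integer seed (random init and restart stream).
#' @return an `admix_fit` (model `"admixture"`) with the EM trace in
#'   `$trace`.
#' @export
fit_admixture <- function(gm, K, init = NULL, tol = 1e-4, max_iter = 200L,
                          seed = 1L) {
  stopifnot(K >= 1, tol > 0)
  n <- n_ind(gm)
  if (K > n) stop("K exceeds the number of individuals")
  enc <- .gmat(gm)
  set.seed(seed)
  make_init <- function(random) {
    if (!random && inherits(init, "admix_fit") && init$K == K) {
      Q0 <- init$Q * 0.9 + (1 - rowSums(init$Q * 0.9)) / max(K - 1, 1) *
        (1 - init$Q)
      if (K == 1L) Q0 <- matrix(1, n, 1)
      P0 <- init$P
      P0[P0 <= 0] <- 1e-9
      P0 <- .renorm_blocks(P0, enc$A)
    } else {
      Q0 <- matrix(stats::rgamma(n * K, 1), n, K)
      Q0 <- Q0 / rowSums(Q0)
      z <- apply(Q0, 1, which.max)
      P0 <- .profile_freqs(enc, z, K, beta = 0.5)
    }
    list(Q0 = Q0, P0 = P0)
  }
  random <- identical(init, "random") || is.null(init)
  for (attempt in 1:5) {
    ini <- make_init(random || attempt > 1)
    r <- cpp_admix_em(enc$G, enc$A, ini$Q0, ini$P0, tol,
                      as.integer(max_iter))
    if (!isTRUE(r$failed)) break
    warning("non-finite likelihood; restarting EM from a fresh random init")
  }
  if (isTRUE(r$failed)) stop("EM failed to obtain a finite likelihood")
  fit <- .new_admix_fit(gm, K, r$Q, r$P, r$trace[length(r$trace)],
                        "admixture", seed, r$iterations, r$converged)
  fit$trace <- r$trace
  fit
}

.renorm_blocks <- function(P, A) {
  off <- c(0L, cumsum(A))
  for (l in seq_along(A)) {
    idx <- (off[l] + 1L):off[l + 1L]
    P[idx, ] <- sweep(P[idx, , drop = FALSE], 2,
                      colSums(P[idx, , drop = FALSE]), "/")
  }
  P
}

#' Run replicate mixture + admixture fits over a range of K
#'
#' For each `K` in `1:k_max`, runs `R` annealing mixture fits from
#' distinct random starts, refines each by admixture EM, and records the
#' log-likelihoods. The best-likelihood replicate per `K` is kept.
#'
#' @param gm a `geno_matrix`.
#' @param k_max largest K assayed.
#' @param R replicates per K.
#' @param seed integer seed; replicate `r` at a given `K` uses a seed
#'   derived from it.
#' @param ... passed to [fit_mixture()].
#' @return list of class `k_scan`: per-K `logL` matrix (R x k_max),
#'   `best_fits` (admixture fits), `k_max`, `R`.
#' @export
scan_k <- function(gm, k_max, R = 10L, seed = 1L, ...) {
  stopifnot(k_max >= 1, R >= 1)
  logL <- matrix(NA_real_, R, k_max)
  best <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    for (r in seq_len(R)) {
      s <- seed + 1000L * K + r
      mix <- fit_mixture(gm, K, seed = s, ...)
      adm <- fit_admixture(gm, K, init = mix, seed = s)
      logL[r, K] <- adm$logL
      if (is.null(best[[K]]) || adm$logL > best[[K]]$logL) {
        adm$z_mixture <- mix$z
        best[[K]] <- adm
      }
    }
  }
  structure(list(logL = logL, best_fits = best, k_max = k_max, R = R,
                 seed = seed),
            class = "k_scan")
}

# plug-in GST and FIS over hard clusters, multi-locus (mean Hs/Ht/Ho)
.gst_fis <- function(gm, z) {
  comp <- .locus_components(gm, as.character(z))
  comp <- comp[!vapply(comp, is.null, TRUE)]
  if (length(comp) == 0L) return(c(GST = NA_real_, FIS = NA_real_))
  Hs <- mean(vapply(comp, `[[`, 0, "Hs"))
  Ht <- mean(vapply(comp, `[[`, 0, "Ht"))
  Ho <- mean(vapply(comp, `[[`, 0, "Ho"))
  c(GST = if (Ht > 0) (Ht - Hs) / Ht else 0,
    FIS = if (Hs > 0) 1 - Ho / Hs else 0)
}

#' Choose K from replicate log-likelihoods
#'
#' The primary criterion is the second-order rate of log-likelihood
#' change, `D_LK2(K) = |L(K+1) - 2 L(K) + L(K-1)| / max(SD(K), eps)` with
#' `L(K)` the replicate mean and `SD(K)` the replicate standard deviation
#' (`eps = 1e-3` guards the frequent zero-variance case); the chosen K is
#' its argmax over `2..k_max-1`, ties broken toward smaller K. A
#' cluster-fixation ratio `F_STIS(K) = GST(K) / max(FIS(K), eps)` from
#' the best replicate's hard assignment is reported alongside. When the
#' likelihood curve has no curvature (all `D_LK2` below `flat_tol` on the
#' unnormalised scale), the choice falls back to K = 1 with a
#' `no_curvature` flag: inspect the raw log-likelihoods or run
#' [panmixia_test()].
#'
#' @param scan a [scan_k()] result.
#' @param gm the `geno_matrix` the scan was run on (for `F_STIS`).
#' @param eps variance floor.
#' @param flat_tol unnormalised curvature below which the curve is
#'   declared flat.
#' @return list of class `k_select`: `table` (per-K summary), `chosen_k`,
#'   `chosen_k_fstis`, `flag`.
#' @export
select_k <- function(scan, gm = NULL, eps = 1e-3, flat_tol = 1e-6) {
  stopifnot(inherits(scan, "k_scan"))
  k_max <- scan$k_max
  if (k_max < 3L) stop("need k_max >= 3 for the curvature criterion")
  Lm <- colMeans(scan$logL)
  Ls <- apply(scan$logL, 2, stats::sd)
  if (scan$R < 2L) Ls[] <- 0
  K <- seq_len(k_max)
  d1 <- c(NA, diff(Lm))
  curv <- rep(NA_real_, k_max)
  d2 <- rep(NA_real_, k_max)
  for (k in 2:(k_max - 1)) {
    curv[k] <- abs(Lm[k + 1] - 2 * Lm[k] + Lm[k - 1])
    d2[k] <- curv[k] / max(Ls[k], eps)
  }
  gf <- matrix(NA_real_, k_max, 2,
               dimnames = list(NULL, c("GST", "FIS")))
  fstis <- rep(NA_real_, k_max)
  if (!is.null(gm)) {
    for (k in 2:k_max) {
      z <- apply(scan$best_fits[[k]]$Q, 1, which.max)
      gf[k, ] <- .gst_fis(gm, z)
      fstis[k] <- gf[k, "GST"] / max(gf[k, "FIS"], eps)
    }
  }
  flat <- all(is.na(curv) | curv < flat_tol)
  chosen <- if (flat) 1L else which.max(d2)   # which.max takes first tie
  flag <- if (flat) "no_curvature" else "ok"
  ch_f <- if (all(is.na(fstis))) NA_integer_ else which.max(fstis)
  tab <- data.frame(K = K, mean_logL = Lm, sd_logL = Ls, D_LK1 = d1,
                    D_LK2 = d2, GST = gf[, "GST"], FIS = gf[, "FIS"],
                    F_STIS = fstis)
  structure(list(table = tab, chosen_k = chosen, chosen_k_fstis = ch_f,
                 flag = flag, eps = eps),
            class = "k_select")
}

#' @export
print.k_select <- function(x, ...) {
  cat(sprintf("K selection (curvature criterion): chosen K = %d [%s]\n",
              x$chosen_k, x$flag))
  if (!is.na(x$chosen_k_fstis))
    cat(sprintf("  F_STIS would choose K = %d\n", x$chosen_k_fstis))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bootstrap test of panmixia
#'
#' Tests whether the sample is one random-mating deme by comparing the
#' clustering gain `DlogL = best logL(K = 2) - logL(K = 1)` against its
#' null distribution: `B` datasets simulated from the fitted K = 1 model
#' under Hardy-Weinberg proportions with the observed missing pattern,
#' each refit at K = 1 and K = 2; `p = (1 + #{Dnull >= Dobs}) / (1 + B)`.
#' The null draws condition on the observed per-locus allele counts
#' (random re-pairing of the observed gene copies) rather than sampling
#' fresh copies from the frequency MLE: an unconditional draw loses rare
#' alleles, deflates the achievable two-cluster overfit, and makes the
#' test sharply anti-conservative for allele-rich markers.
#'
#' @param gm a `geno_matrix` with at least 10 individuals.
#' @param R replicate fits at K = 2 per dataset.
#' @param B bootstrap datasets (>= 19).
#' @param seed integer seed.
#' @param ... ignored (accepted for call compatibility with the
#'   decomposition driver).
#' @return list with `delta_logL`, `p`, `B`, `null_deltas`.
#' @export
panmixia_test <- function(gm, R = 3L, B = 49L, seed = 1L, ...) {
  n <- n_ind(gm)
  if (n < 10L) stop("need at least 10 individuals")
  if (B < 19L) stop("B must be >= 19")
  enc <- .gmat(gm)
  # clustering gain on an encoded matrix (skip R-level object building)
  fit2 <- function(e, s) {
    l1 <- .profile_loglik(e, rep(1L, nrow(e$G)), 1L)
    l2 <- max(vapply(seq_len(R), function(r) {
      set.seed(s + r)
      nn <- nrow(e$G)
      z0 <- as.integer(sample(c(1:2, sample.int(2L, nn - 2L, TRUE))))
      cpp_mix_anneal(e$G, e$A, 2L, z0, 120L, 0.95, 0.5, 5L,
                     as.integer(s + r))$logL
    }, 0))
    l2 - l1
  }
  d_obs <- fit2(enc, seed)
  miss <- missing_calls(gm)
  set.seed(seed + 31L)
  null_d <- vapply(seq_len(B), function(b) {
    G <- matrix(0L, n, 2L * n_loci(gm))
    for (l in seq_len(n_loci(gm))) {
      ok <- which(!miss[, l])
      copies <- c(enc$G[ok, 2L * l - 1L], enc$G[ok, 2L * l])
      copies <- sample(copies)
      G[ok, 2L * l - 1L] <- copies[seq_along(ok)]
      G[ok, 2L * l] <- copies[length(ok) + seq_along(ok)]
    }
    fit2(list(G = G, A = enc$A), seed + 1000L * b)
  }, 0)
  p <- (1 + sum(null_d >= d_obs)) / (1 + B)
  list(delta_logL = d_obs, p = p, B = B, null_deltas = null_d)
}
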