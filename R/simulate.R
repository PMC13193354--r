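#' Configuration for the nested-deme genotype simulator
#'
#' Describes a balanced binary hierarchy of demes drifting apart under the
#' Balding-Nichols model: ancestral allele frequencies are symmetric
#' Dirichlet, and each child deme's frequency vector is drawn
#' `Dirichlet(parent_p * (1 - F) / F)` with its level's drift parameter
#' `F`. The defaults emulate a mixed-stock microsatellite study design:
#' 15 loci with 13-31 alleles each, a depth-3 hierarchy (8 leaf demes)
#' with per-level drift 0.12/0.08/0.05, 16 individuals per leaf and 18.6%
#' missing genotypes.
#'
#' @param depth binary-tree depth (>= 0); leaves = `2^depth`.
#' @param F_levels per-level drift parameters in (0,1), length `depth`.
#' @param n_loci number of loci.
#' @param alleles_per_locus integer range `c(low, high)`; each locus draws
#'   its allele count uniformly from it.
#' @param dirichlet_theta symmetric-Dirichlet concentration of ancestral
#'   frequencies (> 0).
#' @param n_per_leaf individuals sampled per leaf deme.
#' @param admix_alpha optional Dirichlet concentration over leaves for
#'   admixed individuals; `NULL` (default) draws pure-deme individuals.
#' @param missing_rate probability in `[0, 1)` that a call is missing.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a `sim_config` list.
#' @export
sim_config <- function(depth = 3L, F_levels = c(0.12, 0.08, 0.05),
                       n_loci = 15L, alleles_per_locus = c(13L, 31L),
                       dirichlet_theta = 1, n_per_leaf = 16L,
                       admix_alpha = NULL, missing_rate = 0.186,
                       seed = 1L) {
  F_levels <- as.numeric(unlist(F_levels))
  stopifnot(depth >= 0, length(F_levels) == depth,
            all(F_levels > 0 & F_levels < 1) || depth == 0,
            n_loci >= 1, length(alleles_per_locus) == 2L,
            alleles_per_locus[1] >= 2,
            alleles_per_locus[2] >= alleles_per_locus[1],
            dirichlet_theta > 0, n_per_leaf >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(admix_alpha)) stopifnot(admix_alpha > 0)
  structure(list(depth = as.integer(depth), F_levels = F_levels,
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 dirichlet_theta = dirichlet_theta,
                 n_per_leaf = as.integer(n_per_leaf),
                 admix_alpha = admix_alpha,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Dirichlet draw via gamma; zero-concentration components stay exactly 0
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1   # degenerate guard
  x / sum(x)
}

#' Simulate genotypes under a nested hierarchy of demes
#'
#' Generates a `geno_matrix` plus ground truth from a [sim_config()]:
#' allele frequencies drift down a balanced binary tree (Balding-Nichols
#' per level), individuals are drawn by Hardy-Weinberg sampling within
#' their leaf deme (pure mode) or with per-copy cluster draws under
#' individual ancestry `Q ~ Dirichlet(admix_alpha)` (admixed mode), and
#' missing calls are injected at the configured rate. Fully seeded:
#' identical configs give identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a `geno_matrix`, grouped by leaf deme)
#'   and `truth` (class `sim_truth`: per-individual true leaf and `Q`,
#'   per-leaf allele-frequency tables, the tree topology with per-branch
#'   `F`).
#' @export
simulate_demes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  a_range <- cfg$alleles_per_locus[1]:cfg$alleles_per_locus[2]
  A <- a_range[sample.int(length(a_range), L, replace = TRUE)]
  loci <- sprintf("loc%02d", seq_len(L))
  n_leaf <- 2L^cfg$depth

  # frequency tree: list per level; level d+1 has 2^d nodes, each a
  # per-locus list of frequency vectors
  freqs <- list(list(
    lapply(A, function(a) .rdirichlet(rep(cfg$dirichlet_theta, a)))))
  if (cfg$depth > 0) for (d in seq_len(cfg$depth)) {
    Fd <- cfg$F_levels[d]
    parent <- freqs[[d]]
    lev <- vector("list", 2L^d)
    for (node in seq_len(2L^d)) {
      p <- parent[[(node + 1L) %/% 2L]]
      lev[[node]] <- lapply(p, function(pv) .rdirichlet(pv * (1 - Fd) / Fd))
    }
    freqs[[d + 1L]] <- lev
  }
  leaf_freq <- freqs[[cfg$depth + 1L]]
  leaf_names <- if (cfg$depth == 0L) "leaf_1" else
    paste0("leaf_", vapply(seq_len(n_leaf) - 1L, function(i)
      paste(rev(as.integer(intToBits(i))[seq_len(cfg$depth)]), collapse = ""),
      ""))

  n <- n_leaf * cfg$n_per_leaf
  ids <- sprintf("ind%03d", seq_len(n))
  Q <- matrix(0, n, n_leaf, dimnames = list(ids, leaf_names))
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  leaf_of <- rep(seq_len(n_leaf), each = cfg$n_per_leaf)
  if (is.null(cfg$admix_alpha)) {
    Q[cbind(seq_len(n), leaf_of)] <- 1
  } else {
    for (i in seq_len(n)) Q[i, ] <- .rdirichlet(rep(cfg$admix_alpha, n_leaf))
  }
  for (i in seq_len(n)) {
    qi <- Q[i, ]
    for (j in seq_len(L)) {
      k1 <- if (n_leaf == 1L) 1L else sample.int(n_leaf, 1L, prob = qi)
      k2 <- if (n_leaf == 1L) 1L else sample.int(n_leaf, 1L, prob = qi)
      a1[i, j] <- sample.int(A[j], 1L, prob = leaf_freq[[k1]][[j]])
      a2[i, j] <- sample.int(A[j], 1L, prob = leaf_freq[[k2]][[j]])
    }
  }
  grp <- leaf_names[leaf_of]
  gm <- genotype_matrix(ids, grp, loci, a1, a2)
  if (cfg$missing_rate > 0)
    gm <- inject_missing(gm, cfg$missing_rate,
                         seed = cfg$seed + 777L)
  truth <- structure(
    list(ind_id = ids, leaf = leaf_names[leaf_of], Q = Q,
         leaf_freq = stats::setNames(leaf_freq, leaf_names),
         tree = list(depth = cfg$depth, F_levels = cfg$F_levels),
         alleles_per_locus = A, config = cfg),
    class = "sim_truth")
  list(genotypes = gm, truth = truth)
}

#' Pool leaf demes into mixed sampling locations
#'
#' Relabels simulated individuals into sampling locations that mix several
#' leaf demes, creating the heterozygote-deficit (Wahlund) signal of a
#' pooled mixed-stock sample. Ground truth is untouched.
#'
#' @param gm a `geno_matrix` from [simulate_demes()].
#' @param truth the matching `sim_truth`.
#' @param mapping named list: location -> `list(leaves = c(...), weights =
#'   c(...))`, weights summing to 1 within each location.
#' @param n optional named integer vector of location sample sizes. When
#'   given, each location draws its leaf composition
#'   `multinomial(n, weights)` and samples individuals without replacement;
#'   unassigned individuals are dropped. When `NULL`, every individual
#'   whose leaf appears in the mapping is assigned independently with
#'   probability proportional to the location weights for its leaf, and
#'   uncovered individuals keep their leaf label.
#' @param seed integer seed for the assignment draws.
#' @return a relabelled (and, with `n`, subsetted) `geno_matrix`.
#' @export
pool_locations <- function(gm, truth, mapping, n = NULL, seed = 1L) {
  leaves_all <- unique(truth$leaf)
  for (m in names(mapping)) {
    mp <- mapping[[m]]
    if (!all(mp$leaves %in% leaves_all))
      stop("unknown leaf in mapping for location ", m)
    if (abs(sum(mp$weights) - 1) > 1e-8)
      stop("weights for location ", m, " must sum to 1")
  }
  set.seed(seed)
  leaf_of <- truth$leaf[match(gm$ind_id, truth$ind_id)]
  if (is.null(n)) {
    new_grp <- gm$group
    W <- matrix(0, length(leaves_all), length(mapping),
                dimnames = list(leaves_all, names(mapping)))
    for (m in names(mapping)) W[mapping[[m]]$leaves, m] <- mapping[[m]]$weights
    for (i in seq_along(leaf_of)) {
      wi <- W[leaf_of[i], ]
      if (sum(wi) > 0)
        new_grp[i] <- names(mapping)[sample.int(length(wi), 1L, prob = wi)]
    }
    return(subset_ind(gm, TRUE, group = new_grp))
  }
  stopifnot(all(names(mapping) %in% names(n)))
  pick <- integer(0); grp <- character(0)
  avail <- split(seq_along(leaf_of), leaf_of)
  for (m in names(mapping)) {
    mp <- mapping[[m]]
    comp <- as.vector(stats::rmultinom(1, n[[m]], mp$weights))
    # reallocate demand that exceeds a leaf's remaining individuals to
    # leaves with spare capacity (largest spare first, deterministic)
    cap <- vapply(mp$leaves, function(lf) length(avail[[lf]]), 0L)
    repeat {
      over <- comp - cap
      if (all(over <= 0)) break
      excess <- sum(over[over > 0])
      comp[over > 0] <- cap[over > 0]
      spare <- which(comp < cap)
      if (length(spare) == 0L)
        stop("location ", m, " demands more individuals than its leaves hold")
      for (v in spare[order(cap[spare] - comp[spare], decreasing = TRUE)]) {
        add <- min(excess, cap[v] - comp[v])
        comp[v] <- comp[v] + add
        excess <- excess - add
        if (excess == 0L) break
      }
      if (excess > 0L)
        stop("location ", m, " demands more individuals than its leaves hold")
    }
    for (v in seq_along(mp$leaves)) {
      pool <- avail[[mp$leaves[v]]]
      take <- if (length(pool) == 1L) pool else sample(pool, comp[v])
      take <- take[seq_len(comp[v])]
      avail[[mp$leaves[v]]] <- setdiff(pool, take)
      pick <- c(pick, take); grp <- c(grp, rep(m, comp[v]))
    }
  }
  o <- order(pick)
  subset_ind(gm, pick[o], group = grp[o])
}

#' Inject missing genotypes completely at random
#'
#' @param gm a `geno_matrix`.
#' @param rate per-call missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a `geno_matrix` with calls knocked out independently.
#' @export
inject_missing <- function(gm, rate, seed = 1L) {
  if (rate >= 1) stop("missing rate must be < 1")
  if (rate == 0) return(gm)
  set.seed(seed)
  n <- n_ind(gm); L <- n_loci(gm)
  knock <- matrix(stats::runif(n * L) < rate, n, L)
  out <- gm
  for (j in seq_len(L)) {
    out$tab[knock[, j], 2L * j - 1L] <- NA_integer_
    out$tab[knock[, j], 2L * j] <- NA_integer_
  }
  out
}

#' Simulate the default mixed-stock study design
#'
#' Convenience wrapper: simulates the default depth-3 hierarchy and pools
#' the 8 leaf demes into 4 sampling locations of sizes 20/40/40/40 with
#' equal mixing weights, so that sampling locations carry no information
#' about the latent demes (the mixed-stock situation).
#'
#' @param seed integer seed.
#' @param n_per_leaf individuals simulated per leaf before pooling
#'   (default 24, leaving slack for the multinomial draw).
#' @return list with `genotypes` (140 pooled individuals) and `truth`.
#' @export
emulate_study <- function(seed = 1L, n_per_leaf = 24L) {
  cfg <- sim_config(n_per_leaf = n_per_leaf, seed = seed)
  sim <- simulate_demes(cfg)
  leaves <- unique(sim$truth$leaf)
  mapping <- stats::setNames(lapply(c(1, 2, 3, 4), function(i)
    list(leaves = leaves, weights = rep(1 / length(leaves), length(leaves)))),
    c("locA", "locB", "locC", "locD"))
  n <- c(locA = 20L, locB = 40L, locC = 40L, locD = 40L)
  gm <- pool_locations(sim$genotypes, sim$truth, mapping, n = n,
                       seed = seed + 101L)
  list(genotypes = gm, truth = sim$truth)
}
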