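#' Recursive order-by-order decomposition of genetic structure
#'
#' The package's central procedure: cluster the full sample by
#' maximum-likelihood admixture analysis, rearrange individuals into the
#' chosen clusters by their maximum ancestry fraction, then independently
#' re-analyse each cluster at the next order, and so on. Recursion at a
#' node stops when the node is too small (`n < n_min`), when the
#' parametric-bootstrap panmixia test does not reject (`p >= alpha`) or
#' the likelihood curve shows no curvature, or when `max_order` is
#' reached. K ranges default to 14/7/4 at orders 1/2/3 and are capped at
#' `floor(n/5)`.
#'
#' @param gm a `geno_matrix`.
#' @param max_order deepest analysis order (default 3).
#' @param k_ranges integer vector, the largest K assayed at each order.
#' @param n_min smallest node worth analysing.
#' @param alpha level of the panmixia gate.
#' @param R replicate fits per K.
#' @param B_panmix bootstrap datasets for the panmixia test.
#' @param seed integer seed; the whole tree is reproducible from it.
#' @param ... passed to [fit_mixture()] (annealing controls).
#' @return a `deme_tree`: nested nodes with `order`, `members`,
#'   `chosen_k`, `k_select`, `fit`, `stop_reason`, `children`.
#' @export
decompose_demes <- function(gm, max_order = 3L, k_ranges = c(14L, 7L, 4L),
                            n_min = 15L, alpha = 0.05, R = 10L,
                            B_panmix = 49L, seed = 1L, ...) {
  if (n_ind(gm) == 0L) stop("empty input")
  stopifnot(length(k_ranges) >= max_order)
  build <- function(members, order, node_seed) {
    sub <- subset_ind(gm, match(members, gm$ind_id))
    node <- list(order = order, members = members, n = length(members),
                 chosen_k = NA_integer_, k_select = NULL, fit = NULL,
                 stop_reason = NA_character_, children = list())
    if (order >= max_order) { node$stop_reason <- "max_order"; return(node) }
    if (length(members) < n_min) { node$stop_reason <- "too_small"; return(node) }
    pan <- panmixia_test(sub, R = max(2L, R %/% 3L), B = B_panmix,
                         seed = node_seed, ...)
    node$panmixia_p <- pan$p
    if (pan$p >= alpha) { node$stop_reason <- "panmixia"; return(node) }
    k_max <- min(k_ranges[order + 1L], length(members) %/% 5L)
    if (k_max < 3L) { node$stop_reason <- "too_small"; return(node) }
    scan <- scan_k(sub, k_max, R = R, seed = node_seed + 7L, ...)
    sel <- select_k(scan, sub)
    node$k_select <- sel
    if (sel$chosen_k < 2L) { node$stop_reason <- "panmixia"; return(node) }
    fit <- scan$best_fits[[sel$chosen_k]]
    node$chosen_k <- sel$chosen_k
    node$fit <- fit
    z <- apply(fit$Q, 1, which.max)
    for (k in seq_len(sel$chosen_k)) {
      kid_members <- members[z == k]
      node$children[[k]] <-
        if (length(kid_members) == 0L)
          list(order = order + 1L, members = character(0), n = 0L,
               chosen_k = NA_integer_, k_select = NULL, fit = NULL,
               stop_reason = "too_small", children = list())
        else build(kid_members, order + 1L,
                   node_seed + 100000L * k + 13L)
    }
    node
  }
  root <- build(gm$ind_id, 0L, seed)
  structure(list(root = root, max_order = max_order, n_min = n_min,
                 alpha = alpha, seed = seed),
            class = "deme_tree")
}

# walk nodes, applying fn(node, path)
.walk_tree <- function(node, fn, path = integer(0)) {
  fn(node, path)
  for (k in seq_along(node$children))
    .walk_tree(node$children[[k]], fn, c(path, k))
  invisible()
}

#' Cluster membership at a given order
#'
#' Truncates each individual's cluster path at depth `d`; individuals in
#' nodes that stopped earlier keep their final (shallower) cluster.
#'
#' @param tree a `deme_tree`.
#' @param d order (1-based depth).
#' @return named character vector: individual id -> cluster path label.
#' @export
partition_at_order <- function(tree, d) {
  out <- character(0)
  .walk_tree(tree$root, function(node, path) {
    if ((length(path) == d || length(node$children) == 0L) &&
        length(path) <= d && length(node$members)) {
      lab <- if (length(path)) paste(path, collapse = ".") else "root"
      if (length(path) == d || length(node$children) == 0L)
        out[node$members] <<- lab
    }
  })
  out[!is.na(out)]
}

#' @export
print.deme_tree <- function(x, ...) {
  cat(sprintf("deme_tree: %d individuals, max order %d\n",
              length(x$root$members), x$max_order))
  .walk_tree(x$root, function(node, path) {
    lab <- if (length(path)) paste(path, collapse = ".") else "root"
    cat(sprintf("%s%s: n = %d%s%s\n",
                strrep("  ", length(path) + 1L), lab, node$n,
                if (!is.na(node$chosen_k))
                  sprintf(", K = %d", node$chosen_k) else "",
                if (!is.na(node$stop_reason))
                  sprintf(" [%s]", node$stop_reason) else ""))
  })
  invisible(x)
}

#' @export
as.data.frame.deme_tree <- function(x, ...) {
  ids <- x$root$members
  cols <- lapply(seq_len(x$max_order), function(d) {
    p <- partition_at_order(x, d)
    p[ids]
  })
  names(cols) <- paste0("order", seq_len(x$max_order))
  data.frame(ind_id = ids, cols, stringsAsFactors = FALSE)
}

#' Per-order diagnostic summary of a decomposition
#'
#' For each order: number of clusters, mean within-cluster sample size,
#' observed/expected heterozygosity, allele count and inbreeding
#' coefficient, mean pairwise Jost's D and G''ST among the order's
#' clusters, and the mean number of loci conforming to HWE per cluster
#' after Holm correction.
#'
#' @param tree a `deme_tree`.
#' @param gm the analysed `geno_matrix`.
#' @param hwe_B Monte-Carlo resamples for the per-cluster HWE tests.
#' @param seed integer seed.
#' @return data frame, one row per order.
#' @export
order_summary <- function(tree, gm, hwe_B = 2000L, seed = 1L) {
  rows <- lapply(seq_len(tree$max_order), function(d) {
    part <- partition_at_order(tree, d)
    ids <- names(part)
    sub <- subset_ind(gm, match(ids, gm$ind_id), group = unname(part))
    labs <- unique(sub$group)
    div <- diversity_stats(sub)
    over <- div[div$locus == "over loci", , drop = FALSE]
    pairD <- pairG <- NA_real_
    if (length(labs) >= 2L) {
      prs <- utils::combn(labs, 2)
      vals <- apply(prs, 2, function(pr) {
        s <- subset_ind(sub, sub$group %in% pr)
        diff_stats(s, n_perm = 0L, n_boot = 0L)$multilocus
      })
      pairD <- mean(vals["D", ])
      pairG <- mean(vals["Gppst", ])
    }
    hw <- hwe_matrix(sub, B = hwe_B, seed = seed + d)
    in_hwe <- stats::aggregate(!hw$significant,
                               by = list(group = hw$group), FUN = sum)
    data.frame(order = d, n_clusters = length(labs),
               mean_n = mean(over$N), mean_H_O = mean(over$H_O),
               mean_H_E = mean(over$H_E), mean_N_A = mean(over$N_A),
               mean_F = mean(over$F, na.rm = TRUE),
               mean_pairwise_D = pairD, mean_pairwise_Gppst = pairG,
               mean_loci_in_HWE = mean(in_hwe$x))
  })
  do.call(rbind, rows)
}

#' @export
summary.deme_tree <- function(object, gm = NULL, ...) {
  if (is.null(gm)) stop("supply the genotype matrix via gm =")
  order_summary(object, gm, ...)
}

#' Compare an inferred partition with a reference
#'
#' Adjusted Rand index from the contingency table, plus accuracy under
#' the best one-to-one cluster-label matching (exhaustive over label
#' permutations up to 8 clusters, greedy beyond).
#'
#' @param inferred,truth label vectors over the same individuals.
#' @return list with `ari` and `accuracy`.
#' @export
compare_partitions <- function(inferred, truth) {
  if (length(inferred) != length(truth)) stop("length mismatch")
  tab <- table(inferred, truth)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  ari <- if (max_idx == expected) 0 else (sum_ij - expected) / (max_idx - expected)

  r <- nrow(tab); c <- ncol(tab)
  k <- min(r, c)
  acc <- if (max(r, c) <= 8L) {
    perms <- .permutations(max(r, c))
    best <- 0
    for (pi in seq_len(nrow(perms))) {
      s <- 0
      for (i in seq_len(r)) {
        j <- perms[pi, i]
        if (j <= c) s <- s + tab[i, j]
      }
      best <- max(best, s)
    }
    best / n
  } else {
    # greedy matching on the largest cells
    tb <- tab
    s <- 0
    for (step in seq_len(k)) {
      w <- which(tb == max(tb), arr.ind = TRUE)[1, ]
      s <- s + tb[w[1], w[2]]
      tb[w[1], ] <- -1
      tb[, w[2]] <- -1
    }
    s / n
  }
  list(ari = as.numeric(ari), accuracy = as.numeric(acc))
}

.permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
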