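#' Run the full analysis pipeline from a configuration
#'
#' Configuration-driven driver tying the stages together: simulate (or
#' read) genotypes, filter individuals with excessive missing data,
#' within-sample diversity, HWE/LD tests, differentiation and AMOVA,
#' K-scan, hierarchical decomposition and order summaries. Writes a
#' reproducible bundle of CSV/JSON files plus a Markdown report; every
#' file records the seed and a hash of the configuration. Identical
#' configurations (including the seed) give byte-identical outputs.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised fields: `seed` (mandatory), `out_dir` (mandatory), one of
#'   `genepop`/`csv` (input path) or `simulate` (a list of [sim_config()]
#'   arguments), `max_missing_loci`, `stages` (character subset of
#'   `c("diversity", "equilibrium", "differentiation", "hierarchy")`,
#'   default all), `n_perm`, `hwe_B`, `R`, `k_ranges`, `n_min`, `alpha`,
#'   `B_panmix`, `max_order`.
#' @return (invisibly) a list with the loaded genotypes and all stage
#'   results; files are written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  if (is.null(cfg$out_dir)) stop("config error: 'out_dir' is mandatory")
  has_input <- !is.null(cfg$genepop) || !is.null(cfg$csv) ||
    !is.null(cfg$simulate)
  if (!has_input)
    stop("config error: supply 'genepop', 'csv' or 'simulate'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  stages <- cfg$stages %||% c("diversity", "equilibrium",
                              "differentiation", "hierarchy")
  cfg_core <- cfg[setdiff(names(cfg), "out_dir")]   # hash the science, not the path
  cfg_hash <- sum(utf8ToInt(paste(deparse(cfg_core), collapse = ""))) %% 100000L
  stamp <- sprintf("# seed=%d config_hash=%05d", seed, cfg_hash)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    invisible(NULL)
  }
  wcsv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  res <- list(config = cfg)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s",
                                      name, conditionMessage(e))),
                 file.path(cfg$out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    note("%s done in %.1fs", name, proc.time()[3] - t0)
    out
  }

  truth <- NULL
  gm <- run_stage("input", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                  cfg$simulate))
      sim <- simulate_demes(sc)
      truth <- sim$truth
      write_genotypes_csv(sim$genotypes,
                          file.path(cfg$out_dir, "genotypes.csv"))
      jsonlite::write_json(
        list(seed = seed, leaf = as.list(stats::setNames(truth$leaf,
                                                         truth$ind_id)),
             tree = truth$tree),
        file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE)
      sim$genotypes
    } else if (!is.null(cfg$genepop)) read_genepop(cfg$genepop)
    else read_genotypes_csv(cfg$csv)
  })
  res$truth <- truth

  if (!is.null(cfg$max_missing_loci)) {
    fl <- run_stage("filter", filter_missing(gm, cfg$max_missing_loci))
    gm <- fl$genotypes
    wcsv(fl$removed, "removed_individuals.csv")
  }
  res$genotypes <- gm

  md <- c("# hierstock pipeline report", stamp, "",
          sprintf("Individuals: %d; loci: %d; groups: %s.", n_ind(gm),
                  n_loci(gm), paste(unique(gm$group), collapse = ", ")))

  if ("diversity" %in% stages) {
    res$diversity <- run_stage("diversity", diversity_stats(gm))
    wcsv(res$diversity, "diversity.csv")
    over <- res$diversity[res$diversity$locus == "over loci", ]
    md <- c(md, "", "## Diversity (per-group means over loci)", "",
            paste(utils::capture.output(print(
              format(over[, c("group", "N", "N_A", "H_O", "H_E", "F")],
                     digits = 3), row.names = FALSE)), collapse = "\n"))
  }
  if ("equilibrium" %in% stages) {
    res$hwe <- run_stage("hwe", hwe_matrix(gm, B = cfg$hwe_B %||% 2000L,
                                           seed = seed))
    wcsv(res$hwe, "hwe.csv")
    res$ld <- run_stage("ld", {
      prs <- utils::combn(gm$loci, 2)
      rows <- list()
      i <- 0L
      for (g in unique(gm$group)) for (ci in seq_len(ncol(prs))) {
        i <- i + 1L
        r <- ld_test(gm, g, prs[, ci],
                     B = max(199L, cfg$n_perm %||% 999L),
                     seed = seed + i)
        rows[[i]] <- data.frame(group = g, locus1 = prs[1, ci],
                                locus2 = prs[2, ci], G = r$G, p = r$p,
                                skipped = r$skipped,
                                stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      ok <- !df$skipped
      df$significant <- FALSE
      if (any(ok)) df$significant[ok] <- holm_adjust(df$p[ok], 0.05)$reject
      df
    })
    wcsv(res$ld, "ld.csv")
    md <- c(md, "", "## Hardy-Weinberg and linkage disequilibrium", "",
            sprintf("%d of %d (group, locus) HWE tests significant after Holm;",
                    sum(res$hwe$significant), nrow(res$hwe)),
            sprintf("%d of %d locus-pair LD tests significant after Holm.",
                    sum(res$ld$significant), nrow(res$ld)))
  }
  if ("differentiation" %in% stages && length(unique(gm$group)) >= 2L) {
    res$diff <- run_stage("differentiation",
                          diff_stats(gm, n_perm = cfg$n_perm %||% 999L,
                                     seed = seed))
    res$amova <- run_stage("amova",
                           amova(gm, n_perm = cfg$n_perm %||% 999L,
                                 seed = seed))
    wcsv(res$diff$per_locus, "differentiation_per_locus.csv")
    md <- c(md, "", "## Differentiation among groups", "",
            sprintf("Jost's D = %.4f (SE %.4f, p = %.4g); G''ST = %.4f (SE %.4f, p = %.4g); AMOVA phi_ST = %.4f (p = %.4g).",
                    res$diff$multilocus["D"], res$diff$jackknife_se["D"],
                    res$diff$perm_p["D"], res$diff$multilocus["Gppst"],
                    res$diff$jackknife_se["Gppst"],
                    res$diff$perm_p["Gppst"], res$amova$phi_st,
                    res$amova$p))
  }
  if ("hierarchy" %in% stages) {
    res$tree <- run_stage("hierarchy",
      decompose_demes(gm, max_order = cfg$max_order %||% 3L,
                      k_ranges = cfg$k_ranges %||% c(14L, 7L, 4L),
                      n_min = cfg$n_min %||% 15L,
                      alpha = cfg$alpha %||% 0.05,
                      R = cfg$R %||% 10L,
                      B_panmix = cfg$B_panmix %||% 49L, seed = seed))
    flat <- as.data.frame(res$tree)
    wcsv(flat, "cluster_paths.csv")
    if (!is.null(res$tree$root$fit)) {
      q <- res$tree$root$fit$Q
      wcsv(data.frame(ind_id = rownames(q), q, check.names = FALSE),
           "q_order1.csv")
    }
    if (!is.null(res$tree$root$k_select))
      wcsv(res$tree$root$k_select$table, "k_selection_order1.csv")
    res$order_summary <- run_stage("order_summary",
      order_summary(res$tree, gm, hwe_B = cfg$hwe_B %||% 2000L,
                    seed = seed))
    wcsv(res$order_summary, "order_summary.csv")
    md <- c(md, "", "## Hierarchical decomposition", "",
            paste(utils::capture.output(print(res$tree)), collapse = "\n"),
            "", "### Order trends", "",
            paste(utils::capture.output(print(
              format(res$order_summary, digits = 3), row.names = FALSE)),
              collapse = "\n"))
  }
  writeLines(md, file.path(cfg$out_dir, "report.md"))
  writeLines(c(stamp, log_lines), file.path(cfg$out_dir, "run.log"))
  jsonlite::write_json(list(seed = seed, config_hash = cfg_hash,
                            stages = stages),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
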