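#' Read genotypes from GenePop format
#'
#' Parses the classic GenePop interchange format for diploid genotypes:
#' a title line, locus names (one per line or comma-separated on one line),
#' then population blocks delimited by lines equal to `Pop`
#' (case-insensitive). Individual lines are `name , t1 t2 ...` where each
#' token concatenates two fixed-width (2- or 3-digit) allele codes;
#' `00`/`000` codes an undetermined allele. The digit width is
#' auto-detected from token lengths. A call with exactly one missing
#' allele is recorded as half-missing and treated as missing downstream.
#'
#' @param path path to a GenePop file, or its full text via `text`.
#' @param text optional character scalar with file content (overrides `path`).
#' @return a [genotype_matrix()] with one group per `Pop` block (named
#'   `pop1`, `pop2`, ... unless individual names carry a shared prefix).
#' @export
read_genepop <- function(path, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("GenePop file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' line found")
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0L) stop("no locus names found")

  ids <- character(); grp <- character()
  a1 <- NULL; a2 <- NULL
  pop_no <- 0L
  digits <- NA_integer_
  for (k in first_pop:length(lines)) {
    ln <- lines[k]
    if (toupper(trimws(ln)) == "POP") { pop_no <- pop_no + 1L; next }
    if (!nzchar(trimws(ln))) next
    # individual name terminated by comma or tab
    sp <- regexpr("[,\t]", ln)
    if (sp < 0) stop(sprintf("line %d: no ',' or tab after individual name", k))
    nm <- trimws(substr(ln, 1L, sp - 1L))
    toks <- strsplit(trimws(substr(ln, sp + 1L, nchar(ln))), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop(sprintf("line %d: %d genotype tokens, expected %d loci",
                   k, length(toks), L))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop(sprintf("line %d: cannot detect allele digit width from token widths %s",
                   k, paste(w, collapse = "/")))
    d <- w %/% 2L
    if (is.na(digits)) digits <- d
    else if (digits != d) stop(sprintf("line %d: mixed digit widths", k))
    x1 <- as.integer(substr(toks, 1L, d))
    x2 <- as.integer(substr(toks, d + 1L, 2L * d))
    if (anyNA(x1) || anyNA(x2))
      stop(sprintf("line %d: non-numeric allele code", k))
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    ids <- c(ids, nm); grp <- c(grp, sprintf("pop%d", pop_no))
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (length(ids) == 0L) stop("no individuals found")
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gm <- genotype_matrix(ids, grp, loci, a1, a2)
  attr(gm, "digits") <- digits
  gm
}

#' Write genotypes in GenePop format
#'
#' Deterministic output: individual and locus order as stored, missing
#' alleles coded as zeros of the chosen width. Round-trips through
#' [read_genepop()].
#'
#' @param gm a `geno_matrix` whose allele labels are positive integers.
#' @param path output file; if `NULL` the text is returned invisibly.
#' @param digits 2 or 3 digit allele codes (default 3).
#' @param title first line of the file.
#' @return the file text, invisibly.
#' @export
write_genepop <- function(gm, path = NULL, digits = 3L, title = "hierstock export") {
  stopifnot(digits %in% c(2L, 3L))
  labs <- unlist(gm$alleles)
  if (length(labs)) {
    if (!all(labs == as.integer(labs)) || any(labs < 1))
      stop("allele labels must be positive integers for GenePop export")
    if (any(labs >= 10^digits))
      stop(sprintf("allele label >= 10^%d; use digits = 3 or rebin", digits))
  }
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = digits, flag = "0")
  }
  out <- c(title, gm$loci)
  for (g in unique(gm$group)) {
    out <- c(out, "Pop")
    for (i in which(gm$group == g)) {
      toks <- vapply(seq_len(n_loci(gm)), function(j) {
        lab <- gm$alleles[[j]]
        paste0(fmt(lab[gm$tab[i, 2L * j - 1L]]), fmt(lab[gm$tab[i, 2L * j]]))
      }, "")
      out <- c(out, paste0(gm$ind_id[i], " ,  ", paste(toks, collapse = " ")))
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path, useBytes = FALSE)
  invisible(txt)
}

#' Read/write genotypes as tidy CSV
#'
#' One row per individual with columns `id`, `group`, then `"<locus>_a"`,
#' `"<locus>_b"` allele-label pairs; empty cells are missing.
#'
#' @param path CSV file path.
#' @return a `geno_matrix`.
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "group") %in% names(df)))
    stop("CSV needs 'id' and 'group' columns")
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  bcols <- paste0(loci, "_b")
  if (!all(bcols %in% names(df))) stop("unpaired locus columns in CSV")
  as_int <- function(x) { x[x %in% c("", "NA")] <- NA; as.integer(x) }
  a1 <- sapply(acols, function(cn) as_int(as.character(df[[cn]])))
  a2 <- sapply(bcols, function(cn) as_int(as.character(df[[cn]])))
  if (nrow(df) == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  genotype_matrix(df$id, df$group, loci, a1, a2)
}

#' @rdname read_genotypes_csv
#' @param gm a `geno_matrix`.
#' @export
write_genotypes_csv <- function(gm, path) {
  L <- n_loci(gm)
  cols <- vector("list", 2L * L)
  for (j in seq_len(L)) {
    ab <- .allele_labels(gm, j)
    cols[[2L * j - 1L]] <- ab[, 1]
    cols[[2L * j]] <- ab[, 2]
  }
  names(cols) <- as.vector(rbind(paste0(gm$loci, "_a"), paste0(gm$loci, "_b")))
  df <- data.frame(id = gm$ind_id, group = gm$group, cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bin raw fragment lengths into nominal allele classes
#'
#' Automated binning of fragment-analysis sizes onto a repeat-motif grid:
#' the grid offset is searched over `[0, motif_len)` at 0.1-bp resolution
#' and the offset minimising the total squared deviation of lengths from
#' their nearest grid point wins. Allele classes are the rounded grid
#' values, so distinct classes are exact multiples of `motif_len` apart.
#' Per-length residuals are reported so a human can supervise the result
#' against the frequency histogram.
#'
#' @param lengths numeric vector of positive fragment sizes (bp).
#' @param motif_len integer repeat length, at least 2.
#' @return data frame with columns `length`, `allele` (integer class) and
#'   `residual` (length minus its grid point); the chosen `offset` and its
#'   total squared deviation are attached as attributes.
#' @export
bin_fragments <- function(lengths, motif_len) {
  if (length(lengths) == 0L) stop("no fragment lengths supplied")
  if (!all(lengths > 0)) stop("fragment lengths must be positive")
  if (motif_len < 2) stop("motif_len must be >= 2")
  offsets <- seq(0, motif_len - 0.1, by = 0.1)
  ss <- vapply(offsets, function(o) {
    grid <- o + motif_len * round((lengths - o) / motif_len)
    sum((lengths - grid)^2)
  }, 0)
  best <- offsets[which.min(ss)]
  grid <- best + motif_len * round((lengths - best) / motif_len)
  out <- data.frame(length = lengths,
                    allele = as.integer(round(grid)),
                    residual = lengths - grid)
  attr(out, "offset") <- best
  attr(out, "total_sq_dev") <- min(ss)
  out
}
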