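#' Read and write GENEPOP files
#'
#' Parses the standard GENEPOP text format for codominant genotypes: a
#' title line, one locus name per line (or one comma-separated line),
#' population blocks introduced by `Pop`, and individual lines
#' `id , 0101 0202 ...` with 2- or 3-digit allele codes. `00`/`000` alleles
#' are missing data. Populations are labelled by the id of their first
#' individual, and `write_genepop()` round-trips a parsed dataset.
#'
#' @param path File path.
#' @return A long tibble of class `microsat_df` with columns `pop`,
#'   `individual_id`, `locus`, `a1`, `a2` (integer allele size labels,
#'   `NA` = missing).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort("parse error: truncated GENEPOP file.")
  is_pop <- function(x) tolower(trimws(x)) == "pop"
  first_pop <- which(vapply(lines, is_pop, TRUE))[1]
  if (is.na(first_pop) || first_pop < 3L) {
    abort("parse error: no 'Pop' separator after the locus list.")
  }
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1L)], ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) abort("parse error: empty locus list.")
  rows <- list()
  pop_idx <- 0L
  pop_label <- NA_character_
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (is_pop(line)) {
      pop_idx <- pop_idx + 1L
      pop_label <- NA_character_
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) {
      abort(sprintf("parse error at line %d: missing ',' separator.", ln))
    }
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != length(loci)) {
      abort(sprintf("parse error at line %d: %d genotypes for %d loci.",
                    ln, length(gts), length(loci)))
    }
    if (is.na(pop_label)) pop_label <- id
    w <- nchar(gts) / 2
    if (!all(w %in% c(2, 3))) {
      abort(sprintf("parse error at line %d: allele codes must be 2 or 3 digits.", ln))
    }
    a1 <- as.integer(substr(gts, 1L, w))
    a2 <- as.integer(substr(gts, w + 1L, 2L * w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pop = pop_label, individual_id = id, locus = loci, a1 = a1, a2 = a2)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("parse error: no individuals found.")
  class(out) <- c("microsat_df", class(out))
  out
}

#' @rdname read_genepop
#' @param data A `microsat_df` tibble.
#' @param title Title line to write.
#' @param digits Allele code width (2 or 3).
#' @export
write_genepop <- function(data, path, title = "microsatellite dataset",
                          digits = 3L) {
  loci <- unique(data$locus)
  fmt <- function(a) sprintf(paste0("%0", digits, "d"), ifelse(is.na(a), 0L, a))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  for (p in unique(data$pop)) {
    writeLines("Pop", con)
    dp <- data[data$pop == p, , drop = FALSE]
    for (id in unique(dp$individual_id)) {
      di <- dp[dp$individual_id == id, , drop = FALSE]
      di <- di[match(loci, di$locus), , drop = FALSE]
      writeLines(paste0(id, " ,  ",
                        paste(paste0(fmt(di$a1), fmt(di$a2)), collapse = " ")), con)
    }
  }
  invisible(path)
}
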