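#' Read and write site-by-allele count tables
#'
#' Tab-separated layout with one row per site: identifying columns
#' (`site_code`, optionally `location`, `river`, `position`), one column per
#' allele, and an optional `total` column validated against the row sum.
#' Dash cells (`-` or en-dash) are read as zero counts, the convention used
#' in published allele-count tables.
#'
#' @param path File path.
#' @return Allele-count tibble; `total` recomputed/validated.
#' @export
read_counts_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(raw)
  ac <- allele_columns(out)
  for (col in ac) {
    v <- out[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      v[v %in% c("-", "–", "—", "")] <- "0"
      v <- suppressWarnings(as.integer(v))
      if (anyNA(v)) abort(sprintf("validation error: non-numeric counts in column %s.", col))
      out[[col]] <- v
    }
  }
  sums <- rowSums(out[ac])
  if ("total" %in% names(out)) {
    bad <- which(out$total != sums)
    if (length(bad)) {
      abort(sprintf("validation error: row sum mismatch for site %s.",
                    out$site_code[bad[1]]))
    }
  } else {
    out$total <- as.integer(sums)
  }
  out
}

#' @rdname read_counts_table
#' @param counts Allele-count tibble.
#' @export
write_counts_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled MHC allele-count survey of six Alberta river sites
#'
#' Copy numbers of eight MHC class II beta exon 2 alleles genotyped in
#' longnose dace at six sites on three rivers (Bow, Oldman, Milk), one
#' upstream and one downstream site per river. This is the worked example
#' dataset used throughout the package documentation; the single-fish
#' upstream Milk site is conventionally pooled with the downstream Milk
#' site before computing diversity statistics (see [pool_counts()]).
#'
#' @return Allele-count tibble with columns `site_code`, `location`,
#'   `river`, `position`, `A1`-`A8`, `total`.
#' @export
#' @examples
#' dace_mhc_counts()
dace_mhc_counts <- function() {
  read_counts_table(system.file("extdata", "dace_mhc_counts.tsv",
                                package = "riffle", mustWork = TRUE))
}

#' Write per-sample reads as FASTA files plus a truth table
#'
#' One FASTA per individual (reads named `read_1..n`) and a tab-separated
#' truth table (`individual_id`, `site_code`, `allele1`, `allele2`,
#' `replicate_of`), the on-disk interface of the simulator.
#'
#' @param reads Read tibble from [sim_reads()].
#' @param truth Matching truth tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_fasta <- function(reads, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(reads))) {
    rs <- reads$reads[[i]]
    ss <- Biostrings::DNAStringSet(setNames(rs, paste0("read_", seq_along(rs))))
    Biostrings::writeXStringSet(
      ss, file.path(dir, paste0(reads$individual_id[i], ".fasta")))
  }
  utils::write.table(
    truth[, c("individual_id", "site_code", "allele1", "allele2", "replicate_of")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a directory of per-sample FASTA files
#'
#' @param dir Directory of `<individual_id>.fasta` files.
#' @param meta Optional tibble `individual_id`, `site_code`.
#' @return Read tibble as produced by [sim_reads()].
#' @export
read_sample_fasta <- function(dir, meta = NULL) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(files) == 0L) abort("input error: no FASTA files found.")
  ids <- sub("\\.fasta$", "", basename(files))
  reads <- lapply(files, function(f) as.character(Biostrings::readDNAStringSet(f)))
  tibble::tibble(
    individual_id = ids,
    site_code = if (is.null(meta)) NA_character_ else
      meta$site_code[match(ids, meta$individual_id)],
    depth = lengths(reads),
    reads = lapply(reads, unname))
}
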