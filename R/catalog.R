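#' Allele catalogs
#'
#' An allele catalog is the set of distinct amplicon allele sequences, stored
#' as a tibble with columns `allele_id` and `sequence`, plus two attributes:
#' `exon_span`, the 0-based half-open interval of the coding exon within the
#' amplicon, and `frame_offset`, the codon frame (0-2) of the exon's first
#' base. The default geometry is the 236-bp MHC class II beta amplicon with a
#' 207-bp exon segment (`exon_span = c(0, 207)`) followed by 29 bp of intron.
#'
#' @param alleles A data frame with columns `allele_id` (unique short labels)
#'   and `sequence` (A/C/G/T strings of one common length).
#' @param exon_span Integer vector of length 2, 0-based half-open exon
#'   interval within the amplicon.
#' @param frame_offset Integer 0-2; bases of the exon to skip before the
#'   first complete codon.
#' @return A tibble of class `mhc_catalog`.
#' @export
#' @examples
#' cat8 <- sim_allele_catalog(n_alleles = 4, exon_len = 30, intron_len = 6,
#'                            n_segregating = 5, seed = 1)
#' exon_sequences(cat8)
mhc_catalog <- function(alleles, exon_span = c(0L, 207L), frame_offset = 0L) {
  alleles <- tibble::as_tibble(alleles)
  if (!all(c("allele_id", "sequence") %in% names(alleles))) {
    abort("`alleles` needs columns `allele_id` and `sequence`.")
  }
  if (anyDuplicated(alleles$allele_id)) abort("`allele_id` values must be unique.")
  L <- unique(nchar(alleles$sequence))
  if (length(L) != 1L) abort("All catalog sequences must have the same length.")
  if (any(grepl("[^ACGT]", alleles$sequence))) {
    abort("Catalog sequences may only use A/C/G/T.")
  }
  exon_span <- as.integer(exon_span)
  frame_offset <- as.integer(frame_offset)
  if (length(exon_span) != 2L || exon_span[1] < 0L || exon_span[2] > L ||
      exon_span[1] >= exon_span[2]) {
    abort("`exon_span` must be a 0-based half-open interval inside the amplicon.")
  }
  if (!frame_offset %in% 0:2) abort("`frame_offset` must be 0, 1 or 2.")
  usable <- exon_span[2] - exon_span[1] - frame_offset
  if (usable %/% 3L < 1L) abort("Exon too short for a single codon after frame trimming.")
  structure(alleles,
            exon_span = exon_span, frame_offset = frame_offset,
            class = c("mhc_catalog", class(tibble::tibble())))
}

#' @export
print.mhc_catalog <- function(x, ...) {
  sp <- attr(x, "exon_span")
  cat(sprintf("<mhc_catalog> %d alleles, %d bp amplicon, exon [%d,%d), frame %d\n",
              nrow(x), nchar(x$sequence[1]), sp[1], sp[2], attr(x, "frame_offset")))
  NextMethod()
}

#' Extract exon-only, in-frame sequences from a catalog
#'
#' Trims each allele to the exon interval, drops `frame_offset` leading bases
#' and any trailing partial codon, so the result is a codon alignment.
#'
#' @param catalog An [mhc_catalog()].
#' @return Named character vector of equal-length, in-frame coding sequences.
#' @export
exon_sequences <- function(catalog) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  sp <- attr(catalog, "exon_span")
  fo <- attr(catalog, "frame_offset")
  exon <- substr(catalog$sequence, sp[1] + 1L, sp[2])
  exon <- substr(exon, fo + 1L, nchar(exon))
  keep <- (nchar(exon) %/% 3L) * 3L
  setNames(substr(exon, 1L, keep), catalog$allele_id)
}

#' Pairwise nucleotide difference matrix between catalog alleles
#'
#' Counts of differing sites between aligned allele sequences (raw counts,
#' not corrected), the "matrix of pairwise differences" used as squared
#' molecular distances by the AMOVA machinery.
#'
#' @inheritParams exon_sequences
#' @return Symmetric integer matrix with allele ids as dimnames.
#' @export
allele_diff_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  m <- seq_to_mat(catalog$sequence)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(catalog$allele_id, catalog$allele_id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Read and write allele catalogs as FASTA
#'
#' Plain FASTA with one record per allele. Exon coordinates are not part of
#' the FASTA format, so they are supplied on read.
#'
#' @param path File path.
#' @param catalog An [mhc_catalog()] (for writing).
#' @inheritParams mhc_catalog
#' @return `read_allele_fasta()` returns an [mhc_catalog()];
#'   `write_allele_fasta()` returns `path` invisibly.
#' @export
read_allele_fasta <- function(path, exon_span = c(0L, 207L), frame_offset = 0L) {
  ss <- Biostrings::readDNAStringSet(path)
  mhc_catalog(tibble::tibble(allele_id = names(ss), sequence = as.character(ss)),
              exon_span = exon_span, frame_offset = frame_offset)
}

#' @rdname read_allele_fasta
#' @export
write_allele_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  ss <- Biostrings::DNAStringSet(setNames(catalog$sequence, catalog$allele_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
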