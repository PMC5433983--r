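#' Unbiased haplotype (gene) diversity
#'
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} over gene-copy
#' counts, the small-sample-corrected probability that two copies drawn
#' without replacement carry different alleles. The same quantity serves as
#' unbiased expected heterozygosity when computed on a diploid site's allele
#' counts.
#'
#' @param counts Non-negative per-allele gene-copy counts (one population).
#' @return Haplotype diversity in \[0, 1\].
#' @export
#' @examples
#' haplotype_diversity(c(3, 9, 10, 6, 1, 2, 0, 7))  # 0.82788
haplotype_diversity <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n <- sum(counts)
  if (n < 2) abort("Haplotype diversity is undefined for fewer than 2 copies.")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Sequence-level diversity descriptors for one population
#'
#' From the allele catalog and the population's per-allele copy counts:
#' `S`, the number of alignment columns polymorphic among alleles actually
#' present; `k`, the mean number of nucleotide differences over all
#' \eqn{\binom{n}{2}} copy pairs; and `pi = k / L`, the nucleotide
#' diversity per site (L = alignment length).
#'
#' @param catalog An [mhc_catalog()] (aligned, equal-length sequences).
#' @param counts Per-allele copy counts, either named by `allele_id` or in
#'   catalog order.
#' @return Tibble with columns `S`, `k`, `pi`.
#' @export
nucleotide_stats <- function(catalog, counts) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  counts <- align_counts(counts, catalog$allele_id)
  n <- sum(counts)
  if (n < 2) abort("Need at least 2 gene copies.")
  L <- nchar(catalog$sequence[1])
  present <- counts > 0
  m <- seq_to_mat(catalog$sequence[present])
  S <- if (sum(present) < 2) 0L else
    sum(apply(m, 2, function(col) length(unique(col)) > 1L))
  d <- allele_diff_matrix(catalog)
  cc <- outer(counts, counts)
  k <- sum(cc * d) / 2 / choose(n, 2)
  tibble::tibble(S = as.integer(S), k = k, pi = k / L)
}

align_counts <- function(counts, ids) {
  if (!is.null(names(counts))) {
    missing <- setdiff(names(counts), ids)
    if (length(missing)) abort(paste("Unknown alleles:", paste(missing, collapse = ", ")))
    out <- setNames(numeric(length(ids)), ids)
    out[names(counts)] <- counts
    out
  } else {
    if (length(counts) != length(ids)) {
      abort("`counts` must match the catalog allele count (or be named).")
    }
    setNames(as.numeric(counts), ids)
  }
}

#' Observed and expected heterozygosity per site
#'
#' `H_obs` is the fraction of diploid individuals carrying two distinct
#' alleles; `H_exp` is the unbiased gene diversity
#' \eqn{\frac{n_c}{n_c-1}(1-\sum p_i^2)} from the site's gene-copy counts.
#'
#' @param genotypes Genotype tibble: either [call_genotypes()] output
#'   (list-column `alleles`, `ok` rows used) or a truth-style table with
#'   `allele1`/`allele2` columns; must include `site_code`.
#' @return Tibble with one row per site: `site_code`, `n`, `H_obs`, `H_exp`.
#' @export
heterozygosities <- function(genotypes) {
  g <- normalize_genotypes(genotypes)
  g |>
    dplyr::group_by(.data$site_code) |>
    dplyr::summarise(
      n = dplyr::n(),
      H_obs = mean(.data$a1 != .data$a2),
      H_exp = haplotype_diversity(table(c(.data$a1, .data$a2))),
      .groups = "drop")
}

# accept either list-column genotypes (ok only) or allele1/allele2 columns
normalize_genotypes <- function(genotypes) {
  if ("alleles" %in% names(genotypes)) {
    g <- genotypes[genotypes$flag == "ok", , drop = FALSE]
    tibble::tibble(
      individual_id = g$individual_id,
      site_code = g$site_code,
      a1 = purrr::map_chr(g$alleles, 1),
      a2 = purrr::map_chr(g$alleles, function(a) a[[length(a)]]))
  } else if (all(c("allele1", "allele2") %in% names(genotypes))) {
    tibble::tibble(individual_id = genotypes$individual_id,
                   site_code = genotypes$site_code,
                   a1 = genotypes$allele1, a2 = genotypes$allele2)
  } else if (all(c("a1", "a2") %in% names(genotypes))) {
    genotypes[, intersect(c("individual_id", "site_code", "river", "a1", "a2"),
                          names(genotypes))]
  } else {
    abort("Unrecognised genotype table layout.")
  }
}

#' Which alleles are shared between upstream and downstream groups?
#'
#' Counts distinct alleles present (count > 0) in each group's pooled sites
#' and in both.
#'
#' @param counts An allele-count tibble (one row per site, one column per
#'   allele) including the grouping column.
#' @param group Name of the grouping column (default `"position"`); it must
#'   have exactly two levels and no missing values.
#' @return One-row tibble: the two group labels with their allele totals,
#'   and `n_shared`.
#' @export
allele_sharing <- function(counts, group = "position") {
  if (!group %in% names(counts)) abort("input error: grouping column not found.")
  gv <- counts[[group]]
  if (anyNA(gv)) abort("input error: unlabeled site in grouping column.")
  lev <- unique(gv)
  if (length(lev) != 2L) abort("Grouping must have exactly two levels.")
  ac <- allele_columns(counts)
  present <- function(g) {
    cols <- counts[gv == g, ac, drop = FALSE]
    ac[colSums(cols) > 0]
  }
  s1 <- present(lev[1]); s2 <- present(lev[2])
  out <- tibble::tibble(n1 = length(s1), n2 = length(s2),
                        n_shared = length(intersect(s1, s2)))
  names(out)[1:2] <- paste0("n_", lev)
  out
}

allele_columns <- function(counts) {
  setdiff(names(counts),
          c("site_code", "site", "location", "river", "position", "total"))
}

#' Pool sites in an allele-count table
#'
#' Sums the allele counts of several sites into single rows, e.g. combining
#' two sparsely sampled sites on the same river before computing diversity.
#'
#' @param counts Allele-count tibble.
#' @param groups Named list: new site label -> character vector of
#'   `site_code`s to pool. Unlisted sites pass through unchanged.
#' @return Allele-count tibble with pooled rows.
#' @export
pool_counts <- function(counts, groups) {
  ac <- allele_columns(counts)
  pooled <- purrr::imap_dfr(groups, function(sites, label) {
    rows <- counts[counts$site_code %in% sites, , drop = FALSE]
    if (nrow(rows) == 0L) abort(paste("No sites found for pool", label))
    out <- rows[1, , drop = FALSE]
    out$site_code <- label
    if ("location" %in% names(out)) out$location <- label
    if ("position" %in% names(out) && length(unique(rows$position)) > 1L) {
      out$position <- NA_character_
    }
    out[ac] <- as.list(colSums(rows[ac]))
    if ("total" %in% names(out)) out$total <- sum(rows$total)
    out
  })
  rest <- counts[!counts$site_code %in% unlist(groups), , drop = FALSE]
  dplyr::bind_rows(rest, pooled)
}

#' Per-population diversity summary table
#'
#' One row per site of the count table: sample size `n` (diploids), number
#' of distinct alleles `h`, haplotype diversity `H_d`, and - when a catalog
#' is supplied - segregating sites `S`, mean pairwise differences `k` and
#' nucleotide diversity `pi`; `H_exp` equals `H_d`; `H_obs` and the exact
#' Hardy-Weinberg p-value are added when genotypes are supplied.
#'
#' @param counts Allele-count tibble (`site_code`, allele columns, `total`).
#' @param catalog Optional [mhc_catalog()] for the sequence-level statistics.
#' @param genotypes Optional genotype tibble for `H_obs` and the HWE test.
#' @param hwe_args List of arguments passed on to [hwe_exact_test()].
#' @return Tibble, one row per site.
#' @export
diversity_summary <- function(counts, catalog = NULL, genotypes = NULL,
                              hwe_args = list()) {
  ac <- allele_columns(counts)
  res <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    cc <- setNames(as.numeric(unlist(counts[i, ac])), ac)
    n_c <- sum(cc)
    row <- tibble::tibble(site_code = counts$site_code[i],
                          n = n_c / 2,
                          h = sum(cc > 0),
                          H_d = haplotype_diversity(cc))
    if (!is.null(catalog)) row <- dplyr::bind_cols(row, nucleotide_stats(catalog, cc))
    row$H_exp <- row$H_d
    row
  })
  if (!is.null(genotypes)) {
    het <- heterozygosities(genotypes)
    res <- dplyr::left_join(res, het[, c("site_code", "H_obs")], by = "site_code")
    g <- normalize_genotypes(genotypes)
    res$hwe_p <- purrr::map_dbl(res$site_code, function(s) {
      gs <- g[g$site_code == s, , drop = FALSE]
      if (nrow(gs) == 0L) return(NA_real_)
      do.call(hwe_exact_test, c(list(gs$a1, gs$a2), hwe_args))$p_value
    })
  }
  res
}
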