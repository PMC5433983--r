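#' Step 1: identify putative alleles within each sample
#'
#' For each sample, reads are compared all-against-all with a gap-aware edit
#' distance normalised to a p-distance, the pairwise distance matrix is
#' clustered by average linkage (UPGMA, multiplicity-weighted), and the
#' dendrogram is cut wherever an internal branch - the difference between a
#' node's merge height and its parent's - is at least `min_branch`
#' (default 0.1 substitutions per site). Each resulting cluster emits a
#' consensus sequence (per-column weighted majority over reads of the
#' cluster's modal length, ties broken alphabetically) supported by the
#' cluster's read count. Clusters supported by fewer than `min_reads` reads
#' are presumed to be sequencing error and dropped. Because two alleles can
#' diverge by less than `min_branch` and then share one cluster, each
#' cluster additionally reports any exact read sequence carrying at least
#' 10% of the cluster's reads that differs from the consensus - the
#' signature of a heterozygote's minority allele, far above what repeated
#' sequencing errors attain; the cross-sample support filter in
#' [build_allele_catalog()] then separates real alleles from artefacts.
#'
#' @param reads Read tibble from [sim_reads()] (columns `individual_id`,
#'   `reads`; `site_code`/`depth` carried through if present).
#' @param min_branch Minimum internal branch length (p-distance units) for a
#'   split to be kept; must be > 0.
#' @param min_reads Minimum absolute read support per putative allele.
#' @param max_unique Cap on distinct read sequences entered into the distance
#'   matrix per sample (most abundant kept) to bound the O(u^2) alignment
#'   cost at extreme depths.
#' @return Tibble with columns `individual_id`, `sequence`, `support`.
#' @export
call_putative_alleles <- function(reads, min_branch = 0.1, min_reads = 2L,
                                  max_unique = 400L) {
  if (!is.numeric(min_branch) || min_branch <= 0) abort("`min_branch` must be > 0.")
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    rs <- reads$reads[[i]]
    if (length(rs) == 0L) abort("input error: empty read set.")
    cl <- cluster_reads(rs, min_branch, max_unique)
    cl <- cl[cl$support >= min_reads, , drop = FALSE]
    if (nrow(cl) == 0L) return(NULL)
    tibble::tibble(individual_id = reads$individual_id[i],
                   sequence = cl$sequence, support = cl$support)
  })
}

# cluster one sample's reads; returns data.frame(sequence, support)
# Unique sequences seen only once are dropped before clustering when
# anything else remains (singleton reads are presumed errors and can never
# reach the 2-read support floor on their own); this also bounds the cost
# of the all-pairs distance matrix.
cluster_reads <- function(rs, min_branch, max_unique = 400L) {
  tab <- sort(table(rs), decreasing = TRUE)
  uniq <- names(tab)
  wt <- as.integer(tab)
  if (any(wt >= 2L)) {
    uniq <- uniq[wt >= 2L]
    wt <- wt[wt >= 2L]
  }
  if (length(uniq) > max_unique) {
    uniq <- uniq[seq_len(max_unique)]
    wt <- wt[seq_len(max_unique)]
  }
  u <- length(uniq)
  if (u == 1L) {
    return(data.frame(sequence = uniq, support = wt))
  }
  ed <- read_dist(uniq)
  len <- nchar(uniq)
  pd <- ed / outer(len, len, function(a, b) (a + b) / 2)
  hc <- hclust(as.dist(pd), method = "average", members = wt)
  grp <- cut_min_branch(hc, min_branch)
  out <- lapply(split(seq_len(u), grp), function(idx) {
    cons <- weighted_consensus(uniq[idx], wt[idx])
    res <- data.frame(sequence = cons, support = sum(wt[idx]))
    # a cluster can hold two alleles that diverge by less than min_branch:
    # also emit exact sequences carrying a substantial share (>= 10%) of the
    # cluster's reads, so a heterozygote's minority allele is not silenced
    # by the majority consensus; sequencing-error variants never reach
    # this share at realistic error rates
    floor_n <- max(2L, ceiling(0.1 * sum(wt[idx])))
    extra <- idx[wt[idx] >= floor_n & uniq[idx] != cons]
    if (length(extra)) {
      res <- rbind(res, data.frame(sequence = uniq[extra],
                                   support = wt[extra]))
    }
    res
  })
  out <- do.call(rbind, out)
  # distinct within a sample: merge clusters that converged to one consensus
  agg <- tapply(out$support, out$sequence, sum)
  data.frame(sequence = names(agg), support = as.integer(agg),
             row.names = NULL)[order(-as.integer(agg), names(agg)), , drop = FALSE]
}

# Gap-aware edit-distance matrix over unique reads, with a fast Hamming
# path for pairs of equal length (the vast majority; indel-bearing reads
# are the minority under the homopolymer error model).
read_dist <- function(uniq) {
  u <- length(uniq)
  len <- nchar(uniq)
  d <- matrix(0, u, u)
  for (L in unique(len)) {
    ix <- which(len == L)
    if (length(ix) > 1L) {
      M <- matrix(utf8ToInt(paste(uniq[ix], collapse = "")),
                  nrow = length(ix), ncol = L, byrow = TRUE)
      h <- matrix(0, length(ix), length(ix))
      for (j in seq_len(L)) h <- h + outer(M[, j], M[, j], "!=")
      d[ix, ix] <- h
    }
  }
  lens <- unique(len)
  if (length(lens) > 1L) {
    for (a in seq_along(lens)[-length(lens)]) for (b in (a + 1L):length(lens)) {
      ia <- which(len == lens[a]); ib <- which(len == lens[b])
      d[ia, ib] <- adist(uniq[ia], uniq[ib])
      d[ib, ia] <- t(d[ia, ib, drop = FALSE])
    }
  }
  d
}

# Cut a dendrogram by collapsing internal branches shorter than min_branch:
# an edge from a merge node to a child survives (separates) only if
# parent height - child height >= min_branch; leaves grouped by the
# connected components of collapsed edges.
cut_min_branch <- function(hc, min_branch) {
  n <- length(hc$order)
  parent <- integer(n + n - 1L)            # node ids: leaves 1..n, merges n+m
  height <- c(rep(0, n), hc$height)
  for (m in seq_len(n - 1L)) {
    for (ch in hc$merge[m, ]) {
      id <- if (ch < 0L) -ch else n + ch
      parent[id] <- n + m
    }
  }
  # union-find over collapsed (short) edges
  uf <- seq_len(n + n - 1L)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  for (id in seq_len(n + n - 2L)) {
    p <- parent[id]
    if (p > 0L && (height[p] - height[id]) < min_branch) {
      uf[find(id)] <- find(p)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# per-column majority over reads of the modal (weight-dominant) length
weighted_consensus <- function(seqs, wt) {
  len <- nchar(seqs)
  mode_len <- as.integer(names(which.max(tapply(wt, len, sum))))
  keep <- len == mode_len
  seqs <- seqs[keep]; wt <- wt[keep]
  if (length(seqs) == 1L) return(seqs)
  m <- seq_to_mat(seqs)
  cols <- vapply(seq_len(ncol(m)), function(j) {
    sc <- tapply(wt, m[, j], sum)
    sc <- sort(sc, decreasing = TRUE)
    top <- names(sc)[sc == sc[1]]
    sort(top)[1]                     # alphabetical tie-break: deterministic
  }, "")
  paste(cols, collapse = "")
}

#' Step 2: pool putative alleles across samples into a consensus catalog
#'
#' Putative allele sequences from all samples are grouped by exact identity;
#' a group becomes a catalog allele when it was seen in at least
#' `min_support_samples` distinct samples, or in any single sample when
#' `allow_singletons = TRUE` (the rerun mode that guards against biasing the
#' catalog against rare alleles). Allele ids are assigned in order of
#' decreasing total read support.
#'
#' @param putative Tibble from [call_putative_alleles()] pooled over samples.
#' @param min_support_samples Distinct-sample support required per allele.
#' @param allow_singletons If `TRUE`, sequences seen in only one sample are
#'   retained as alleles.
#' @inheritParams mhc_catalog
#' @return An [mhc_catalog()].
#' @export
build_allele_catalog <- function(putative, min_support_samples = 2L,
                                 allow_singletons = FALSE,
                                 exon_span = c(0L, 207L), frame_offset = 0L) {
  if (nrow(putative) == 0L) abort("empty-catalog error: no putative alleles.")
  need <- if (allow_singletons) 1L else as.integer(min_support_samples)
  grp <- putative |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$individual_id),
                     support = sum(.data$support), .groups = "drop") |>
    dplyr::filter(.data$n_samples >= need) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$sequence)
  if (nrow(grp) == 0L) {
    abort("empty-catalog error: no putative allele met the sample-support threshold.")
  }
  mhc_catalog(tibble::tibble(allele_id = paste0("A", seq_len(nrow(grp))),
                             sequence = grp$sequence),
              exon_span = exon_span, frame_offset = frame_offset)
}

#' Step 3: assign genotypes by matching reads to catalog alleles
#'
#' Each read is matched to its nearest catalog allele by edit distance; reads
#' equidistant from several alleles contribute equal fractional weight to
#' each, so fractions stay normalised and the rule is deterministic. Alleles
#' whose read fraction reaches `min_fraction` (default 20%) are called.
#' Samples with more than two passing alleles are flagged `ambiguous`, with
#' none `failed`; samples below `min_depth` reads are flagged `failed`
#' without genotyping.
#'
#' @param reads Read tibble from [sim_reads()].
#' @param catalog An [mhc_catalog()].
#' @param min_fraction Read-fraction threshold in (0, 1) for calling an allele.
#' @param min_depth Minimum read depth for attempting a genotype.
#' @return Genotype tibble with columns `individual_id`, `site_code`,
#'   `alleles` (list of called allele ids), `fractions` (list of the called
#'   alleles' read fractions) and `flag` (`ok` / `ambiguous` / `failed`).
#' @export
call_genotypes <- function(reads, catalog, min_fraction = 0.2, min_depth = 20L) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  if (nrow(catalog) == 0L) abort("Catalog is empty.")
  assert_prob(min_fraction, "min_fraction", lo_open = TRUE, hi_open = TRUE)
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    rs <- reads$reads[[i]]
    base <- tibble::tibble(
      individual_id = reads$individual_id[i],
      site_code = if ("site_code" %in% names(reads)) reads$site_code[i] else NA_character_)
    if (length(rs) < min_depth) {
      return(dplyr::mutate(base, alleles = list(character()),
                           fractions = list(numeric()), flag = "failed"))
    }
    fr <- read_fractions(rs, catalog)
    called <- names(fr)[fr >= min_fraction]
    flag <- if (length(called) == 0L) "failed"
            else if (length(called) > 2L) "ambiguous" else "ok"
    dplyr::mutate(base, alleles = list(called),
                  fractions = list(fr[called]), flag = flag)
  })
}

# per-allele read fractions for one sample (tie reads split evenly)
read_fractions <- function(rs, catalog) {
  tab <- table(rs)
  uniq <- names(tab)
  wt <- as.numeric(tab)
  L <- nchar(catalog$sequence[1])
  same <- nchar(uniq) == L
  d <- matrix(0, length(uniq), nrow(catalog))
  if (any(same)) {
    M <- matrix(utf8ToInt(paste(uniq[same], collapse = "")),
                nrow = sum(same), ncol = L, byrow = TRUE)
    A <- matrix(utf8ToInt(paste(catalog$sequence, collapse = "")),
                nrow = nrow(catalog), ncol = L, byrow = TRUE)
    h <- matrix(0, sum(same), nrow(catalog))
    for (j in seq_len(L)) h <- h + outer(M[, j], A[, j], "!=")
    d[same, ] <- h
  }
  if (any(!same)) d[!same, ] <- adist(uniq[!same], catalog$sequence)
  w <- matrix(0, length(uniq), nrow(catalog))
  for (k in seq_along(uniq)) {
    best <- which(d[k, ] == min(d[k, ]))
    w[k, best] <- wt[k] / length(best)
  }
  fr <- colSums(w) / sum(wt)
  setNames(fr, catalog$allele_id)
}

#' Repeatability from duplicate samples
#'
#' Fraction (as a percentage) of replicate pairs whose unordered called
#' allele sets agree between the two independent amplifications. Discordant
#' pairs are listed so they can be excluded from downstream statistics.
#'
#' @param genotypes Genotype tibble from [call_genotypes()].
#' @param pairs Tibble with columns `individual_id`, `replicate_id`.
#' @return Object of class `mhc_repeatability`: list with `rate` (percent),
#'   `n_pairs`, `n_discordant` and `discordant` (tibble of failing pairs).
#' @export
#' @examples
#' g <- tibble::tibble(individual_id = c("a", "a_rep"), site_code = "S",
#'                     alleles = list(c("A1", "A2"), c("A2", "A1")),
#'                     fractions = list(c(.5, .5), c(.5, .5)), flag = "ok")
#' estimate_repeatability(g, tibble::tibble(individual_id = "a",
#'                                          replicate_id = "a_rep"))$rate
estimate_repeatability <- function(genotypes, pairs) {
  if (nrow(pairs) == 0L) abort("input error: no replicate pairs.")
  idx1 <- match(pairs$individual_id, genotypes$individual_id)
  idx2 <- match(pairs$replicate_id, genotypes$individual_id)
  if (anyNA(idx1) || anyNA(idx2)) {
    abort("input error: replicate pair member missing from the genotype table.")
  }
  same <- vapply(seq_len(nrow(pairs)), function(k) {
    setequal(genotypes$alleles[[idx1[k]]], genotypes$alleles[[idx2[k]]])
  }, TRUE)
  structure(list(rate = 100 * mean(same),
                 n_pairs = nrow(pairs),
                 n_discordant = sum(!same),
                 discordant = pairs[!same, , drop = FALSE]),
            class = "mhc_repeatability")
}

#' @export
print.mhc_repeatability <- function(x, ...) {
  cat(sprintf("Repeatability: %.1f%% (%d of %d replicate pairs concordant)\n",
              x$rate, x$n_pairs - x$n_discordant, x$n_pairs))
  if (x$n_discordant > 0) {
    cat("Discordant pairs (excluded downstream):\n")
    print(x$discordant)
  }
  invisible(x)
}

#' Collapse called genotypes into a site-by-allele copy-count table
#'
#' Only `ok`-flagged genotypes are counted; single-allele calls count as
#' homozygotes (2 copies). Individuals named in `exclude` (for example
#' discordant replicate pairs) and replicate re-runs themselves (ids present
#' in `replicate_ids`) are dropped first.
#'
#' @param genotypes Genotype tibble from [call_genotypes()].
#' @param meta Optional tibble `site_code`, `river`, `position` to label sites.
#' @param exclude Character vector of individual ids to drop.
#' @param replicate_ids Character vector of replicate-run ids to drop.
#' @return An allele-count tibble (`site_code`, `river`, `position`, one
#'   column per allele, `total`), as accepted by the diversity statistics.
#' @export
genotypes_to_counts <- function(genotypes, meta = NULL, exclude = character(),
                                replicate_ids = character()) {
  g <- genotypes |>
    dplyr::filter(.data$flag == "ok",
                  !.data$individual_id %in% c(exclude, replicate_ids))
  long <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    al <- g$alleles[[i]]
    if (length(al) == 1L) al <- rep(al, 2L)
    tibble::tibble(site_code = g$site_code[i], allele = al)
  })
  wide <- long |>
    dplyr::count(.data$site_code, .data$allele) |>
    tidyr::pivot_wider(names_from = "allele", values_from = "n",
                       values_fill = 0L)
  allele_cols <- setdiff(names(wide), "site_code")
  wide <- wide[, c("site_code", sort(allele_cols))]
  wide$total <- rowSums(wide[sort(allele_cols)])
  if (!is.null(meta)) {
    wide <- dplyr::left_join(meta, wide, by = "site_code")
    wide$total[is.na(wide$total)] <- 0L
    wide[is.na(wide)] <- 0L
  }
  tibble::as_tibble(wide)
}
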