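#' Simulate an MHC amplicon allele catalog
#'
#' Builds `n_alleles` distinct amplicon haplotypes that differ at exactly
#' `n_segregating` biallelic positions. The exon part is assembled from sense
#' codons and variants are rejected if they introduce an internal stop codon,
#' so the catalog is always usable for codon-level selection statistics. At
#' least one segregating position falls in the exon and changes the encoded
#' amino acid in at least one allele. The default geometry mirrors the
#' 236-bp class II beta amplicon: a 207-bp exon segment plus a 29-bp intron
#' tail, with around 16 segregating sites for an eight-allele pool.
#'
#' @param n_alleles Number of alleles (>= 2).
#' @param exon_len Exon length in bp; must leave whole codons after
#'   `frame_offset` trimming.
#' @param intron_len Intron length in bp (>= 0).
#' @param n_segregating Number of polymorphic positions among the alleles.
#' @param seed Integer RNG seed; identical seeds give byte-identical catalogs.
#' @param frame_offset Codon frame of the exon's first base (0-2).
#' @return An [mhc_catalog()] with alleles `A1..An`.
#' @export
#' @examples
#' cat8 <- sim_allele_catalog(8, 207, 29, 16, seed = 1)
#' nrow(cat8)
sim_allele_catalog <- function(n_alleles, exon_len = 207L, intron_len = 29L,
                               n_segregating = 16L, seed = 1L,
                               frame_offset = 0L) {
  n_alleles <- as.integer(n_alleles)
  exon_len <- as.integer(exon_len)
  intron_len <- as.integer(intron_len)
  n_segregating <- as.integer(n_segregating)
  if (n_alleles < 2L) abort("`n_alleles` must be at least 2.")
  if ((exon_len - frame_offset) %% 3L != 0L) {
    abort("`exon_len` must be divisible into codons after `frame_offset` trimming.")
  }
  L <- exon_len + intron_len
  if (n_segregating < 1L || n_segregating > L) {
    abort("`n_segregating` must be between 1 and the amplicon length.")
  }
  if (n_segregating < 31L && n_alleles > 2^n_segregating) {
    abort(sprintf(
      "parameter error: %d alleles cannot be distinct over %d biallelic sites.",
      n_alleles, n_segregating))
  }
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  set.seed(as.integer(seed))
  for (try in seq_len(500L)) {
    n_codon <- (exon_len - frame_offset) %/% 3L
    exon <- paste0(
      paste(sample(BASES, frame_offset, replace = TRUE), collapse = ""),
      paste(sample(sense, n_codon, replace = TRUE), collapse = ""))
    intron <- paste(sample(BASES, intron_len, replace = TRUE), collapse = "")
    ref <- paste0(exon, intron)
    pos <- sort(sample.int(L, n_segregating))
    if (exon_len > 0L && !any(pos <= exon_len)) next
    ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    alt <- vapply(pos, function(p) sample(setdiff(BASES, ref_chars[p]), 1L), "")
    # biallelic haplotype patterns: every column polymorphic by construction
    # (1..n-1 alleles carry the alternate base); rows must be distinct
    pat <- vapply(seq_len(n_segregating), function(s) {
      n_alt <- sample.int(n_alleles - 1L, 1L)
      col <- integer(n_alleles)
      col[sample.int(n_alleles, n_alt)] <- 1L
      col
    }, integer(n_alleles))
    pat <- matrix(pat, nrow = n_alleles)
    if (anyDuplicated(pat) > 0L) next
    seqs <- vapply(seq_len(n_alleles), function(i) {
      ch <- ref_chars
      ch[pos[pat[i, ] == 1L]] <- alt[pat[i, ] == 1L]
      paste(ch, collapse = "")
    }, "")
    catalog <- mhc_catalog(
      tibble::tibble(allele_id = paste0("A", seq_len(n_alleles)), sequence = seqs),
      exon_span = c(0L, exon_len), frame_offset = frame_offset)
    aa <- translate_codons(exon_sequences(catalog))
    if (any(grepl("\\*", aa))) next            # a variant created a stop
    if (length(unique(aa)) < 2L) next          # need a nonsynonymous variant
    return(catalog)
  }
  abort("Could not build a valid catalog for these parameters.")
}

#' Simulate diploid genotypes for one population
#'
#' Draws `n_ind` diploid genotypes from allele frequencies `freqs` with an
#' optional inbreeding-like heterozygote deficit: with probability
#' `inbreeding_f` an individual is made homozygous for an allele drawn from
#' `freqs`; otherwise its two copies are independent draws. This gives
#' P(homozygote i) = f p_i + (1-f) p_i^2 and
#' P(heterozygote ij) = (1-f) 2 p_i p_j.
#'
#' @param catalog An [mhc_catalog()].
#' @param freqs Allele frequency vector (length `nrow(catalog)`, sums to 1).
#' @param n_ind Number of diploid individuals.
#' @param inbreeding_f Heterozygote-deficit parameter in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param site_code,river,position Labels attached to every individual.
#' @return A truth tibble with columns `individual_id`, `site_code`, `river`,
#'   `position`, `allele1`, `allele2`, `replicate_of`.
#' @export
sim_population <- function(catalog, freqs, n_ind, inbreeding_f = 0,
                           seed = 1L, site_code = "S1", river = "R1",
                           position = "upstream") {
  stopifnot(inherits(catalog, "mhc_catalog"))
  if (length(freqs) != nrow(catalog)) {
    abort("`freqs` must have one entry per catalog allele.")
  }
  if (any(freqs < 0)) abort("parameter error: negative allele frequency.")
  if (abs(sum(freqs) - 1) > 1e-9) abort("`freqs` must sum to 1.")
  if (n_ind < 1L) abort("`n_ind` must be at least 1.")
  assert_prob(inbreeding_f, "inbreeding_f")
  ids <- catalog$allele_id
  set.seed(as.integer(seed))
  hom <- runif(n_ind) < inbreeding_f
  a1 <- sample(ids, n_ind, replace = TRUE, prob = freqs)
  a2 <- ifelse(hom, a1, sample(ids, n_ind, replace = TRUE, prob = freqs))
  tibble::tibble(
    individual_id = sprintf("%s_%03d", site_code, seq_len(n_ind)),
    site_code = site_code, river = river, position = position,
    allele1 = a1, allele2 = a2, replicate_of = NA_character_)
}

#' Simulate genotypes for several sites at once
#'
#' Convenience wrapper around [sim_population()]: one row of `layout` per
#' site, with per-site allele frequencies. Per-site seeds are derived from
#' `seed` with [stage_seed()]-style arithmetic so each site is independently
#' reproducible.
#'
#' @param catalog An [mhc_catalog()].
#' @param layout Tibble with columns `site_code`, `river`, `position`, `n_ind`.
#' @param freqs Either one frequency vector recycled to all sites, or a list
#'   of per-site vectors named by `site_code`.
#' @inheritParams sim_population
#' @return Truth tibble (one row per individual) as in [sim_population()].
#' @export
sim_sites <- function(catalog, layout, freqs, inbreeding_f = 0, seed = 1L) {
  layout <- tibble::as_tibble(layout)
  stopifnot(all(c("site_code", "river", "position", "n_ind") %in% names(layout)))
  purrr::pmap_dfr(layout, function(site_code, river, position, n_ind, ...) {
    f <- if (is.list(freqs)) freqs[[site_code]] else freqs
    sim_population(catalog, f, n_ind, inbreeding_f,
                   seed = stage_seed(seed, match(site_code, layout$site_code)),
                   site_code = site_code, river = river, position = position)
  })
}

# Apply the 454-style error model to one template: i.i.d. substitutions,
# then one indel opportunity per homopolymer run of length >= 2 with
# probability hp_indel_rate * (run length - 1), insertion/deletion 50:50.
corrupt_read <- function(chars, sub_rate, hp_indel_rate) {
  if (sub_rate > 0) {
    hit <- which(runif(length(chars)) < sub_rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit],
                           function(b) sample(BASES[BASES != b], 1L), "",
                           USE.NAMES = FALSE)
    }
  }
  if (hp_indel_rate > 0) {
    r <- rle(chars)
    run <- which(r$lengths >= 2L)
    for (k in run) {
      p <- min(1, hp_indel_rate * (r$lengths[k] - 1L))
      if (runif(1) < p) {
        r$lengths[k] <- r$lengths[k] + (if (runif(1) < 0.5) 1L else -1L)
      }
    }
    chars <- inverse.rle(r)
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon reads for genotyped individuals
#'
#' Every read is a copy of one of the individual's true alleles (the first
#' allele is chosen with probability `allele_balance` for heterozygotes),
#' corrupted by i.i.d. substitutions at `sub_rate` and homopolymer
#' single-base indels at `hp_indel_rate` per run (scaled by run length).
#' With `depth = NULL` the per-sample depth is drawn log-uniformly from
#' \[101, 14027\], the depth range typical of one-way 454 amplicon runs;
#' a scalar or per-individual vector overrides it.
#'
#' @param truth Truth tibble from [sim_population()] / [sim_sites()].
#' @param catalog The [mhc_catalog()] the genotypes refer to.
#' @param depth `NULL`, a scalar, or a vector of per-individual read depths.
#' @param sub_rate Per-base substitution probability in \[0, 1).
#' @param hp_indel_rate Per-homopolymer-run indel rate in \[0, 1).
#' @param allele_balance Probability a heterozygote read comes from `allele1`.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `individual_id`, `site_code`, `depth` and a
#'   list-column `reads` of character vectors.
#' @export
sim_reads <- function(truth, catalog, depth = NULL, sub_rate = 0.005,
                      hp_indel_rate = 0.005, allele_balance = 0.5, seed = 1L) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  assert_prob(sub_rate, "sub_rate", hi_open = TRUE)
  assert_prob(hp_indel_rate, "hp_indel_rate", hi_open = TRUE)
  assert_prob(allele_balance, "allele_balance", lo_open = TRUE, hi_open = TRUE)
  n <- nrow(truth)
  seqs <- setNames(catalog$sequence, catalog$allele_id)
  if (!all(c(truth$allele1, truth$allele2) %in% names(seqs))) {
    abort("Truth records reference alleles missing from the catalog.")
  }
  set.seed(as.integer(seed))
  depths <- if (is.null(depth)) {
    as.integer(round(exp(runif(n, log(101), log(14027)))))
  } else {
    d <- as.integer(rep_len(depth, n))
    if (any(d < 1L)) abort("`depth` must be at least 1.")
    d
  }
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    d <- depths[i]
    from1 <- if (truth$allele1[i] == truth$allele2[i]) rep(TRUE, d)
             else runif(d) < allele_balance
    src <- ifelse(from1, truth$allele1[i], truth$allele2[i])
    tpl <- strsplit(seqs[c(truth$allele1[i], truth$allele2[i])], "", fixed = TRUE)
    names(tpl) <- c(truth$allele1[i], truth$allele2[i])
    reads[[i]] <- vapply(src, function(a)
      corrupt_read(tpl[[a]], sub_rate, hp_indel_rate), "", USE.NAMES = FALSE)
  }
  tibble::tibble(individual_id = truth$individual_id,
                 site_code = truth$site_code,
                 depth = depths, reads = reads)
}

#' Re-amplify a fraction of samples as technical replicates
#'
#' Picks `round(fraction * n)` individuals and simulates an independent
#' second read set for each (fresh error draws, same underlying genotype),
#' mirroring duplicate amplification used to estimate repeatability.
#' Replicates get the suffix `_rep` and a `replicate_of` link.
#'
#' @param reads Read tibble from [sim_reads()].
#' @param truth Matching truth tibble.
#' @inheritParams sim_reads
#' @param fraction Fraction of individuals to duplicate in \[0, 1\].
#' @return List with elements `reads` (original + replicate read sets),
#'   `truth` (original + replicate truth rows) and `pairs`
#'   (tibble `individual_id`, `replicate_id`).
#' @export
sim_duplicates <- function(reads, truth, catalog, fraction, seed = 1L,
                           sub_rate = 0.005, hp_indel_rate = 0.005,
                           allele_balance = 0.5) {
  assert_prob(fraction, "fraction")
  n_dup <- round(fraction * nrow(reads))
  if (n_dup == 0L) {
    return(list(reads = reads, truth = truth,
                pairs = tibble::tibble(individual_id = character(),
                                       replicate_id = character())))
  }
  set.seed(stage_seed(seed, 1L))
  chosen <- sort(sample(truth$individual_id, n_dup))
  truth_rep <- truth[match(chosen, truth$individual_id), ]
  truth_rep$replicate_of <- truth_rep$individual_id
  truth_rep$individual_id <- paste0(truth_rep$individual_id, "_rep")
  depth_rep <- reads$depth[match(chosen, reads$individual_id)]
  reads_rep <- sim_reads(truth_rep, catalog, depth = depth_rep,
                         sub_rate = sub_rate, hp_indel_rate = hp_indel_rate,
                         allele_balance = allele_balance,
                         seed = stage_seed(seed, 2L))
  list(reads = dplyr::bind_rows(reads, reads_rep),
       truth = dplyr::bind_rows(truth, truth_rep),
       pairs = tibble::tibble(individual_id = chosen,
                              replicate_id = paste0(chosen, "_rep")))
}
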