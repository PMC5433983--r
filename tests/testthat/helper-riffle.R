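# shared fixtures, all built in code

# tiny hand-built catalog: 4-base amplicon, 3-base exon
tiny_catalog <- function(seqs = c(A1 = "AAAA", A2 = "AAAT")) {
  mhc_catalog(tibble::tibble(allele_id = names(seqs), sequence = unname(seqs)),
              exon_span = c(0L, 3L), frame_offset = 0L)
}

# a 2-allele catalog whose alleles diverge at >10% of sites, so that the
# within-sample dendrogram separates a heterozygote's two alleles
divergent_pair_catalog <- function() {
  sim_allele_catalog(n_alleles = 2, exon_len = 30, intron_len = 6,
                     n_segregating = 12, seed = 42)
}

study_catalog <- function() sim_allele_catalog(8, 207, 29, 16, seed = 1)

# per-site frequencies and layout mirroring the bundled six-site survey
study_freqs <- function(counts = dace_mhc_counts()) {
  ac <- allele_columns(counts)
  f <- lapply(seq_len(nrow(counts)), function(i) {
    cc <- as.numeric(unlist(counts[i, ac]))
    cc / sum(cc)
  })
  names(f) <- counts$site_code
  f
}

study_layout <- function(counts = dace_mhc_counts(),
                         n_ind = c(20L, 17L, 20L, 19L, 1L, 18L)) {
  tibble::tibble(site_code = counts$site_code, river = counts$river,
                 position = counts$position, n_ind = n_ind)
}

# fraction of individuals whose called genotype (mapped back to true allele
# ids through the sequences) matches the simulated truth
recovery_rate <- function(genotypes, truth, true_catalog, called_catalog) {
  gt <- genotypes[genotypes$flag == "ok" &
                    genotypes$individual_id %in% truth$individual_id, ]
  seq_of <- setNames(called_catalog$sequence, called_catalog$allele_id)
  id_of <- setNames(true_catalog$allele_id, true_catalog$sequence)
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    row <- gt[gt$individual_id == truth$individual_id[i], ]
    if (nrow(row) != 1L) return(FALSE)
    al <- row$alleles[[1]]
    if (length(al) == 1L) al <- rep(al, 2L)
    called <- unname(id_of[seq_of[al]])
    if (anyNA(called)) return(FALSE)
    setequal_pair(called, c(truth$allele1[i], truth$allele2[i]))
  }, TRUE)
  mean(hits)
}

setequal_pair <- function(a, b) identical(sort(a), sort(b))

# random unordered genotype draws for HWE fixtures
random_genotypes <- function(n, freqs, seed) {
  set.seed(seed)
  alleles <- names(freqs) %||% paste0("a", seq_along(freqs))
  list(a1 = sample(alleles, n, TRUE, prob = freqs),
       a2 = sample(alleles, n, TRUE, prob = freqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
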