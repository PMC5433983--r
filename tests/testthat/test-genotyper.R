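test_that("identical reads collapse to one putative allele with full support", {
  rd <- tibble::tibble(individual_id = "x", site_code = "S",
                       depth = 40L, reads = list(rep("ACGTACGT", 40)))
  put <- call_putative_alleles(rd)
  expect_equal(nrow(put), 1L)
  expect_equal(put$sequence, "ACGTACGT")
  expect_equal(put$support, 40L)
})

test_that("reads from two 20%-divergent templates split into two clusters", {
  set.seed(1)
  x <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  xc <- strsplit(x, "")[[1]]
  pos <- sample(100, 20)
  yc <- xc
  yc[pos] <- vapply(xc[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  y <- paste(yc, collapse = "")
  rd <- tibble::tibble(individual_id = "x", site_code = "S", depth = 100L,
                       reads = list(c(rep(x, 50), rep(y, 50))))
  put <- call_putative_alleles(rd, min_branch = 0.1)
  expect_setequal(put$sequence, c(x, y))
  expect_equal(sort(put$support), c(50L, 50L))
})

test_that("a zero-error heterozygote yields its two alleles as putative alleles", {
  cat2 <- divergent_pair_catalog()   # alleles diverge at >10% of sites
  truth <- tibble::tibble(individual_id = "h1", site_code = "S", river = "R",
                          position = "upstream", allele1 = "A1", allele2 = "A2",
                          replicate_of = NA_character_)
  rd <- sim_reads(truth, cat2, depth = 60, sub_rate = 0, hp_indel_rate = 0,
                  seed = 2)
  put <- call_putative_alleles(rd, min_branch = 0.1)
  expect_setequal(put$sequence, cat2$sequence)
})

test_that("empty read sets are rejected", {
  rd <- tibble::tibble(individual_id = "x", site_code = "S", depth = 0L,
                       reads = list(character()))
  expect_error(call_putative_alleles(rd), "empty read set")
})

test_that("catalog building honours sample support and the singleton rerun", {
  put <- tibble::tibble(
    individual_id = c("a", "b", "c"),
    sequence = c("AAAA", "AAAA", "TTTT"),
    support = c(10L, 12L, 9L))
  strict <- build_allele_catalog(put, min_support_samples = 2,
                                 exon_span = c(0, 3))
  expect_equal(strict$sequence, "AAAA")
  loose <- build_allele_catalog(put, allow_singletons = TRUE,
                                exon_span = c(0, 3))
  expect_setequal(loose$sequence, c("AAAA", "TTTT"))
  only_single <- put[3, ]
  expect_error(build_allele_catalog(only_single, min_support_samples = 2,
                                    exon_span = c(0, 3)),
               "empty-catalog")
})

test_that("singleton toggle leaves the catalog unchanged when all alleles are shared", {
  cat2 <- divergent_pair_catalog()
  truth <- sim_population(cat2, c(0.5, 0.5), 12, seed = 3)
  rd <- sim_reads(truth, cat2, depth = 40, sub_rate = 0, hp_indel_rate = 0,
                  seed = 4)
  put <- call_putative_alleles(rd)
  strict <- build_allele_catalog(put, min_support_samples = 2,
                                 exon_span = attr(cat2, "exon_span"))
  loose <- build_allele_catalog(put, allow_singletons = TRUE,
                                exon_span = attr(cat2, "exon_span"))
  expect_identical(strict, loose)
})

test_that("the 20% rule calls alleles from read fractions", {
  cat3 <- sim_allele_catalog(3, 30, 6, 10, seed = 8)
  mk <- function(n) {
    tibble::tibble(individual_id = "x", site_code = "S", depth = sum(n),
                   reads = list(rep(cat3$sequence, times = n)))
  }
  g <- call_genotypes(mk(c(55, 30, 15)), cat3, min_fraction = 0.2)
  expect_equal(g$flag, "ok")
  expect_setequal(g$alleles[[1]], c("A1", "A2"))
  expect_equal(sort(unname(g$fractions[[1]])), c(0.30, 0.55))
  hom <- call_genotypes(mk(c(100, 0, 0)), cat3, min_fraction = 0.2)
  expect_equal(hom$alleles[[1]], "A1")
  expect_equal(hom$flag, "ok")
  amb <- call_genotypes(mk(c(34, 33, 33)), cat3, min_fraction = 0.2)
  expect_equal(amb$flag, "ambiguous")
})

test_that("low-depth samples are flagged failed, not genotyped", {
  cat3 <- sim_allele_catalog(3, 30, 6, 10, seed = 8)
  rd <- tibble::tibble(individual_id = "x", site_code = "S", depth = 10L,
                       reads = list(rep(cat3$sequence[1], 10)))
  g <- call_genotypes(rd, cat3, min_depth = 20)
  expect_equal(g$flag, "failed")
  expect_length(g$alleles[[1]], 0L)
})

test_that("raising min_fraction never increases the number of called alleles", {
  cat4 <- sim_allele_catalog(4, 30, 6, 8, seed = 5)
  set.seed(42)
  for (rep in 1:5) {
    n <- as.integer(rmultinom(1, 100, runif(4)))
    rd <- tibble::tibble(individual_id = "x", site_code = "S", depth = 100L,
                         reads = list(rep(cat4$sequence, times = n)))
    n_called <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(f) {
      length(call_genotypes(rd, cat4, min_fraction = f)$alleles[[1]])
    }, 0L)
    expect_true(all(diff(n_called) <= 0L))
  }
})

test_that("called genotypes stay inside the catalog with at most two alleles", {
  cat8 <- study_catalog()
  truth <- sim_sites(cat8, study_layout(n_ind = c(6L, 6L, 6L, 6L, 1L, 6L)),
                     study_freqs(), seed = 21)
  rd <- sim_reads(truth, cat8, depth = 80, sub_rate = 0.005,
                  hp_indel_rate = 0.005, seed = 22)
  put <- call_putative_alleles(rd)
  cc <- build_allele_catalog(put, exon_span = c(0, 207))
  g <- call_genotypes(rd, cc)
  ok <- g[g$flag == "ok", ]
  expect_true(all(lengths(ok$alleles) <= 2L))
  expect_true(all(unlist(ok$alleles) %in% cc$allele_id))
  expect_true(all(unlist(ok$fractions) >= 0.2))
})

test_that("zero-error synthetic data is genotyped back to truth exactly", {
  cat8 <- study_catalog()
  truth <- sim_sites(cat8, study_layout(n_ind = c(8L, 8L, 8L, 8L, 1L, 8L)),
                     study_freqs(), seed = 31)
  rd <- sim_reads(truth, cat8, depth = 60, sub_rate = 0, hp_indel_rate = 0,
                  seed = 32)
  put <- call_putative_alleles(rd)
  cc <- build_allele_catalog(put, exon_span = c(0, 207))
  g <- call_genotypes(rd, cc)
  expect_equal(recovery_rate(g, truth, cat8, cc), 1)
})

test_that("repeatability arithmetic matches direct counts", {
  mk_geno <- function(ids, allele_sets) {
    tibble::tibble(individual_id = ids, site_code = "S",
                   alleles = allele_sets,
                   fractions = lapply(allele_sets, function(a)
                     setNames(rep(1 / length(a), length(a)), a)),
                   flag = "ok")
  }
  ids <- c(paste0("i", 1:26), paste0("i", 1:26, "_rep"))
  sets <- c(rep(list(c("A1", "A2")), 26), rep(list(c("A1", "A2")), 26))
  sets[[27]] <- c("A1", "A3")      # one discordant replicate
  g <- mk_geno(ids, sets)
  pairs <- tibble::tibble(individual_id = paste0("i", 1:26),
                          replicate_id = paste0("i", 1:26, "_rep"))
  est <- estimate_repeatability(g, pairs)
  expect_equal(round(est$rate, 1), 96.2)
  expect_equal(est$n_discordant, 1L)
  expect_equal(est$discordant$individual_id, "i1")
  # all concordant and half discordant
  sets[[27]] <- c("A2", "A1")      # unordered comparison
  expect_equal(estimate_repeatability(mk_geno(ids, sets), pairs)$rate, 100)
  sets[2 + 26] <- list("A1"); sets[4 + 26] <- list("A1")
  sets[6 + 26] <- list("A1"); sets[8 + 26] <- list("A1")
  sets[10 + 26] <- list("A1")
  est50 <- estimate_repeatability(mk_geno(ids, sets), pairs[1:10, ])
  expect_equal(est50$rate, 50)
  expect_error(estimate_repeatability(g, tibble::tibble(
    individual_id = "nope", replicate_id = "i1_rep")), "missing")
})
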