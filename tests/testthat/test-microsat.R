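toy_genepop <- function(path) {
  writeLines(c(
    "toy dataset",
    "LocA",
    "LocB",
    "Pop",
    "up_01 ,  101102 0000",
    "up_02 ,  101101 120121",
    "Pop",
    "dn_01 ,  102102 121121",
    "dn_02 ,  101103 120120"), path)
  path
}

test_that("GENEPOP files parse faithfully and round-trip", {
  f <- tempfile(fileext = ".gen")
  on.exit(unlink(f))
  ds <- read_genepop(toy_genepop(f))
  expect_s3_class(ds, "microsat_df")
  expect_equal(length(unique(ds$pop)), 2L)
  expect_equal(unique(ds$locus), c("LocA", "LocB"))
  # 0000 is missing data
  miss <- ds[ds$individual_id == "up_01" & ds$locus == "LocB", ]
  expect_true(is.na(miss$a1) && is.na(miss$a2))
  f2 <- tempfile(fileext = ".gen")
  on.exit(unlink(f2), add = TRUE)
  write_genepop(ds, f2)
  expect_identical(as.data.frame(read_genepop(f2)), as.data.frame(ds))
  bad <- tempfile()
  on.exit(unlink(bad), add = TRUE)
  writeLines(c("t", "LocA", "Pop", "x 101101"), bad)   # missing comma
  expect_error(read_genepop(bad), "line 4")
})

test_that("Weir-Cockerham theta hits the fixation endpoints", {
  mk <- function(a_all, b_all) {
    d <- tibble::tibble(
      pop = rep(c("A", "B"), each = 10),
      individual_id = paste0("i", 1:20),
      locus = "L1",
      a1 = c(rep(a_all, 10), rep(b_all, 10)),
      a2 = c(rep(a_all, 10), rep(b_all, 10)))
    class(d) <- c("microsat_df", class(d))
    d
  }
  expect_equal(wc_fst(mk(101L, 102L)), 1)
  # one panmictic pool: theta near zero, may be negative
  set.seed(8)
  pool <- tibble::tibble(
    pop = rep(c("A", "B"), each = 30),
    individual_id = paste0("i", 1:60),
    locus = rep(c("L1", "L2"), 30),
    a1 = sample(101:104, 60, TRUE), a2 = sample(101:104, 60, TRUE))
  class(pool) <- c("microsat_df", class(pool))
  expect_lt(abs(wc_fst(pool)), 0.15)
  # invariance under allele relabeling
  relab <- pool
  relab$a1 <- relab$a1 + 100L
  relab$a2 <- relab$a2 + 100L
  expect_equal(wc_fst(pool), wc_fst(relab))
})

test_that("haploid-recoded theta equals two-level Phi-ST with 0/1 distances", {
  set.seed(12)
  for (rep in 1:5) {
    g <- tibble::tibble(
      pop = rep(c("P1", "P2"), each = 12),
      individual_id = paste0("x", 1:24),
      locus = "L1",
      a1 = sample(101:103, 24, TRUE, prob = c(0.5, 0.3, 0.2)),
      a2 = sample(101:103, 24, TRUE, prob = c(0.2, 0.5, 0.3)))
    class(g) <- c("microsat_df", class(g))
    theta <- wc_fst(g, ploidy = 1)
    lab <- paste0("A", 101:103)
    d01 <- 1 - diag(3); dimnames(d01) <- list(lab, lab)
    gm <- tibble::tibble(individual_id = g$individual_id, site_code = g$pop,
                         allele1 = paste0("A", g$a1), allele2 = paste0("A", g$a2))
    phi <- phi_st(gm[gm$site_code == "P1", ], gm[gm$site_code == "P2", ],
                  d01, n_perm = 5, seed = 1)$phi_st
    expect_equal(theta, phi, tolerance = 1e-6)
  }
})

test_that("rarefied allelic richness follows the hypergeometric closed form", {
  d <- tibble::tibble(pop = "P", individual_id = paste0("i", 1:5), locus = "L",
                      a1 = c(101L, 101L, 101L, 101L, 101L),
                      a2 = c(101L, 101L, 101L, 101L, 102L))
  # N = 10 copies, counts (9, 1): g = 2 gives 1 + (1 - 36/45) = 1.2
  expect_equal(rarefied_allelic_richness(d, "L", "P", 2), 1.2)
  expect_equal(rarefied_allelic_richness(d, "L", "P", 10), 2)  # g = N
  mono <- d; mono$a2 <- 101L
  for (g in c(1, 4, 10)) {
    expect_equal(rarefied_allelic_richness(mono, "L", "P", g), 1)
  }
  expect_error(rarefied_allelic_richness(d, "L", "P", 11), "exceeds")
  # monotone non-decreasing in g
  ar <- vapply(1:10, function(g) rarefied_allelic_richness(d, "L", "P", g), 0)
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("microsatellite diversity summary averages over loci", {
  f <- tempfile(fileext = ".gen")
  on.exit(unlink(f))
  ds <- read_genepop(toy_genepop(f))
  ms <- microsat_diversity(ds)
  expect_equal(nrow(ms), 2L)
  expect_true(all(ms$A_R >= 1))
  expect_true(all(ms$H_E >= 0 & ms$H_E <= 1))
})

test_that("Mantel tests: affine relation, self-control, input checks", {
  set.seed(3)
  m <- as.matrix(dist(matrix(rnorm(14), 7)))
  aff <- mantel_test(m, 2 * m + 1, n_perm = 199, seed = 1)
  expect_equal(aff$r, 1, tolerance = 1e-12)
  expect_lte(aff$p, 0.05)
  # partial test controlling for (nearly) the second matrix removes the
  # correlation that matrix carried
  m2 <- m + as.matrix(dist(matrix(rnorm(14), 7)))
  ctrl <- m2 + as.matrix(dist(matrix(rnorm(14), 7))) * 0.02
  plain <- mantel_test(m, m2, n_perm = 99, seed = 1)
  pm <- partial_mantel_test(m, m2, ctrl, n_perm = 99, seed = 1)
  expect_lt(abs(pm$r), abs(plain$r))
  expect_lt(abs(pm$r), 0.35)
  expect_error(mantel_test(m, matrix(0, 7, 7)), "Constant")
  expect_error(mantel_test(m[1:3, 1:3], m[1:3, 1:3]), "4 taxa")
})

test_that("independent matrices give roughly uniform Mantel p-values", {
  set.seed(5)
  ps <- replicate(60, {
    a <- as.matrix(dist(matrix(rnorm(12), 6)))
    b <- as.matrix(dist(matrix(rnorm(12), 6)))
    mantel_test(a, b, n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("isolation-by-distance applies the declared transforms", {
  set.seed(6)
  km <- as.matrix(dist(matrix(rnorm(10) * 10, 5))) + 5
  diag(km) <- 0
  fst <- as.matrix(dist(matrix(rnorm(10), 5))) / 10
  fst[1, 2] <- fst[2, 1] <- -0.01          # negative estimate gets floored
  direct <- ibd_mantel(fst, km, n_perm = 99, seed = 2)
  gen <- pmax(fst, 0); gen <- gen / (1 - gen)
  geo <- log(km); diag(geo) <- 0
  manual <- mantel_test(gen, geo, n_perm = 99, seed = 2)
  expect_equal(direct$r, manual$r)
  expect_equal(direct$p, manual$p)
  barr <- as.matrix(dist(matrix(rnorm(10), 5)))
  partial <- ibd_mantel(fst, km, barriers = barr, n_perm = 99, seed = 2)
  expect_true(is.finite(partial$r))
})
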