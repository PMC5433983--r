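test_that("pathway site counts: syn + nonsyn = 3 for every sense codon", {
  st <- riffle:::codon_site_table()
  code <- riffle:::genetic_code()
  sense <- names(code)[code != "*"]
  expect_length(sense, 61L)
  expect_true(all(abs(rowSums(st[sense, ]) - 3) < 1e-12))
  expect_equal(unname(st["TTT", "syn"]), 1 / 3)
  expect_equal(unname(st["TTT", "nonsyn"]), 8 / 3)
})

test_that("Nei-Gojobori rates on simple alignments", {
  same <- nei_gojobori(c("TTTAAA", "TTTAAA"))
  expect_equal(unlist(same[c("pS", "pN", "dS", "dN")]),
               c(pS = 0, pN = 0, dS = 0, dN = 0))
  # one synonymous change: TTT -> TTC
  syn <- suppressWarnings(nei_gojobori(c("TTTAAA", "TTCAAA")))  # pS in the JC-undefined zone
  expect_equal(syn$pN, 0)
  expect_gt(syn$pS, 0)
  # one nonsynonymous change: TTT -> GTT
  non <- nei_gojobori(c("TTTAAA", "GTTAAA"))
  expect_equal(non$pS, 0)
  expect_gt(non$pN, 0)
})

test_that("Jukes-Cantor correction: closed form, symmetry, domain", {
  expect_equal(jc_distance("AAAA", "AAAA"), 0)
  expect_equal(round(jc_distance("AAAA", "AAAT"), 5), 0.30410)
  expect_equal(jc_distance("ACGT", "ACGA"), jc_distance("ACGA", "ACGT"))
  expect_error(jc_distance("AAAA", "TTTT"), "undefined")
  expect_error(jc_distance("AAAA", "AAA"), "equal length")
  expect_error(jc_distance("AANA", "AAAA"), "Ambiguity")
})

test_that("dN/dS is invariant to ordering and weights mimic duplication", {
  cat8 <- study_catalog()
  ex <- exon_sequences(cat8)[1:4]
  a <- nei_gojobori(ex, c(2, 1, 1, 1))
  b <- nei_gojobori(c(ex[1], ex), c(1, 1, 1, 1, 1))
  expect_equal(a$pS, b$pS, tolerance = 1e-12)
  expect_equal(a$pN, b$pN, tolerance = 1e-12)
  shuffled <- nei_gojobori(ex[c(3, 1, 4, 2)], c(2, 1, 1, 1)[c(3, 1, 4, 2)])
  expect_equal(a$pN, shuffled$pN, tolerance = 1e-12)
})

test_that("the codon Z-test degenerates sensibly and signs follow construction", {
  ident <- codon_z_test(c("TTTAAA", "TTTAAA"), seed = 1)
  expect_equal(ident$p, 1)
  expect_equal(ident$Z, 0)
  # only synonymous differences force Z < 0 (divergence kept inside the
  # Jukes-Cantor domain)
  anc <- c("TTT", "AAA", "GGA", "CGA", "CCC", "GAT", "ACA", "TGC",
           "CTG", "ATT", "GCC", "AGA")
  der <- anc
  der[1] <- "TTC"; der[2] <- "AAG"
  syn_only <- c(paste(anc, collapse = ""), paste(der, collapse = ""))
  expect_equal(nei_gojobori(syn_only)$pN, 0)
  z <- suppressWarnings(codon_z_test(syn_only, n_boot = 200, seed = 2))
  expect_lt(z$Z, 0)
})

test_that("dN/dS recovers the simulated substitution-rate ratio", {
  # evolve sequences from one ancestor with nonsyn:syn substitution counts
  # in ratio R by accepting random single-base changes by class
  code <- riffle:::genetic_code()
  sense <- names(code)[code != "*"]
  set.seed(31)
  anc <- paste(sample(sense, 60, TRUE), collapse = "")
  mutate_class <- function(seq, n_syn, n_non) {
    ch <- strsplit(seq, "")[[1]]
    got_s <- 0; got_n <- 0
    while (got_s < n_syn || got_n < n_non) {
      p <- sample(length(ch), 1)
      old <- ch[p]
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ch2 <- ch; ch2[p] <- new
      cod <- ((p - 1) %/% 3) + 1
      c_old <- paste(ch[(3 * cod - 2):(3 * cod)], collapse = "")
      c_new <- paste(ch2[(3 * cod - 2):(3 * cod)], collapse = "")
      if (code[[c_new]] == "*") next
      if (code[[c_old]] == code[[c_new]] && got_s < n_syn) {
        ch <- ch2; got_s <- got_s + 1
      } else if (code[[c_old]] != code[[c_new]] && got_n < n_non) {
        ch <- ch2; got_n <- got_n + 1
      }
    }
    paste(ch, collapse = "")
  }
  seqs <- vapply(1:6, function(i) mutate_class(anc, n_syn = 2, n_non = 8), "")
  ng <- nei_gojobori(seqs)
  # syn sites ~ 1/4 of total, so equal counts would give pN/pS ~ 1/3;
  # an 8:2 count ratio inflates dN/dS well above 1
  expect_gt(ng$dnds, 1)
  seqs_s <- vapply(1:6, function(i) mutate_class(anc, n_syn = 6, n_non = 2), "")
  ng_s <- nei_gojobori(seqs_s)
  expect_lt(ng_s$dnds, ng$dnds)
})

test_that("four-gamete Rm: definitions and infinite-sites simulations", {
  expect_equal(four_gamete_rm(c("AA", "AT", "TT")), 0L)
  expect_equal(four_gamete_rm(c("AA", "AT", "TA", "TT")), 1L)
  # perfect phylogeny (each mutation at a fresh site, no recombination)
  set.seed(13)
  for (rep in 1:20) {
    L <- 40
    haps <- list(paste(rep("A", L), collapse = ""))
    used <- integer(0)
    for (step in 1:10) {
      src <- strsplit(haps[[sample(length(haps), 1)]], "")[[1]]
      p <- sample(setdiff(seq_len(L), used), 1)
      used <- c(used, p)
      src[p] <- "T"
      haps[[length(haps) + 1]] <- paste(src, collapse = "")
    }
    expect_equal(four_gamete_rm(unlist(haps)), 0L)
  }
  # planted incompatibility is always detected
  for (rep in 1:20) {
    L <- 30
    base <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
    ij <- sort(sample(L, 2))
    h <- vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(bits) {
      x <- base
      if (bits[1]) x[ij[1]] <- "T"
      if (bits[2]) x[ij[2]] <- "T"
      paste(x, collapse = "")
    }, "")
    expect_gte(four_gamete_rm(h), 1L)
  }
})

test_that("the window scan flags a constructed nonsynonymous hotspot only", {
  # window 1: nonsynonymous variation; window 2: synonymous variation
  anc <- c("TTT", "CAT", "AAA", "GGA", "CCT",
           "GGG", "CGA", "ACA", "TCC", "GTT")
  v1 <- anc; v1[1] <- "GTT"; v1[2] <- "CGT"                 # nonsyn, win 1
  v2 <- anc; v2[3] <- "ACA"; v2[4] <- "GCA"; v2[5] <- "CAT" # nonsyn, win 1
  v3 <- anc; v3[6] <- "GGA"; v3[7] <- "CGG"                 # syn, win 2
  v4 <- anc; v4[8] <- "ACG"; v4[9] <- "TCT"; v4[10] <- "GTC" # syn, win 2
  seqs <- vapply(list(anc, v1, v2, v3, v4), paste, "", collapse = "")
  scan <- window_dnds_scan(seqs, window_codons = 5, n_perm = 300,
                           threshold_prob = 0.9, seeds = c(1, 2))
  w <- scan$windows
  expect_equal(nrow(w), 2L)
  expect_true(w$flagged[1])
  expect_false(w$flagged[2])
  expect_gt(w$stat[1], 0)
  expect_lt(w$stat[2], 0)
})

test_that("monomorphic alignments are never flagged and flags need both runs", {
  mono <- rep("TTTAAAGGACGACAT", 4)
  scan <- window_dnds_scan(mono, window_codons = 2, n_perm = 50,
                           seeds = c(3, 4))
  expect_false(any(scan$windows$flagged))
  expect_error(window_dnds_scan(mono, window_codons = 99), "longer")
  # flag set agrees with the conjunction of the two runs by construction
  expect_equal(scan$windows$flagged,
               scan$windows$prob_run1 >= 0.95 & scan$windows$prob_run2 >= 0.95)
})

test_that("neighbor-joining recovers additive trees and matches UPGMA on ultrametric input", {
  # 4-taxon additive matrix from a known topology ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 2, b = 3, c = 4, d = 5, mid = 6)
  d["a", "b"] <- d["b", "a"] <- bl["a"] + bl["b"]
  d["c", "d"] <- d["d", "c"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- bl[x] + bl["mid"] + bl[y]
  }
  tr <- nj_tree(d)
  expect_equal(sum(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]] - d), 0,
               tolerance = 1e-10)
  # ultrametric input: NJ and UPGMA topologies agree
  set.seed(2)
  x <- matrix(rnorm(12), 6)
  hm <- as.matrix(dist(x))
  hc <- hclust(as.dist(hm), method = "average")
  upgma <- ape::as.phylo(hc)
  um <- ape::cophenetic.phylo(upgma)          # ultrametric distances
  njt <- nj_tree(um[rownames(hm), rownames(hm)])
  expect_equal(ape::dist.topo(ape::unroot(upgma), ape::unroot(njt))[1], 0)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("the allele tree writes valid Newick with JC branch lengths", {
  cat8 <- study_catalog()
  tr <- nj_allele_tree(cat8)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, cat8$allele_id)
  f <- tempfile(fileext = ".nwk")
  on.exit(unlink(f))
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back))[1], 0)
})
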