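# Codon-level selection statistics on the exon alignment.
#
# All pairwise Nei-Gojobori quantities decompose into per-codon-position
# sums, so we precompute, for every sequence pair, per-position arrays of
# synonymous/nonsynonymous differences (pathway-averaged, stop-avoiding)
# and site counts (averaged over the pair). Population-level statistics,
# codon-site bootstraps and window scans are then cheap array reductions.

ng_arrays <- function(seqs, weights = NULL) {
  validate_codon_alignment(seqs)
  n <- length(seqs)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) abort("Bad `weights`.")
  cods <- t(vapply(seqs, split_codons, character(nchar(seqs[1]) %/% 3L)))
  n_pos <- ncol(cods)
  ST <- codon_site_table()
  s_site <- matrix(ST[cods, "syn"], n, n_pos)       # per-seq per-pos syn sites
  prs <- utils::combn(n, 2L)
  n_pair <- ncol(prs)
  sd <- nd <- ss <- ns <- matrix(0, n_pair, n_pos)
  for (p in seq_len(n_pair)) {
    i <- prs[1, p]; j <- prs[2, p]
    for (t in seq_len(n_pos)) {
      dd <- codon_diff(cods[i, t], cods[j, t])
      sd[p, t] <- dd[["syn"]]; nd[p, t] <- dd[["nonsyn"]]
    }
    ss[p, ] <- (s_site[i, ] + s_site[j, ]) / 2
    ns[p, ] <- 3 - ss[p, ]
  }
  # homotypic "pairs" (identical copies under weights>1): zero differences
  list(sd = sd, nd = nd, ss = ss, ns = ns,
       w_pair = w[prs[1, ]] * w[prs[2, ]],
       w_self = choose(w, 2), s_self = s_site,
       n_pos = n_pos)
}

# weighted-mean pairwise proportions over a set of codon positions
ng_props <- function(arr, pos = NULL) {
  pos <- pos %||% seq_len(arr$n_pos)
  sS <- rowSums(arr$ss[, pos, drop = FALSE])
  sN <- rowSums(arr$ns[, pos, drop = FALSE])
  pS_pair <- rowSums(arr$sd[, pos, drop = FALSE]) / sS
  pN_pair <- rowSums(arr$nd[, pos, drop = FALSE]) / sN
  pS_pair[sS == 0] <- 0    # no synonymous sites in the window
  pN_pair[sN == 0] <- 0
  wtot <- sum(arr$w_pair) + sum(arr$w_self)
  list(pS = sum(arr$w_pair * pS_pair) / wtot,    # homotypic pairs add 0
       pN = sum(arr$w_pair * pN_pair) / wtot,
       syn_sites = (sum(arr$w_pair * sS) +
                      sum(arr$w_self * rowSums(arr$s_self[, pos, drop = FALSE]))) / wtot,
       nonsyn_sites = (sum(arr$w_pair * sN) +
                         sum(arr$w_self *
                               (3 * length(pos) -
                                  rowSums(arr$s_self[, pos, drop = FALSE])))) / wtot)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})} with `p` the proportion of
#' differing sites; undefined (error) at `p >= 3/4`.
#'
#' @param a,b Equal-length A/C/G/T strings.
#' @return Substitutions per site.
#' @export
jc_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("Sequences must have equal length.")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) abort("Ambiguity codes not allowed.")
  p <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  jc_correct(p, error = TRUE)
}

jc_correct <- function(p, error = FALSE) {
  if (p >= 0.75) {
    if (error) abort("Jukes-Cantor correction undefined at p >= 3/4.")
    warn("Jukes-Cantor correction undefined at p >= 3/4; returning NA.")
    return(NA_real_)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori synonymous/nonsynonymous rates for one population
#'
#' Pathway-method site and difference counts per codon (each position's
#' synonymous fraction is the share of its 3 possible changes that preserve
#' the amino acid; multi-step codon differences are averaged over minimal
#' mutational pathways avoiding stop codons). Pairwise proportions pS and pN
#' are averaged over all weighted sequence-copy pairs (a weight of 2 is
#' exactly equivalent to listing a sequence twice), then Jukes-Cantor
#' corrected into dS and dN.
#'
#' @param seqs In-frame coding sequences (e.g. [exon_sequences()]), aligned.
#' @param weights Optional per-sequence copy counts.
#' @return One-row tibble: `syn_sites`, `nonsyn_sites`, `pS`, `pN`,
#'   `dS`, `dN`, `dnds` (`NA` when `dS` is 0 or undefined).
#' @export
#' @examples
#' nei_gojobori(c("TTTAAA", "TTCAAA"))
nei_gojobori <- function(seqs, weights = NULL) {
  arr <- ng_arrays(seqs, weights)
  pr <- ng_props(arr)
  dS <- jc_correct(pr$pS)
  dN <- jc_correct(pr$pN)
  tibble::tibble(syn_sites = pr$syn_sites, nonsyn_sites = pr$nonsyn_sites,
                 pS = pr$pS, pN = pr$pN, dS = dS, dN = dN,
                 dnds = ifelse(!is.na(dS) && dS > 0, dN / dS, NA_real_))
}

#' Codon-based Z-test of neutral evolution
#'
#' Tests dN - dS = 0. The standard error of dN - dS comes from a bootstrap
#' over codon sites (codons resampled whole, preserving codon integrity);
#' the p-value is two-sided from the normal reference.
#'
#' @inheritParams nei_gojobori
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Integer RNG seed.
#' @return One-row tibble: `dN`, `dS`, `Z`, `p`, `se`, `n_boot`.
#' @export
codon_z_test <- function(seqs, weights = NULL, n_boot = 500L, seed = 1L) {
  arr <- ng_arrays(seqs, weights)
  pr <- ng_props(arr)
  dS <- jc_correct(pr$pS); dN <- jc_correct(pr$pN)
  D <- dN - dS
  if (length(unique(seqs)) == 1L || (!is.na(D) && pr$pN == 0 && pr$pS == 0)) {
    return(tibble::tibble(dN = dN, dS = dS, Z = 0, p = 1, se = NA_real_,
                          n_boot = 0L))
  }
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    pos <- sample.int(arr$n_pos, arr$n_pos, replace = TRUE)
    prb <- ng_props(arr, pos)
    jc_correct(prb$pN) - jc_correct(prb$pS)
  }, 0)
  se <- stats::sd(boot, na.rm = TRUE)
  if (is.na(se) || se == 0) {
    warn("Zero bootstrap variance; p set to 1.")
    return(tibble::tibble(dN = dN, dS = dS, Z = 0, p = 1, se = se,
                          n_boot = as.integer(n_boot)))
  }
  Z <- D / se
  tibble::tibble(dN = dN, dS = dS, Z = Z, p = 2 * pnorm(-abs(Z)), se = se,
                 n_boot = as.integer(n_boot))
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Four-gamete test over all pairs of biallelic segregating sites; pairs
#' exhibiting all four gametes define incompatible intervals, nested
#' intervals are culled, and Rm is the maximum number of pairwise disjoint
#' intervals remaining. Sites with more than two states are ignored.
#'
#' @param seqs Aligned equal-length sequences (full amplicon).
#' @return Integer Rm >= 0.
#' @export
four_gamete_rm <- function(seqs) {
  seqs <- unique(seqs)
  if (length(seqs) < 2L) return(0L)
  m <- seq_to_mat(seqs)
  nstate <- apply(m, 2, function(col) length(unique(col)))
  sites <- which(nstate == 2L)
  if (length(sites) < 2L) return(0L)
  iv <- NULL
  for (x in seq_along(sites)[-length(sites)]) {
    for (y in (x + 1L):length(sites)) {
      gam <- unique(paste0(m[, sites[x]], m[, sites[y]]))
      if (length(gam) == 4L) iv <- rbind(iv, c(sites[x], sites[y]))
    }
  }
  if (is.null(iv)) return(0L)
  # cull intervals that contain another incompatible interval
  keep <- vapply(seq_len(nrow(iv)), function(r) {
    !any(iv[, 1] >= iv[r, 1] & iv[, 2] <= iv[r, 2] &
           (iv[, 1] > iv[r, 1] | iv[, 2] < iv[r, 2]))
  }, TRUE)
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 2]), , drop = FALSE]
  rm_count <- 0L
  last_end <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= last_end) {
      rm_count <- rm_count + 1L
      last_end <- iv[r, 2]
    }
  }
  rm_count
}

#' Sliding-window scan for locally elevated nonsynonymous variation
#'
#' A deliberately simple, permutation-based stand-in for full Bayesian
#' variable-omega models: for each window of `window_codons` codons the
#' statistic pN - pS is computed from the window's codons only, and compared
#' with a null built by shuffling codon columns across the whole alignment
#' `n_perm` times. A window's exceedance probability is the fraction of
#' permuted values below the observed one (ties counted half); a window is
#' flagged as under diversifying selection only when the probability reaches
#' `threshold_prob` in BOTH of two independently seeded runs, a two-run
#' agreement rule that squares the per-window false-positive rate.
#'
#' @inheritParams nei_gojobori
#' @param window_codons Window width in codons (default 10).
#' @param n_perm Permutations per run (default 200).
#' @param threshold_prob Flagging threshold (default 0.95).
#' @param seeds Integer seeds of the two runs.
#' @return Object of class `mhc_scan`: tibble `windows` with 0-based
#'   half-open codon intervals (`start`, `end`), `stat` (pN - pS),
#'   `prob_run1`, `prob_run2`, `flagged`; plus the scan settings.
#' @export
window_dnds_scan <- function(seqs, weights = NULL, window_codons = 10L,
                             n_perm = 200L, threshold_prob = 0.95,
                             seeds = c(1L, 2L)) {
  if (window_codons < 1L) abort("`window_codons` must be >= 1.")
  arr <- ng_arrays(seqs, weights)
  if (window_codons > arr$n_pos) abort("Window longer than the alignment.")
  starts <- seq(1L, arr$n_pos, by = window_codons)
  wins <- lapply(starts, function(s) s:min(s + window_codons - 1L, arr$n_pos))
  obs <- vapply(wins, function(ix) {
    pr <- ng_props(arr, ix); pr$pN - pr$pS
  }, 0)
  run_probs <- function(seed) {
    set.seed(as.integer(seed))
    below <- ties <- numeric(length(wins))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(arr$n_pos)
      for (wi in seq_along(wins)) {
        ix <- perm[wins[[wi]]]
        pr <- ng_props(arr, ix)
        st <- pr$pN - pr$pS
        if (st < obs[wi] - 1e-12) below[wi] <- below[wi] + 1
        else if (abs(st - obs[wi]) <= 1e-12) ties[wi] <- ties[wi] + 1
      }
    }
    (below + 0.5 * ties) / n_perm
  }
  q1 <- run_probs(seeds[1])
  q2 <- run_probs(seeds[2])
  windows <- tibble::tibble(
    start = vapply(wins, function(ix) ix[1] - 1L, 0L),
    end = vapply(wins, function(ix) ix[length(ix)], 0L),
    stat = obs, prob_run1 = q1, prob_run2 = q2,
    flagged = q1 >= threshold_prob & q2 >= threshold_prob)
  structure(list(windows = windows, window_codons = as.integer(window_codons),
                 n_perm = as.integer(n_perm), threshold_prob = threshold_prob,
                 seeds = seeds),
            class = "mhc_scan")
}

#' @export
print.mhc_scan <- function(x, ...) {
  cat(sprintf(
    "Window dN-dS scan (permutation stand-in; %d-codon windows, %d perms, 2-run rule)\n",
    x$window_codons, x$n_perm))
  print(x$windows)
  invisible(x)
}

#' Per-population selection summary
#'
#' Runs [nei_gojobori()] and [codon_z_test()] on each site's exon alignment
#' weighted by its allele copy counts.
#'
#' @param catalog An [mhc_catalog()].
#' @param counts Allele-count tibble (one row per site).
#' @param n_boot Bootstrap replicates for the Z-test.
#' @param seed Integer RNG seed.
#' @return Tibble, one row per site: NG quantities plus `Z` and `p`.
#' @export
population_selection <- function(catalog, counts, n_boot = 500L, seed = 1L) {
  ex <- exon_sequences(catalog)
  ac <- allele_columns(counts)
  purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    cc <- setNames(as.numeric(unlist(counts[i, ac])), ac)
    cc <- align_counts(cc, catalog$allele_id)
    keep <- cc > 0
    if (sum(keep) < 2L) {
      # monomorphic site: no within-population sequence variation to test
      return(tibble::tibble(site_code = counts$site_code[i],
                            syn_sites = NA_real_, nonsyn_sites = NA_real_,
                            pS = 0, pN = 0, dS = 0, dN = 0, dnds = NA_real_,
                            Z = 0, p = 1))
    }
    ng <- nei_gojobori(ex[keep], cc[keep])
    zt <- codon_z_test(ex[keep], cc[keep], n_boot = n_boot,
                       seed = stage_seed(seed, i))
    dplyr::bind_cols(tibble::tibble(site_code = counts$site_code[i]), ng,
                     zt[, c("Z", "p")])
  })
}

#' Neighbor-joining tree of the catalog alleles
#'
#' Jukes-Cantor distances between the full amplicon sequences, joined by the
#' Saitou-Nei neighbor-joining algorithm (via \pkg{ape}); returned unrooted
#' with branch lengths in substitutions per site.
#'
#' @param catalog An [mhc_catalog()].
#' @return An [ape::nj()] `phylo` object.
#' @export
nj_allele_tree <- function(catalog) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  n <- nrow(catalog)
  if (n < 3L) abort("Need at least 3 alleles for a tree.")
  d <- matrix(0, n, n, dimnames = list(catalog$allele_id, catalog$allele_id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- jc_distance(catalog$sequence[i], catalog$sequence[j])
  }
  nj_tree(d)
}

#' Neighbor-joining from a labelled distance matrix
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa).
#' @return A `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("Need at least 3 taxa.")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("Distance matrix must be symmetric.")
  }
  ape::nj(as.dist(d))
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
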