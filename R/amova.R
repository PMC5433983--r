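# Molecular-variance machinery. All sums of squares are computed on allele
# copy counts against the allele-by-allele squared-distance matrix
# (nucleotide differences), using SS(set) = c' D c / (2 n) for a set of
# copies with count vector c -- exact because distances depend only on
# allele identity.

ss_from_counts <- function(cnt, D) {
  n <- sum(cnt)
  if (n == 0) return(0)
  as.numeric(cnt %*% D %*% cnt) / (2 * n)
}

counts_by <- function(a1, a2, fac, levels_d) {
  # copy counts per group: rows = groups, cols = alleles of D
  tab <- table(factor(rep(fac, 2L), levels = unique(fac)),
               factor(c(a1, a2), levels = levels_d))
  unclass(tab)
}

# normalize genotype table for AMOVA: individual_id, site_code, river, a1, a2
amova_frame <- function(genotypes, meta = NULL) {
  g <- normalize_genotypes(genotypes)
  if (!"river" %in% names(g)) {
    if ("river" %in% names(genotypes)) {
      g$river <- genotypes$river[match(g$individual_id, genotypes$individual_id)]
    } else if (!is.null(meta)) {
      g$river <- meta$river[match(g$site_code, meta$site_code)]
    }
  }
  g
}

#' Pairwise population divergence Phi-ST
#'
#' Two-level AMOVA on haplotype copies with squared intercopy distance equal
#' to the number of nucleotide differences between the alleles carried.
#' \eqn{\Phi_{ST} = \sigma^2_{among} / (\sigma^2_{among} + \sigma^2_{within})};
#' significance from random reassignment of individuals (copy pairs) to the
#' two populations, observed value included in the null set, so
#' p >= 1/(n_perm+1).
#'
#' @param gA,gB Genotype tibbles for the two populations ([call_genotypes()]
#'   output or `allele1`/`allele2` columns).
#' @param diffs Symmetric allele-by-allele difference matrix
#'   ([allele_diff_matrix()]); use a 0/1 matrix for identity distances.
#' @param n_perm Number of permutations (default 110).
#' @param seed Integer RNG seed.
#' @return One-row tibble: `phi_st`, `p`, `n_perm`.
#' @export
phi_st <- function(gA, gB, diffs, n_perm = 110L, seed = 1L) {
  a <- normalize_genotypes(gA); b <- normalize_genotypes(gB)
  if (nrow(a) < 1L || nrow(b) < 1L) abort("Each population needs >= 1 diploid.")
  ind <- dplyr::bind_rows(dplyr::mutate(a, pop = "A"), dplyr::mutate(b, pop = "B"))
  lev <- rownames(diffs)
  stat <- function(pop) {
    cnt <- counts_by(ind$a1, ind$a2, pop, lev)
    np <- rowSums(cnt)
    if (any(np < 2)) abort("A population has fewer than 2 gene copies.")
    N <- sum(np); P <- nrow(cnt)
    ssw <- sum(apply(cnt, 1, ss_from_counts, D = diffs))
    sst <- ss_from_counts(colSums(cnt), diffs)
    msw <- ssw / (N - P)
    msa <- (sst - ssw) / (P - 1)
    n0 <- (N - sum(np^2) / N) / (P - 1)
    s_a <- (msa - msw) / n0
    s_a / (s_a + msw)
  }
  obs <- stat(ind$pop)
  set.seed(as.integer(seed))
  null <- replicate(n_perm, stat(sample(ind$pop)))
  tibble::tibble(phi_st = obs,
                 p = (sum(null >= obs - 1e-12) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm))
}

#' Pairwise Phi-ST matrix over all sites
#'
#' @param genotypes Genotype tibble covering several sites.
#' @inheritParams phi_st
#' @return Tibble with one row per site pair: `site1`, `site2`, `phi_st`, `p`.
#' @export
pairwise_phi_st <- function(genotypes, diffs, n_perm = 110L, seed = 1L) {
  g <- normalize_genotypes(genotypes)
  sites <- unique(g$site_code)
  prs <- utils::combn(sites, 2L)
  purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    r <- phi_st(g[g$site_code == prs[1, k], ], g[g$site_code == prs[2, k], ],
                diffs, n_perm = n_perm, seed = stage_seed(seed, k))
    dplyr::bind_cols(tibble::tibble(site1 = prs[1, k], site2 = prs[2, k]), r)
  })
}

#' Hierarchical (four-level) AMOVA on diploid MHC genotypes
#'
#' Decomposes molecular variance into components among rivers, among sites
#' within rivers, among individuals within sites, and within individuals
#' (between the two allele copies of each diploid), following the
#' sums-of-squares-on-distances construction with squared distance = number
#' of nucleotide differences. Negative variance-component estimates are
#' reported as estimated but truncated to zero for the percent-of-variation
#' column. Per-level permutation p-values use the scheme appropriate to each
#' level: copies among individuals within sites (within-individual and
#' among-individual components; the within-individual p is left-tailed,
#' flagging a deficit of intra-individual variation, i.e. heterozygote
#' deficit, while all among-component p-values are right-tailed), whole
#' individuals among sites within rivers (among-site component), and whole
#' sites among rivers (among-river component). The observed value is always
#' included in the null set.
#'
#' @param genotypes Genotype tibble with `site_code` and `river` (either as
#'   columns or via `meta`).
#' @param diffs Allele difference matrix ([allele_diff_matrix()]).
#' @param n_perm Number of permutations per scheme (default 3024).
#' @param seed Integer RNG seed.
#' @param meta Optional tibble `site_code`, `river` used to label genotypes.
#' @return Object of class `mhc_amova` with a `table` tibble
#'   (`level`, `df`, `sigma2`, `pct`, `p`) and the permutation settings.
#' @export
hierarchical_amova <- function(genotypes, diffs, n_perm = 3024L, seed = 1L,
                               meta = NULL) {
  g <- amova_frame(genotypes, meta)
  if (!"river" %in% names(g) || anyNA(g$river)) {
    abort("Every individual needs a `river` label (supply `meta`).")
  }
  if (length(unique(g$river)) < 2L) abort("Need at least 2 rivers.")
  empty <- tapply(g$individual_id, g$site_code, length)
  if (any(empty == 0)) abort(paste("Empty stratum:", names(empty)[empty == 0][1]))
  lev <- rownames(diffs)
  comp <- amova_components(g, diffs, lev)
  set.seed(as.integer(seed))
  # scheme 1: copies among individuals within sites
  null1 <- replicate(n_perm, {
    gp <- permute_copies_within_sites(g)
    cc <- amova_components(gp, diffs, lev)
    c(cc$sigma2[["within_individuals"]], cc$sigma2[["among_individuals"]])
  })
  # scheme 2: individuals among sites within rivers
  null2 <- replicate(n_perm, {
    gp <- g
    for (ix in split(seq_len(nrow(g)), g$river)) {
      gp$site_code[ix] <- sample(gp$site_code[ix])
    }
    amova_components(gp, diffs, lev)$sigma2[["among_sites"]]
  })
  # scheme 3: sites among rivers
  site_river <- unique(g[, c("site_code", "river")])
  null3 <- replicate(n_perm, {
    sr <- site_river
    sr$river <- sample(sr$river)
    gp <- g
    gp$river <- sr$river[match(gp$site_code, sr$site_code)]
    amova_components(gp, diffs, lev)$sigma2[["among_rivers"]]
  })
  s2 <- comp$sigma2
  pv <- c(
    among_rivers = (sum(null3 >= s2[["among_rivers"]] - 1e-12) + 1) / (n_perm + 1),
    among_sites = (sum(null2 >= s2[["among_sites"]] - 1e-12) + 1) / (n_perm + 1),
    among_individuals = (sum(null1[2, ] >= s2[["among_individuals"]] - 1e-12) + 1) /
      (n_perm + 1),
    within_individuals = (sum(null1[1, ] <= s2[["within_individuals"]] + 1e-12) + 1) /
      (n_perm + 1))
  tr <- pmax(s2, 0)
  pct <- if (sum(tr) > 0) 100 * tr / sum(tr) else rep(0, 4)
  lvl <- c("among_rivers", "among_sites", "among_individuals",
           "within_individuals")
  tab <- tibble::tibble(level = lvl,
                        df = unname(comp$df[lvl]),
                        sigma2 = unname(s2[lvl]),
                        pct = unname(pct[lvl]),
                        p = unname(pv[lvl]))
  structure(list(table = tab, n_perm = as.integer(n_perm), seed = seed),
            class = "mhc_amova")
}

permute_copies_within_sites <- function(g) {
  for (ix in split(seq_len(nrow(g)), g$site_code)) {
    copies <- sample(c(g$a1[ix], g$a2[ix]))
    g$a1[ix] <- copies[seq_along(ix)]
    g$a2[ix] <- copies[seq_along(ix) + length(ix)]
  }
  g
}

# variance components of the 4-level decomposition
amova_components <- function(g, D, lev) {
  Ncop <- 2L * nrow(g)
  I <- nrow(g)
  sites <- unique(g$site_code)
  S <- length(sites)
  rivers <- unique(g$river)
  G <- length(rivers)
  cnt_site <- counts_by(g$a1, g$a2, g$site_code, lev)
  cnt_riv <- counts_by(g$a1, g$a2, g$river, lev)
  ss_wi <- sum(D[cbind(match(g$a1, lev), match(g$a2, lev))]) / 2
  ss_ws <- sum(apply(cnt_site, 1, ss_from_counts, D = D))
  ss_wr <- sum(apply(cnt_riv, 1, ss_from_counts, D = D))
  ss_tot <- ss_from_counts(colSums(cnt_site), D)
  df <- c(among_rivers = G - 1L, among_sites = S - G,
          among_individuals = I - S, within_individuals = I)
  n_s <- rowSums(cnt_site)                      # copies per site
  n_g <- rowSums(cnt_riv)                       # copies per river
  riv_of_site <- g$river[match(rownames(cnt_site), g$site_code)]
  sum_ns2_by_riv <- tapply(n_s^2, riv_of_site, sum)[rownames(cnt_riv)]
  k3 <- (Ncop - sum(sum_ns2_by_riv / n_g)) / (S - G)
  k5 <- (sum(sum_ns2_by_riv / n_g) - sum(n_s^2) / Ncop) / (G - 1)
  k6 <- (Ncop - sum(n_g^2) / Ncop) / (G - 1)
  ms_wi <- ss_wi / df[["within_individuals"]]
  ms_ind <- (ss_ws - ss_wi) / df[["among_individuals"]]
  ms_site <- (ss_wr - ss_ws) / df[["among_sites"]]
  ms_riv <- (ss_tot - ss_wr) / df[["among_rivers"]]
  s_d <- ms_wi
  s_c <- (ms_ind - s_d) / 2
  s_b <- (ms_site - s_d - 2 * s_c) / k3
  s_a <- (ms_riv - s_d - 2 * s_c - k5 * s_b) / k6
  list(sigma2 = c(among_rivers = s_a, among_sites = s_b,
                  among_individuals = s_c, within_individuals = s_d),
       df = df)
}

#' @export
print.mhc_amova <- function(x, ...) {
  cat(sprintf("Hierarchical AMOVA (%d permutations per scheme)\n", x$n_perm))
  print(x$table)
  invisible(x)
}

#' Average between-population substitutions per site (Dxy)
#'
#' \eqn{D_{xy} = \sum_i \sum_j x_i y_j d_{ij} / L} over the two
#' populations' allele frequencies and the allele difference matrix.
#'
#' @param catalog An [mhc_catalog()].
#' @param counts_a,counts_b Per-allele copy counts of the two populations.
#' @return Dxy (substitutions per site).
#' @export
dxy <- function(catalog, counts_a, counts_b) {
  stopifnot(inherits(catalog, "mhc_catalog"))
  L <- nchar(catalog$sequence[1])
  if (L == 0L) abort("Zero-length alignment.")
  ca <- align_counts(counts_a, catalog$allele_id)
  cb <- align_counts(counts_b, catalog$allele_id)
  if (sum(ca) == 0 || sum(cb) == 0) abort("Empty population.")
  x <- ca / sum(ca); y <- cb / sum(cb)
  d <- allele_diff_matrix(catalog)
  as.numeric(x %*% d %*% y) / L
}
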