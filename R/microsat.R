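#' Weir-Cockerham F-statistics (theta)
#'
#' Multi-allele, multi-locus Weir-Cockerham estimator of F_ST as the
#' ratio-of-sums of the variance components a (among populations),
#' b (among individuals within populations) and c (within individuals),
#' accumulated over alleles and loci. Missing genotypes are excluded
#' pairwise per locus. With `ploidy = 1` every gene copy is treated as an
#' independent haploid sample (no within-individual component), the
#' classical ANOVA form theta = sum(MSP - MSW) / sum(MSP + (nc - 1) MSW).
#'
#' @param data A `microsat_df` tibble ([read_genepop()]).
#' @param pops Optional two population labels to restrict to (default: all).
#' @param ploidy 2 (diploid, default) or 1 (copies as haploids).
#' @return Estimate of theta (can be negative near zero differentiation).
#' @export
wc_fst <- function(data, pops = NULL, ploidy = 2L) {
  if (!is.null(pops)) data <- data[data$pop %in% pops, , drop = FALSE]
  r_pops <- unique(data$pop)
  if (length(r_pops) < 2L) abort("Need at least 2 populations.")
  num <- den <- 0
  shared <- FALSE
  for (loc in unique(data$locus)) {
    d <- data[data$locus == loc & !is.na(data$a1) & !is.na(data$a2), , drop = FALSE]
    tab <- table(d$pop)
    if (length(tab) < length(r_pops) || any(tab < 2L)) next
    shared <- TRUE
    if (ploidy == 2L) {
      comp <- wc_components_diploid(d)
    } else {
      comp <- wc_components_haploid(
        data.frame(pop = rep(d$pop, 2L), allele = c(d$a1, d$a2)))
    }
    num <- num + comp$a
    den <- den + comp$tot
  }
  if (!shared) abort("No locus is typed in >= 2 individuals of every population.")
  num / den
}

# Weir & Cockerham (1984) a, b, c summed over alleles for one locus
wc_components_diploid <- function(d) {
  pops <- unique(d$pop)
  r <- length(pops)
  n_i <- as.numeric(table(factor(d$pop, levels = pops)))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(d$a1, d$a2)))
  a_sum <- tot_sum <- 0
  for (u in alleles) {
    cnt <- tapply((d$a1 == u) + (d$a2 == u), factor(d$pop, levels = pops), sum)
    p_i <- as.numeric(cnt) / (2 * n_i)
    h_i <- as.numeric(tapply((d$a1 == u) != (d$a2 == u),
                             factor(d$pop, levels = pops), sum)) / n_i
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    tot_sum <- tot_sum + a + b + cc
  }
  list(a = a_sum, tot = tot_sum)
}

wc_components_haploid <- function(d) {
  pops <- unique(d$pop)
  r <- length(pops)
  n_i <- as.numeric(table(factor(d$pop, levels = pops)))
  N <- sum(n_i)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  alleles <- sort(unique(d$allele))
  a_sum <- tot_sum <- 0
  for (u in alleles) {
    cnt <- as.numeric(tapply(d$allele == u, factor(d$pop, levels = pops), sum))
    p_i <- cnt / n_i
    pbar <- sum(cnt) / N
    msp <- sum(n_i * (p_i - pbar)^2) / (r - 1)
    msw <- sum(n_i * p_i * (1 - p_i)) / (N - r)
    a_sum <- a_sum + (msp - msw) / nc
    tot_sum <- tot_sum + (msp - msw) / nc + msw
  }
  list(a = a_sum, tot = tot_sum)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' @inheritParams wc_fst
#' @return Symmetric matrix of pairwise theta with population labels.
#' @export
pairwise_wc_fst <- function(data, ploidy = 2L) {
  pops <- unique(data$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1L):length(pops)) {
    m[i, j] <- m[j, i] <- wc_fst(data, pops = c(pops[i], pops[j]),
                                 ploidy = ploidy)
  }
  m
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies,
#' \eqn{A_R = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]},
#' enabling comparison of allele counts across unequal sample sizes.
#'
#' @param data A `microsat_df` tibble.
#' @param locus,population Which locus/population to rarefy.
#' @param g Rarefaction gene-copy count (`g = N` gives the observed count).
#' @return Rarefied allelic richness (>= 1 for a typed locus).
#' @export
rarefied_allelic_richness <- function(data, locus, population, g) {
  d <- data[data$locus == locus & data$pop == population &
              !is.na(data$a1) & !is.na(data$a2), , drop = FALSE]
  copies <- c(d$a1, d$a2)
  N <- length(copies)
  if (g > N) abort("`g` exceeds the number of typed gene copies.")
  if (g < 1L) abort("`g` must be >= 1.")
  Na <- table(copies)
  sum(1 - exp(lchoose(N - Na, g) - lchoose(N, g)))
}

#' Per-population microsatellite diversity summary
#'
#' Mean rarefied allelic richness and mean unbiased expected heterozygosity
#' across loci for each population. The rarefaction size defaults to the
#' smallest number of typed gene copies over all locus-population cells so
#' every cell is comparable.
#'
#' @param data A `microsat_df` tibble.
#' @param g Rarefaction size (gene copies); default: minimum typed copies.
#' @return Tibble `pop`, `A_R`, `H_E`, `g`.
#' @export
microsat_diversity <- function(data, g = NULL) {
  cc <- data[!is.na(data$a1) & !is.na(data$a2), , drop = FALSE]
  sizes <- cc |>
    dplyr::count(.data$pop, .data$locus) |>
    dplyr::mutate(copies = 2L * .data$n)
  g <- g %||% min(sizes$copies)
  purrr::map_dfr(unique(data$pop), function(p) {
    ar <- vapply(unique(data$locus), function(l)
      rarefied_allelic_richness(data, l, p, g), 0)
    he <- vapply(unique(data$locus), function(l) {
      d <- cc[cc$locus == l & cc$pop == p, , drop = FALSE]
      haplotype_diversity(table(c(d$a1, d$a2)))
    }, 0)
    tibble::tibble(pop = p, A_R = mean(ar), H_E = mean(he), g = g)
  })
}

#' Mantel and partial Mantel tests
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices, with significance from joint row/column permutations
#' (one-sided, observed included in the null set). The partial version
#' correlates the residuals of both matrices after removing the control
#' matrix. Implemented with \pkg{vegan}'s permutation engine.
#'
#' @param m1,m2 Symmetric matrices with matching labels.
#' @param control Control matrix (partial test only).
#' @param n_perm Number of permutations (default 100,000 to resolve small
#'   p-values; reduce for exploratory runs).
#' @param seed Integer RNG seed.
#' @return Tibble `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 100000L, seed = 1L) {
  check_mantel_input(m1, m2)
  set.seed(as.integer(seed))
  fit <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = n_perm)
  tibble::tibble(r = unname(fit$statistic), p = fit$signif,
                 n_perm = as.integer(n_perm))
}

#' @rdname mantel_test
#' @export
partial_mantel_test <- function(m1, m2, control, n_perm = 100000L, seed = 1L) {
  check_mantel_input(m1, m2)
  check_mantel_input(m1, control)
  set.seed(as.integer(seed))
  fit <- vegan::mantel.partial(as.dist(m1), as.dist(m2), as.dist(control),
                               permutations = n_perm)
  tibble::tibble(r = unname(fit$statistic), p = fit$signif,
                 n_perm = as.integer(n_perm))
}

check_mantel_input <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) abort("Matrices must have matching dimensions.")
  if (nrow(m1) < 4L) abort("Need at least 4 taxa for a meaningful permutation test.")
  for (m in list(m1, m2)) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) abort("Matrices must be symmetric.")
    if (sd(m[lower.tri(m)]) == 0) abort("Constant matrix: correlation undefined.")
  }
  invisible(TRUE)
}

#' Isolation-by-distance transforms and tests
#'
#' Applies the conventional transforms - genetic distance
#' \eqn{F_{ST}/(1-F_{ST})} with negative estimates floored at zero, and
#' log-transformed geographic distance - then runs a Mantel test, or a
#' partial Mantel test controlling for a barrier-count matrix if supplied.
#'
#' @param fst Pairwise F_ST matrix ([pairwise_wc_fst()]).
#' @param dist_km Pairwise geographic distances (km, matching labels).
#' @param barriers Optional matrix of barrier counts between sites.
#' @inheritParams mantel_test
#' @return Tibble `r`, `p`, `n_perm`.
#' @export
ibd_mantel <- function(fst, dist_km, barriers = NULL, n_perm = 100000L,
                       seed = 1L) {
  gen <- pmax(fst, 0)
  gen <- gen / (1 - gen)
  geo <- log(dist_km)
  diag(geo) <- 0
  if (is.null(barriers)) {
    mantel_test(gen, geo, n_perm = n_perm, seed = seed)
  } else {
    partial_mantel_test(gen, geo, barriers, n_perm = n_perm, seed = seed)
  }
}
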