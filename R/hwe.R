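#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype array given the allele counts.
#' The conditional probability of a genotype table \eqn{\{n_{ij}\}} with
#' allele counts \eqn{m_i} and \eqn{H} heterozygotes is
#' \deqn{P = \frac{n!\,\prod_i m_i!\;2^H}{(2n)!\,\prod_{i\le j} n_{ij}!},}
#' and the p-value is the total probability of tables no more probable than
#' the observed one. Two engines are provided: complete enumeration of all
#' tables with the observed allele counts (feasible for small samples; the
#' oracle), and a Markov chain over random pairings of the gene copies -
#' each step swaps partners between two randomly chosen genotype pairs,
#' which leaves the conditional distribution invariant - with a
#' dememorization burn-in, in the spirit of the Guo-Thompson chain.
#'
#' @param a1,a2 Allele labels of each individual's two gene copies.
#' @param method `"chain"` (default) or `"enumerate"`.
#' @param chain_steps Markov-chain length after burn-in (default 100,000).
#' @param dememorization Burn-in steps (default 1,000).
#' @param seed Integer RNG seed for the chain.
#' @return List with `p_value`, `method`, and for the chain engine `se`, a
#'   binomial Monte-Carlo standard error. Monomorphic input returns p = 1.
#' @export
#' @examples
#' # two individuals AA and aa: the exact conditional p is 1/3
#' hwe_exact_test(c("A", "a"), c("A", "a"), method = "enumerate")$p_value
hwe_exact_test <- function(a1, a2, method = c("chain", "enumerate"),
                           chain_steps = 100000L, dememorization = 1000L,
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(a1) == length(a2), length(a1) >= 1L)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 1L) return(list(p_value = 1, method = "monomorphic"))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  tab <- matrix(0L, k, k)
  for (t in seq_along(i1)) {
    i <- max(i1[t], i2[t]); j <- min(i1[t], i2[t])
    tab[i, j] <- tab[i, j] + 1L
  }
  logp_obs <- hwe_log_prob(tab)
  if (method == "enumerate") {
    m <- allele_copy_counts(tab)
    all_tabs <- enumerate_tables(m)
    logps <- vapply(all_tabs, hwe_log_prob, 0)
    probs <- exp(logps - max(logps)); probs <- probs / sum(probs)
    p <- sum(probs[logps <= logp_obs + 1e-9])
    list(p_value = p, method = "enumerate", n_tables = length(all_tabs))
  } else {
    set.seed(as.integer(seed))
    p <- hwe_chain(i1, i2, logp_obs, chain_steps, dememorization)
    list(p_value = p, method = "chain",
         se = sqrt(p * (1 - p) / chain_steps))
  }
}

allele_copy_counts <- function(tab) {
  k <- nrow(tab)
  low <- tab + t(tab); diag(low) <- 2L * diag(tab)
  rowSums(low)
}

hwe_log_prob <- function(tab) {
  n <- sum(tab)
  m <- allele_copy_counts(tab)
  H <- sum(tab) - sum(diag(tab))
  lfactorial(n) + sum(lfactorial(m)) + H * log(2) -
    lfactorial(2 * n) - sum(lfactorial(tab[lower.tri(tab, diag = TRUE)]))
}

# all genotype tables (lower-triangular count matrices) with copy counts m
enumerate_tables <- function(m) {
  k <- length(m)
  out <- list()
  cells <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i = i, j = seq_len(i))))   # (i,j) with j <= i, row-major by i
  rec <- function(idx, rem, tab) {
    if (idx > nrow(cells)) {
      if (all(rem == 0L)) out[[length(out) + 1L]] <<- tab
      return(invisible())
    }
    i <- cells[idx, "i"]; j <- cells[idx, "j"]
    max_n <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (nn in 0:max_n) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * nn
      else { rem2[i] <- rem2[i] - nn; rem2[j] <- rem2[j] - nn }
      # once the last cell of column j (= row k) passes, rem[j] must be 0
      tab2 <- tab; tab2[i, j] <- nn
      if (i == k && rem2[j] != 0L) next
      rec(idx + 1L, rem2, tab2)
    }
  }
  rec(1L, as.integer(m), matrix(0L, k, k))
  out
}

# Markov chain over pairings of gene copies; p = fraction of visited states
# with conditional probability <= observed
hwe_chain <- function(i1, i2, logp_obs, steps, burn) {
  n <- length(i1)
  k <- max(c(i1, i2))
  pairs <- cbind(i1, i2)
  tab <- matrix(0L, k, k)
  for (t in seq_len(n)) {
    i <- max(pairs[t, ]); j <- min(pairs[t, ])
    tab[i, j] <- tab[i, j] + 1L
  }
  # constant part of log P; track the table-dependent part incrementally
  const <- lfactorial(n) + sum(lfactorial(allele_copy_counts(tab))) -
    lfactorial(2 * n)
  sumlf <- sum(lfactorial(tab[lower.tri(tab, diag = TRUE)]))
  H <- n - sum(diag(tab))
  logp <- const + H * log(2) - sumlf
  hits <- 0L
  total <- steps + burn
  u_pair <- matrix(sample.int(n, 2L * total, replace = TRUE), ncol = 2L)
  u_side <- matrix(runif(2L * total) < 0.5, ncol = 2L)
  for (s in seq_len(total)) {
    p1 <- u_pair[s, 1]; p2 <- u_pair[s, 2]
    if (p1 != p2) {
      c1 <- if (u_side[s, 1]) 1L else 2L
      c2 <- if (u_side[s, 2]) 1L else 2L
      for (t in c(p1, p2)) {
        i <- max(pairs[t, ]); j <- min(pairs[t, ])
        sumlf <- sumlf - lfactorial(tab[i, j])
        tab[i, j] <- tab[i, j] - 1L
        sumlf <- sumlf + lfactorial(tab[i, j])
        if (i != j) H <- H - 1L
      }
      tmp <- pairs[p1, c1]
      pairs[p1, c1] <- pairs[p2, c2]
      pairs[p2, c2] <- tmp
      for (t in c(p1, p2)) {
        i <- max(pairs[t, ]); j <- min(pairs[t, ])
        sumlf <- sumlf - lfactorial(tab[i, j])
        tab[i, j] <- tab[i, j] + 1L
        sumlf <- sumlf + lfactorial(tab[i, j])
        if (i != j) H <- H + 1L
      }
      logp <- const + H * log(2) - sumlf
    }
    if (s > burn && logp <= logp_obs + 1e-9) hits <- hits + 1L
  }
  hits / steps
}
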