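#' Ewens-Watterson homozygosity test of neutrality
#'
#' Compares the observed homozygosity \eqn{F = \sum_i p_i^2} of an allele
#' configuration to its neutral null distribution conditional on the sample
#' size (gene copies) and the observed number of distinct alleles `k`.
#' Null configurations are drawn from the Ewens sampling formula: the
#' scaled mutation rate theta is solved from \eqn{E[K] = \sum_{i=0}^{n-1}
#' \theta/(\theta+i) = k} by Newton iteration, samples are generated by the
#' Chinese-restaurant construction, and draws are rejected until they carry
#' exactly `k` alleles (the classic conditional-on-k construction). The
#' one-sided p-value is the fraction of null samples at least as homozygous
#' as observed, so small p flags excess homozygosity and p near 1 flags the
#' excess evenness expected under balancing selection.
#'
#' @param counts Per-allele gene-copy counts (zeros allowed, ignored).
#' @param n_sim Number of accepted null samples (default 1,000).
#' @param seed Integer RNG seed.
#' @return List with `F_obs`, `p` (one-sided, P(F_null >= F_obs)), `theta`,
#'   `n`, `k`, and the vector `F_null` of simulated homozygosities.
#' @export
#' @examples
#' ewens_watterson_test(c(3, 9, 10, 6, 1, 2, 0, 7), n_sim = 200, seed = 1)$F_obs
ewens_watterson_test <- function(counts, n_sim = 1000L, seed = 1L) {
  counts <- counts[!is.na(counts) & counts > 0]
  n <- sum(counts)
  k <- length(counts)
  if (n < 2) abort("Need at least 2 gene copies.")
  if (k < 2) abort("Ewens-Watterson test undefined for a monomorphic sample.")
  F_obs <- sum((counts / n)^2)
  if (k == n) {
    # all-singleton sample: the conditional null is degenerate at F = 1/n
    return(list(F_obs = F_obs, p = 1, theta = Inf, n = n, k = k,
                F_null = rep(1 / n, n_sim)))
  }
  theta <- solve_theta(n, k)
  set.seed(as.integer(seed))
  F_null <- numeric(n_sim)
  got <- 0L
  tries <- 0L
  max_tries <- 2000L * n_sim
  while (got < n_sim && tries < max_tries) {
    tries <- tries + 1L
    cfg <- rcrp(n, theta)
    if (length(cfg) == k) {
      got <- got + 1L
      F_null[got] <- sum((cfg / n)^2)
    }
  }
  if (got < n_sim) {
    warn("Low acceptance in the conditional Ewens sampler; p based on fewer draws.")
    F_null <- F_null[seq_len(got)]
  }
  list(F_obs = F_obs, p = mean(F_null >= F_obs - 1e-12), theta = theta,
       n = n, k = k, F_null = F_null)
}

# solve E[K](theta) = k for theta by Newton iteration on the monotone map
solve_theta <- function(n, k) {
  ek <- function(th) sum(th / (th + 0:(n - 1)))
  dek <- function(th) sum((0:(n - 1)) / (th + 0:(n - 1))^2)
  th <- 1
  for (it in seq_len(200L)) {
    f <- ek(th) - k
    if (abs(f) < 1e-10) break
    th <- th - f / dek(th)
    if (th <= 0) th <- 1e-8
  }
  th
}

# one Chinese-restaurant draw: allele configuration (unordered counts)
rcrp <- function(n, theta) {
  counts <- integer(0)
  for (j in seq_len(n)) {
    if (runif(1) < theta / (theta + j - 1)) {
      counts <- c(counts, 1L)
    } else {
      tab <- counts / (j - 1)
      pick <- sample.int(length(counts), 1L, prob = tab)
      counts[pick] <- counts[pick] + 1L
    }
  }
  counts
}
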