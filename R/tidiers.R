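# broom-style tidiers for the package's fitted objects

#' Tidy an AMOVA fit
#'
#' @param x An `mhc_amova` object.
#' @param ... Unused.
#' @return Tibble `level`, `df`, `sigma2`, `pct`, `p`.
#' @exportS3Method generics::tidy
tidy.mhc_amova <- function(x, ...) x$table

#' @rdname tidy.mhc_amova
#' @exportS3Method generics::glance
glance.mhc_amova <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm,
                 pct_within_individuals =
                   x$table$pct[x$table$level == "within_individuals"])
}

#' Tidy a repeatability estimate
#'
#' @param x An `mhc_repeatability` object.
#' @param ... Unused.
#' @return `tidy()`: the discordant pairs; `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.mhc_repeatability <- function(x, ...) x$discordant

#' @rdname tidy.mhc_repeatability
#' @exportS3Method generics::glance
glance.mhc_repeatability <- function(x, ...) {
  tibble::tibble(rate = x$rate, n_pairs = x$n_pairs,
                 n_discordant = x$n_discordant)
}

#' Tidy a window selection scan
#'
#' @param x An `mhc_scan` object.
#' @param ... Unused.
#' @return `tidy()`: per-window tibble; `glance()`: scan settings and the
#'   number of flagged windows.
#' @exportS3Method generics::tidy
tidy.mhc_scan <- function(x, ...) x$windows

#' @rdname tidy.mhc_scan
#' @exportS3Method generics::glance
glance.mhc_scan <- function(x, ...) {
  tibble::tibble(window_codons = x$window_codons, n_perm = x$n_perm,
                 threshold_prob = x$threshold_prob,
                 n_windows = nrow(x$windows),
                 n_flagged = sum(x$windows$flagged))
}
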