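#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a frame image into a long tibble
#'
#' @param x A `frame_image` (or `dose_map`).
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x_mm`, `y_mm`, `value`.
#' @export
tidy.frame_image <- function(x, ...) {
  pos <- frame_positions(x)
  tibble::tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    x_mm = rep(pos$row_mm, times = ncol(x)),
    y_mm = rep(pos$col_mm, each = nrow(x)),
    value = as.numeric(unclass(x))
  )
}

#' Tidy a kernel into its radial profile
#' @param x A [kernel()].
#' @param n_bins Annuli for [radial_profile()] (default 32).
#' @param ... Unused.
#' @return Tibble with `radius_mm`, `value`, `n_px`.
#' @export
tidy.kernel <- function(x, n_bins = 32, ...) radial_profile(x, n_bins)

#' Per-pixel gamma values as a tibble
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `gamma`, `evaluated`, `pass`.
#' @export
tidy.gamma_result <- function(x, ...) {
  gm <- x$gamma_map
  tibble::tibble(
    row = rep(seq_len(nrow(gm)), times = ncol(gm)),
    col = rep(seq_len(ncol(gm)), each = nrow(gm)),
    gamma = as.numeric(gm),
    evaluated = as.logical(x$evaluated_mask),
    pass = as.numeric(gm) <= 1
  )
}

#' One-row summary of a gamma comparison
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @return Tibble with the criteria, pass rate and evaluation counts.
#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(
    criterion = format_criteria(x$criteria),
    dose_diff_pct = x$criteria$dose_diff_pct,
    dta_mm = x$criteria$dta_mm,
    pass_rate_pct = x$pass_rate_pct,
    n_evaluated = x$n_evaluated,
    n_excluded_edge = x$n_excluded_edge,
    mean_gamma = mean(x$gamma_map[x$evaluated_mask]),
    max_gamma = if (x$n_evaluated) max(x$gamma_map[x$evaluated_mask])
                else NA_real_
  )
}
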