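#' Photon energy modes
#'
#' The five beam modes of a modern C-arm linac: 6, 10 and 15 MV with a
#' flattening filter (WFF) and 6, 10 MV flattening-filter-free (FFF).
#' Each mode carries the depth of dose maximum in water, `d_max`, which is
#' the plane where dose maps are reconstructed: 1.5 cm for 6 MV and
#' 6 MV FFF, 2.5 cm for 10 MV and 10 MV FFF, 3.0 cm for 15 MV.
#'
#' @param name One of `"6MV_WFF"`, `"10MV_WFF"`, `"15MV_WFF"`, `"6MV_FFF"`,
#'   `"10MV_FFF"`.
#' @return An object of class `energy_mode`: a list with `name`,
#'   `nominal_MV`, `d_max_cm` and `has_flattening_filter`.
#' @examples
#' energy_mode("6MV_FFF")$d_max_cm
#' @export
energy_mode <- function(name) {
  name <- match.arg(name, names(.d_max_table))
  structure(
    list(
      name = name,
      nominal_MV = as.numeric(sub("MV.*", "", name)),
      d_max_cm = .d_max_table[[name]],
      has_flattening_filter = grepl("WFF$", name)
    ),
    class = "energy_mode"
  )
}

.d_max_table <- c(
  "6MV_WFF" = 1.5, "6MV_FFF" = 1.5,
  "10MV_WFF" = 2.5, "10MV_FFF" = 2.5,
  "15MV_WFF" = 3.0
)

#' All supported energy-mode names
#' @return Character vector of the five mode names.
#' @export
energy_mode_names <- function() names(.d_max_table)

as_energy_mode <- function(mode) {
  if (inherits(mode, "energy_mode")) return(mode)
  energy_mode(mode)
}

#' @export
print.energy_mode <- function(x, ...) {
  cat(sprintf(
    "<energy_mode> %s (%s), d_max = %.1f cm\n",
    x$name, if (x$has_flattening_filter) "flattened" else "filter-free",
    x$d_max_cm
  ))
  invisible(x)
}
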