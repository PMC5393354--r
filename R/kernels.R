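#' Kernel container
#'
#' A 2D point response on a square grid with the peak at the centre bin:
#' either the detector glare/deconvolution kernel (`"glare"`) or the
#' water pencil-beam dose kernel (`"pencil_beam"`).
#'
#' @param values Non-negative (2h+1) x (2h+1) matrix.
#' @param pitch_mm Grid spacing in mm.
#' @param kind `"glare"` or `"pencil_beam"`.
#' @param mode [energy_mode()] or name (optional).
#' @param normalization `"sum_to_one"` (default; enforced) or
#'   `"peak_to_one"`.
#' @param meta Optional named list (histories, seed, uncertainty map ...).
#' @return A `kernel` object (matrix with attributes).
#' @export
kernel <- function(values, pitch_mm, kind = c("glare", "pencil_beam"),
                   mode = NULL,
                   normalization = c("sum_to_one", "peak_to_one"),
                   meta = list()) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) %% 2L == 0L)
    stop("kernel must be square with odd dimensions, got ",
         nrow(values), "x", ncol(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("kernel values must be finite and non-negative")
  if (normalization == "sum_to_one") {
    s <- sum(values)
    if (s <= 0) stop("kernel sums to zero")
    values <- values / s
  } else {
    values <- values / max(values)
  }
  if (!is.null(mode)) mode <- as_energy_mode(mode)
  structure(values, pitch_mm = pitch_mm, kind = kind, mode = mode,
            normalization = normalization, meta = meta,
            class = c("kernel", "matrix", "array"))
}

#' @export
print.kernel <- function(x, ...) {
  h <- (nrow(x) - 1L) %/% 2L
  cat(sprintf(
    "<kernel> %s, %d x %d px @ %.3g mm (half-size %d), centre bin %.3g%s\n",
    attr(x, "kind"), nrow(x), ncol(x), pitch_mm(x), h,
    x[h + 1L, h + 1L],
    if (is.null(attr(x, "mode"))) "" else paste0(" [", attr(x, "mode")$name, "]")
  ))
  invisible(x)
}

kernel_half_size <- function(k) (nrow(k) - 1L) %/% 2L

#' Packaged glare-kernel parameters per energy mode
#'
#' The detector point response is modelled as a narrow Gaussian core
#' (optical spread in the scintillator, sub-mm) carrying most of the
#' response, plus two exponential tails (optical glare and backscatter,
#' few-mm and ~cm scales) at the few-percent level. Higher-energy beams
#' get a slightly broader core; filter-free modes a marginally larger
#' tail fraction (softer spectrum, more low-energy scatter).
#'
#' @param mode [energy_mode()] or name.
#' @return A `glare_params` list: `core_weight`, `core_sigma_mm`, `tails`
#'   (list of `c(weight, scale_mm)`), `mode`.
#' @export
default_glare_params <- function(mode) {
  mode <- as_energy_mode(mode)
  width <- 1 + 0.05 * (mode$nominal_MV - 6) / 9 # mild energy broadening
  tail_w <- if (mode$has_flattening_filter) 0.055 else 0.065
  glare_params(
    core_weight = 1 - tail_w - 0.018,
    core_sigma_mm = 0.35 * width,
    tails = list(c(tail_w, 2.5 * width), c(0.018, 12 * width)),
    mode = mode
  )
}

#' Construct glare-kernel parameters
#' @param core_weight Weight of the Gaussian core (all weights sum to 1).
#' @param core_sigma_mm Core standard deviation, mm; must be below the
#'   smallest tail scale.
#' @param tails List of `c(weight, scale_mm)` exponential components.
#' @param mode Optional [energy_mode()].
#' @return A `glare_params` object.
#' @export
glare_params <- function(core_weight, core_sigma_mm, tails = list(),
                         mode = NULL) {
  w <- c(core_weight, vapply(tails, `[`, 0, 1L))
  if (any(w <= 0)) stop("all component weights must be positive")
  if (abs(sum(w) - 1) > 1e-8)
    stop("component weights must sum to 1 (got ", sum(w), ")")
  scales <- vapply(tails, `[`, 0, 2L)
  if (any(scales <= 0)) stop("tail scales must be positive")
  if (length(scales) && core_sigma_mm >= min(scales))
    stop("core sigma must be smaller than the smallest tail scale")
  if (!is.null(mode)) mode <- as_energy_mode(mode)
  structure(list(core_weight = core_weight, core_sigma_mm = core_sigma_mm,
                 tails = tails, mode = mode),
            class = "glare_params")
}

#' Build the glare / deconvolution kernel
#'
#' Discretises the radial model
#' `K(r) = w0 * G(r; sigma) + sum_i w_i * Exp(r; s_i)`
#' (each component normalised to unit 2D integral: the Gaussian as
#' `exp(-r^2/2 sigma^2) / (2 pi sigma^2)`, each exponential as
#' `exp(-r/s) / (2 pi s^2)`) on the pixel grid and sum-normalises.
#' The result is radially symmetric and monotone non-increasing.
#'
#' @param params [glare_params()] (or [default_glare_params()] output).
#' @param pitch_mm Grid spacing.
#' @param half_size_px Kernel half width in pixels (>= 8); the kernel is
#'   `(2*half_size_px+1)^2`.
#' @return A `kernel` of kind `"glare"`, sum-normalised.
#' @export
build_glare_kernel <- function(params, pitch_mm, half_size_px = 32L) {
  stopifnot(inherits(params, "glare_params"))
  if (half_size_px < 8L) stop("half_size_px must be at least 8")
  x <- (-half_size_px:half_size_px) * pitch_mm
  r <- sqrt(outer(x^2, x^2, `+`))
  s2 <- params$core_sigma_mm^2
  v <- params$core_weight * exp(-r^2 / (2 * s2)) / (2 * pi * s2)
  for (tl in params$tails) {
    v <- v + tl[1L] * exp(-r / tl[2L]) / (2 * pi * tl[2L]^2)
  }
  kernel(v * pitch_mm^2, pitch_mm = pitch_mm, kind = "glare",
         mode = params$mode,
         meta = list(params = unclass(params)))
}

#' Azimuthally averaged radial profile of a kernel
#'
#' Mean kernel value in equal-width annuli about the centre bin, the
#' standard way point-response kernels are displayed and compared.
#'
#' @param k A [kernel()].
#' @param n_bins Number of annuli (>= 4).
#' @return Tibble with `radius_mm` (annulus mid-radius), `value` (mean),
#'   `n_px` (pixels in the annulus).
#' @export
radial_profile <- function(k, n_bins = 32) {
  if (n_bins < 4) stop("n_bins must be at least 4")
  h <- kernel_half_size(k)
  x <- (-h:h) * pitch_mm(k)
  r <- sqrt(outer(x^2, x^2, `+`))
  r_max <- max(abs(x)) + pitch_mm(k) / 2
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  bin <- pmin(findInterval(r, breaks, rightmost.closed = TRUE), n_bins)
  tibble::tibble(
    radius_mm = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
    value = as.numeric(tapply(as.numeric(k), factor(bin, levels = seq_len(n_bins)),
                              mean, default = NA_real_)),
    n_px = as.integer(table(factor(bin, levels = seq_len(n_bins))))
  )
}

#' Resample a kernel to a different pitch
#'
#' Bilinear resampling onto a new grid of the same physical extent,
#' then renormalisation. Pitch mismatches between kernel and image are an
#' error everywhere in the pipeline; this is the explicit remedy.
#'
#' @param k A [kernel()].
#' @param new_pitch_mm Target spacing.
#' @return A `kernel` at the new pitch.
#' @export
resample_kernel <- function(k, new_pitch_mm) {
  h_old_mm <- kernel_half_size(k) * pitch_mm(k)
  h_new <- max(8L, floor(h_old_mm / new_pitch_mm))
  x <- (-h_new:h_new) * new_pitch_mm
  pts <- expand.grid(row = x, col = x)
  v <- interp_bilinear(unclass(k), pitch_mm(k), pts$row, pts$col)
  v[is.na(v)] <- 0
  kernel(matrix(pmax(v, 0), 2 * h_new + 1L), pitch_mm = new_pitch_mm,
         kind = attr(k, "kind"), mode = attr(k, "mode"),
         meta = attr(k, "meta"))
}

#' Store / load a kernel
#'
#' CSV matrix + JSON metadata (`kind`, `energy_mode`, `pitch_mm`,
#' `center`, `normalization`, plus any Monte Carlo provenance).
#'
#' @param k A [kernel()].
#' @param stem Path stem.
#' @return `stem` (write) / a `kernel` (read).
#' @export
write_kernel <- function(k, stem) {
  h <- kernel_half_size(k)
  meta <- c(
    list(kind = attr(k, "kind"),
         energy_mode = if (is.null(attr(k, "mode"))) NA else attr(k, "mode")$name,
         pitch_mm = pitch_mm(k),
         center = c(h + 1L, h + 1L),
         normalization = attr(k, "normalization")),
    attr(k, "meta")[setdiff(names(attr(k, "meta")), c("uncertainty", "params"))]
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    format(unclass(k), digits = 17, scientific = TRUE, trim = TRUE),
    paste0(stem, ".csv"), sep = ",",
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(stem)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ",",
                                   header = FALSE, colClasses = "numeric"))
  dimnames(m) <- NULL
  kernel(m, pitch_mm = meta$pitch_mm, kind = meta$kind,
         mode = if (is.na(meta$energy_mode)) NULL else meta$energy_mode,
         normalization = meta$normalization,
         meta = meta[setdiff(names(meta),
                             c("kind", "energy_mode", "pitch_mm", "center",
                               "normalization"))])
}
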