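#' Gamma-index criteria
#'
#' @param dose_diff_pct Dose-difference criterion as percent of the
#'   global maximum of the reference distribution (global normalisation).
#' @param dta_mm Distance-to-agreement criterion in mm.
#' @param threshold_frac Low-dose cutoff: evaluated points must exceed
#'   this fraction of the reference maximum (default 0.10).
#' @param search_radius_factor Spatial search bound as a multiple of
#'   `dta_mm` (default 3).
#' @param interp_factor Integer upsampling factor applied to the
#'   reference for subpixel distance-to-agreement (default 4).
#' @param normalization `"global"` (default) or `"local"` (dose
#'   difference relative to the local reference value; provided as an
#'   option, the validation protocol uses global).
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 3,
                           threshold_frac = 0.10,
                           search_radius_factor = 3, interp_factor = 4L,
                           normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  if (dose_diff_pct <= 0 || dta_mm <= 0 || search_radius_factor <= 0)
    stop("criteria must be positive")
  if (threshold_frac < 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in [0, 1)")
  interp_factor <- as.integer(interp_factor)
  if (interp_factor < 1L) stop("interp_factor must be a positive integer")
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 threshold_frac = threshold_frac,
                 search_radius_factor = search_radius_factor,
                 interp_factor = interp_factor,
                 normalization = normalization),
            class = "gamma_criteria")
}

format_criteria <- function(crit) {
  sprintf("%g%%/%gmm", crit$dose_diff_pct, crit$dta_mm)
}

#' 2D gamma-index comparison of two dose distributions
#'
#' For every evaluated point (dose above the low-dose threshold) the
#' gamma index is the minimum over nearby reference points of
#' `sqrt(dist^2 / dta^2 + (D_eval - D_ref)^2 / dD^2)`, with `dD` the
#' dose criterion as a fraction of the reference global maximum. The
#' comparison runs on the evaluated grid; the reference is bilinearly
#' resampled once onto a lattice refined by `interp_factor` and searched
#' over all offsets within `search_radius_factor * dta_mm`, visited in
#' order of increasing distance with early termination (identical to the
#' exhaustive search within the radius). Grids may differ in pitch, e.g.
#' a 10 mm ion-chamber array against a 0.2 mm EPID grid. Evaluated points
#' whose entire search region falls outside the reference extent are
#' excluded from the evaluated mask.
#'
#' @param eval_dose `dose_map`/`frame_image` being tested.
#' @param ref_dose Reference `dose_map`/`frame_image`.
#' @param crit A [gamma_criteria()].
#' @return A `gamma_result`: list with `gamma_map` (matrix, `NA` where
#'   not evaluated), `evaluated_mask`, `pass_rate_pct`, `n_evaluated`,
#'   `n_excluded_edge` and `criteria`.
#' @export
gamma_index <- function(eval_dose, ref_dose, crit = gamma_criteria()) {
  ref_max <- max(unclass(ref_dose))
  if (ref_max <= 0) stop("reference distribution has non-positive maximum")
  ep <- pitch_mm(eval_dose)
  rp <- pitch_mm(ref_dose)
  # refined lattice aligned with the evaluated grid: spacing eval_pitch/k,
  # with k chosen so it is at least as fine as ref_pitch / interp_factor
  k <- max(1L, as.integer(ceiling(ep * crit$interp_factor / rp)))
  h <- ep / k
  radius <- crit$search_radius_factor * crit$dta_mm
  pos_e <- frame_positions(eval_dose)
  # lattice covering the evaluated grid plus the search radius
  n_ext <- ceiling(radius / h)
  lat_r <- seq(pos_e$row_mm[1] - n_ext * h,
               by = h, length.out = (nrow(eval_dose) - 1L) * k + 2L * n_ext + 1L)
  lat_c <- seq(pos_e$col_mm[1] - n_ext * h,
               by = h, length.out = (ncol(eval_dose) - 1L) * k + 2L * n_ext + 1L)
  grid <- expand.grid(row = lat_r, col = lat_c)
  ref_fine <- matrix(
    interp_bilinear(unclass(ref_dose), rp, grid$row, grid$col),
    nrow = length(lat_r)
  )
  if (all(is.na(ref_fine))) stop("dose distributions do not overlap")
  de <- unclass(eval_dose)
  eval_sel <- de > crit$threshold_frac * ref_max
  # lattice indices of the evaluated pixel centres
  er <- n_ext + 1L + (seq_len(nrow(eval_dose)) - 1L) * k
  ec <- n_ext + 1L + (seq_len(ncol(eval_dose)) - 1L) * k
  idx <- which(eval_sel, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    gm <- matrix(NA_real_, nrow(eval_dose), ncol(eval_dose))
    return(new_gamma_result(gm, eval_sel & FALSE, crit, 0L))
  }
  pr <- er[idx[, 1L]]
  pc <- ec[idx[, 2L]]
  dvals <- de[idx]
  dd_abs <- crit$dose_diff_pct / 100 *
    (if (crit$normalization == "global") ref_max else NA)
  # offsets sorted by distance
  off <- expand.grid(dr = -n_ext:n_ext, dc = -n_ext:n_ext)
  dist2 <- (off$dr * h)^2 + (off$dc * h)^2
  keep <- dist2 <= radius^2 + 1e-12
  off <- off[keep, ]
  dist2 <- dist2[keep]
  ord <- order(dist2)
  off <- off[ord, ]
  dist_term <- dist2[ord] / crit$dta_mm^2
  best <- rep(Inf, length(dvals))
  any_ref <- rep(FALSE, length(dvals))
  nlr <- length(lat_r)
  for (j in seq_len(nrow(off))) {
    dt <- dist_term[j]
    mx <- max(best)
    if (dt >= mx) break
    rv <- ref_fine[cbind(pr + off$dr[j], pc + off$dc[j])]
    ok <- !is.na(rv)
    if (!any(ok)) next
    any_ref <- any_ref | ok
    denom <- if (crit$normalization == "global") dd_abs
             else crit$dose_diff_pct / 100 * rv[ok]
    g2 <- dt + (dvals[ok] - rv[ok])^2 / denom^2
    upd <- g2 < best[ok]
    bi <- which(ok)[upd]
    best[bi] <- g2[which(upd)]
  }
  gamma <- sqrt(best)
  gm <- matrix(NA_real_, nrow(eval_dose), ncol(eval_dose))
  mask <- matrix(FALSE, nrow(eval_dose), ncol(eval_dose))
  n_excl <- sum(!any_ref)
  gm[idx[any_ref, , drop = FALSE]] <- gamma[any_ref]
  mask[idx[any_ref, , drop = FALSE]] <- TRUE
  new_gamma_result(gm, mask, crit, n_excl)
}

new_gamma_result <- function(gamma_map, mask, crit, n_excluded) {
  n_eval <- sum(mask)
  pass <- if (n_eval) 100 * sum(gamma_map[mask] <= 1) / n_eval else NA_real_
  structure(list(gamma_map = gamma_map, evaluated_mask = mask,
                 pass_rate_pct = pass, n_evaluated = n_eval,
                 n_excluded_edge = n_excluded, criteria = crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %s: pass rate %.1f%% over %d evaluated px (%d edge-excluded)\n",
    format_criteria(x$criteria), x$pass_rate_pct, x$n_evaluated,
    x$n_excluded_edge
  ))
  invisible(x)
}

#' Pass-rate table over a set of criteria
#'
#' Runs [gamma_index()] at several criteria (default the standard
#' 3%/3mm, 2%/2mm, 1%/1mm ladder) and tabulates the pass rates, the
#' layout used for field-by-field QA reporting.
#'
#' @param eval_dose,ref_dose Dose distributions as in [gamma_index()].
#' @param criteria List of [gamma_criteria()] (or `c(pct, mm)` pairs).
#' @param label Row label (e.g. field description).
#' @return Tibble with `label`, `criterion`, `dose_diff_pct`, `dta_mm`,
#'   `pass_rate_pct`, `n_evaluated`.
#' @export
gamma_report <- function(eval_dose, ref_dose,
                         criteria = list(c(3, 3), c(2, 2), c(1, 1)),
                         label = "field") {
  rows <- lapply(criteria, function(cr) {
    crit <- if (inherits(cr, "gamma_criteria")) cr
            else gamma_criteria(dose_diff_pct = cr[1L], dta_mm = cr[2L])
    res <- gamma_index(eval_dose, ref_dose, crit)
    tibble::tibble(label = label,
                   criterion = format_criteria(crit),
                   dose_diff_pct = crit$dose_diff_pct,
                   dta_mm = crit$dta_mm,
                   pass_rate_pct = res$pass_rate_pct,
                   n_evaluated = res$n_evaluated)
  })
  dplyr::bind_rows(rows)
}
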