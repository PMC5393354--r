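# Desk-scale photon Monte Carlo for pencil-beam dose kernels in water,
# under the kerma approximation: energy transferred to electrons is
# deposited at the interaction point (so kernel cores are slightly
# narrower than with electron transport). Photons are transported in
# batches of vectorised histories; secondaries from pair production join
# the active set. Geometry: a 30 cm water cube, beam entering at the
# centre of the top face along +z; photons leaving the cube are scored as
# escaped, so energy bookkeeping closes exactly.

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Kahn's composition-rejection method, exact for all photon energies.
#' Used internally by the transport loop and exported so the sampling can
#' be validated against the analytic differential cross section.
#'
#' @param E_MeV Incident photon energy (scalar, MeV).
#' @param n Number of samples.
#' @param seed Optional RNG seed.
#' @return Tibble with `cos_theta` (scattering angle cosine) and
#'   `E_out_MeV` (scattered photon energy).
#' @export
sample_klein_nishina <- function(E_MeV, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- kahn_sample(rep(E_MeV, n))
  alpha <- E_MeV / ELECTRON_REST_MEV
  tibble::tibble(
    cos_theta = 1 - (eta - 1) / alpha,
    E_out_MeV = E_MeV / eta
  )
}

# eta = E/E' in [1, 1+2 alpha], vectorised over photon energies.
kahn_sample <- function(E_MeV) {
  alpha <- E_MeV / ELECTRON_REST_MEV
  n <- length(alpha)
  eta <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    a <- alpha[todo]
    r1 <- stats::runif(length(todo))
    r2 <- stats::runif(length(todo))
    r3 <- stats::runif(length(todo))
    branch1 <- r1 <= (1 + 2 * a) / (9 + 2 * a)
    cand <- ifelse(branch1, 1 + 2 * a * r2, (1 + 2 * a) / (1 + 2 * a * r2))
    ct <- 1 - (cand - 1) / a
    acc <- ifelse(branch1,
                  r3 <= 4 * (1 / cand - 1 / cand^2),
                  r3 <= (ct^2 + 1 / cand) / 2)
    eta[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  eta
}

#' Klein-Nishina angular density (unnormalised)
#'
#' `dsigma/dcos(theta)` up to a constant: the analytic curve the sampled
#' scattering angles are tested against.
#'
#' @param E_MeV Incident photon energy (MeV).
#' @param cos_theta Scattering angle cosines.
#' @return Unnormalised density values.
#' @export
klein_nishina_density <- function(E_MeV, cos_theta) {
  alpha <- E_MeV / ELECTRON_REST_MEV
  ratio <- 1 / (1 + alpha * (1 - cos_theta)) # E'/E
  ratio^2 * (ratio + 1 / ratio - (1 - cos_theta^2))
}

# Rotate unit vectors (ux,uy,uz) by polar angle theta (cos ct) and
# azimuth phi about their own axis.
rotate_direction <- function(ux, uy, uz, ct, phi) {
  st <- sqrt(pmax(0, 1 - ct^2))
  cp <- cos(phi); sp <- sin(phi)
  denom <- sqrt(pmax(1e-24, 1 - uz^2))
  straight <- denom < 1e-10
  nx <- ux * ct + st * (ux * uz * cp - uy * sp) / denom
  ny <- uy * ct + st * (uy * uz * cp + ux * sp) / denom
  nz <- uz * ct - denom * st * cp
  nx[straight] <- (st * cp)[straight]
  ny[straight] <- (st * sp)[straight]
  nz[straight] <- (sign(uz) * ct)[straight]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  list(ux = nx / nrm, uy = ny / nrm, uz = nz / nrm)
}

#' Generate a pencil-beam dose kernel by Monte Carlo
#'
#' Transports a normally incident pencil beam of photons, sampled from
#' `spectrum`, through a water cube. Free paths are sampled from the total
#' attenuation coefficient; at each interaction the channel is chosen
#' among Compton (Klein-Nishina energy/angle), photoelectric (local
#' absorption) and pair production (local deposition of E - 1.022 MeV
#' plus two opposed 0.511 MeV annihilation photons). Energy transferred
#' to electrons is deposited at the interaction point (kerma
#' approximation). Dose is tallied on a 2D grid in a slab of stated
#' thickness centred at `depth_cm`, and the kernel is sum-normalised.
#' Histories are split into `n_batches` independent batches; the per-bin
#' relative standard error over batches is reported in the kernel
#' metadata, together with the full energy bookkeeping and the primary
#' (never-interacted) transmission past `depth_cm`.
#'
#' @param spectrum A [photon_spectrum()] (may be a single line).
#' @param xs A [cross_section_table()].
#' @param depth_cm Tally depth (the mode's d_max), within the cube.
#' @param pitch_mm Tally grid spacing.
#' @param half_size_px Tally half width in pixels.
#' @param n_histories Total primary histories (>= 1e4).
#' @param seed Mandatory RNG seed.
#' @param n_batches Batches for the uncertainty estimate (default 10).
#' @param cube_cm Water cube side (default 30).
#' @param slab_thickness_cm Tally slab thickness (default 0.2, i.e. 2 mm).
#' @param cutoff_MeV Photons below this energy are absorbed locally
#'   (default 0.01).
#' @return A `kernel` of kind `"pencil_beam"`; `attr(k, "meta")` holds
#'   `n_histories`, `seed`, `rel_uncertainty` (matrix), `energy`
#'   (launched / deposited / escaped, MeV) and `primary_transmission`.
#' @export
generate_pencil_beam_kernel <- function(spectrum, xs, depth_cm,
                                        pitch_mm = 1, half_size_px = 30L,
                                        n_histories = 1e5, seed,
                                        n_batches = 10L, cube_cm = 30,
                                        slab_thickness_cm = 0.2,
                                        cutoff_MeV = 0.01) {
  stopifnot(inherits(spectrum, "photon_spectrum"),
            inherits(xs, "cross_section_table"))
  if (missing(seed)) stop("seed is mandatory for kernel generation")
  if (n_histories < 1e4) stop("n_histories must be at least 1e4")
  if (depth_cm <= 0 || depth_cm >= cube_cm)
    stop("depth_cm must lie inside the water cube (0, ", cube_cm, ")")
  set.seed(seed)
  n_side <- 2L * half_size_px + 1L
  per_batch <- ceiling(n_histories / n_batches)
  tallies <- array(0, dim = c(n_side, n_side, n_batches))
  launched <- deposited <- escaped <- 0
  n_primary_past <- 0L
  for (b in seq_len(n_batches)) {
    res <- mc_transport_batch(per_batch, spectrum, xs, depth_cm,
                              pitch_mm, half_size_px, cube_cm,
                              slab_thickness_cm, cutoff_MeV)
    tallies[, , b] <- res$tally
    launched <- launched + res$launched
    deposited <- deposited + res$deposited
    escaped <- escaped + res$escaped
    n_primary_past <- n_primary_past + res$n_primary_past
  }
  total <- apply(tallies, c(1, 2), sum)
  bmean <- total / n_batches
  bsd <- sqrt(apply(sweep(tallies, c(1, 2), bmean)^2, c(1, 2), sum) /
                (n_batches - 1))
  rel_se <- bsd / sqrt(n_batches) / pmax(bmean, .Machine$double.xmin)
  rel_se[total == 0] <- NA_real_
  kernel(total, pitch_mm = pitch_mm, kind = "pencil_beam",
         mode = spectrum$mode,
         meta = list(
           n_histories = n_batches * per_batch, seed = seed,
           depth_cm = depth_cm, slab_thickness_cm = slab_thickness_cm,
           rel_uncertainty = rel_se,
           energy = list(launched_MeV = launched,
                         deposited_MeV = deposited,
                         escaped_MeV = escaped),
           primary_transmission = n_primary_past / (n_batches * per_batch)
         ))
}

# One batch of vectorised histories; returns the slab tally and the
# energy ledger.
mc_transport_batch <- function(n, spectrum, xs, depth_cm, pitch_mm,
                               half_size_px, cube_cm, slab_thickness_cm,
                               cutoff_MeV) {
  n_side <- 2L * half_size_px + 1L
  half_cm <- cube_cm / 2
  pitch_cm <- pitch_mm / 10
  z_lo <- depth_cm - slab_thickness_cm / 2
  z_hi <- depth_cm + slab_thickness_cm / 2
  ebin <- sample.int(length(spectrum$energy_MeV), n, replace = TRUE,
                     prob = spectrum$weights)
  E <- spectrum$energy_MeV[ebin]
  launched <- sum(E)
  x <- y <- numeric(n); z <- numeric(n)
  ux <- uy <- numeric(n); uz <- rep(1, n)
  primary <- rep(TRUE, n)
  tally <- matrix(0, n_side, n_side)
  deposited <- escaped <- 0
  n_primary_past <- 0L
  deposit <- function(xx, yy, zz, ee) {
    deposited <<- deposited + sum(ee)
    in_slab <- zz >= z_lo & zz <= z_hi
    if (!any(in_slab)) return(invisible())
    ri <- round(xx[in_slab] / pitch_cm) + half_size_px + 1L
    ci <- round(yy[in_slab] / pitch_cm) + half_size_px + 1L
    on <- ri >= 1L & ri <= n_side & ci >= 1L & ci <= n_side
    if (any(on)) {
      lin <- (ci[on] - 1L) * n_side + ri[on]
      add <- tabulate_weighted(lin, ee[in_slab][on], n_side * n_side)
      tally <<- tally + matrix(add, n_side, n_side)
    }
    invisible()
  }
  while (length(E)) {
    mu <- mu_water(xs, E)
    s <- stats::rexp(length(E)) / mu
    if (any(primary)) {
      # first flight of an original photon travels straight down +z
      n_primary_past <- n_primary_past + sum(primary & s > depth_cm)
    }
    x <- x + ux * s; y <- y + uy * s; z <- z + uz * s
    out <- abs(x) > half_cm | abs(y) > half_cm | z < 0 | z > cube_cm
    escaped <- escaped + sum(E[out])
    keep <- !out
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]
    E <- E[keep]; primary <- rep(FALSE, length(E))
    if (!length(E)) break
    # choose the interaction channel
    mu_t <- mu_water(xs, E)
    p_pe <- mu_water(xs, E, "mu_photoelectric") / mu_t
    p_pair <- mu_water(xs, E, "mu_pair") / mu_t
    u <- stats::runif(length(E))
    is_pe <- u < p_pe
    is_pair <- !is_pe & u < p_pe + p_pair & E > 2 * ELECTRON_REST_MEV
    is_co <- !is_pe & !is_pair
    if (any(is_pe)) deposit(x[is_pe], y[is_pe], z[is_pe], E[is_pe])
    # pair production: local deposit of E - 2 m_e c^2, two opposed
    # annihilation photons with isotropic orientation
    nx <- ny <- nz <- nux <- nuy <- nuz <- nE <- numeric(0)
    if (any(is_pair)) {
      ee <- E[is_pair] - 2 * ELECTRON_REST_MEV
      deposit(x[is_pair], y[is_pair], z[is_pair], ee)
      np <- sum(is_pair)
      ct <- stats::runif(np, -1, 1)
      ph <- stats::runif(np, 0, 2 * pi)
      st <- sqrt(1 - ct^2)
      dx <- st * cos(ph); dy <- st * sin(ph); dz <- ct
      nx <- rep(x[is_pair], 2L); ny <- rep(y[is_pair], 2L)
      nz <- rep(z[is_pair], 2L)
      nux <- c(dx, -dx); nuy <- c(dy, -dy); nuz <- c(dz, -dz)
      nE <- rep(ELECTRON_REST_MEV, 2L * np)
    }
    # Compton: deposit the electron share, scatter the photon
    if (any(is_co)) {
      eta <- kahn_sample(E[is_co])
      Eout <- E[is_co] / eta
      ct <- 1 - (eta - 1) * ELECTRON_REST_MEV / E[is_co]
      deposit(x[is_co], y[is_co], z[is_co], E[is_co] - Eout)
      ph <- stats::runif(sum(is_co), 0, 2 * pi)
      dirs <- rotate_direction(ux[is_co], uy[is_co], uz[is_co], ct, ph)
      low <- Eout < cutoff_MeV
      if (any(low))
        deposit(x[is_co][low], y[is_co][low], z[is_co][low], Eout[low])
      ok <- !low
      nx <- c(nx, x[is_co][ok]); ny <- c(ny, y[is_co][ok])
      nz <- c(nz, z[is_co][ok])
      nux <- c(nux, dirs$ux[ok]); nuy <- c(nuy, dirs$uy[ok])
      nuz <- c(nuz, dirs$uz[ok])
      nE <- c(nE, Eout[ok])
    }
    x <- nx; y <- ny; z <- nz
    ux <- nux; uy <- nuy; uz <- nuz
    E <- nE
    primary <- rep(FALSE, length(E))
  }
  list(tally = tally, launched = launched, deposited = deposited,
       escaped = escaped, n_primary_past = n_primary_past)
}

# sum weights w into `nbins` cells indexed by `idx`
tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  tmp <- rowsum(w, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1L]
  out
}
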