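# Water photon cross sections backing the pencil-beam Monte Carlo.
#
# Partial mass attenuation coefficients (cm^2/g) are built analytically:
#  * Compton (incoherent): closed-form Klein-Nishina total cross section
#    per electron times the electron density of water (free-electron
#    approximation, good above ~100 keV).
#  * Photoelectric: E^-3 power law anchored at 10 keV (4.94 cm^2/g).
#  * Pair production: standard water anchor values above the 1.022 MeV
#    threshold, interpolated in log energy.
# Coherent (Rayleigh) scattering is excluded by design (<5% above
# 100 keV); the total is the sum of the partials. Tabulated on ~40
# log-spaced energies over 0.01-20 MeV, interpolated log-log.

ELECTRON_REST_MEV <- 0.51099895
# electrons per gram of water: (Z/A)_water * N_A = 0.55509 * 6.02214e23
WATER_ELECTRONS_PER_G <- 3.3428e23
# classical electron radius squared in cm^2 (Thomson scale)
RE2_CM2 <- 7.940787e-26

# Klein-Nishina total cross section per electron (cm^2) at photon energy
# E (MeV); closed form in k = E / (electron rest energy).
kn_total_cs <- function(E_MeV) {
  k <- E_MeV / ELECTRON_REST_MEV
  2 * pi * RE2_CM2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

# pair-production anchors for water (cm^2/g), nuclear + electron field
.pair_anchor_E <- c(1.022, 1.25, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20)
.pair_anchor_mu <- c(0, 3.0e-5, 7.5e-5, 3.9e-4, 1.13e-3, 1.77e-3, 2.35e-3,
                     2.87e-3, 3.76e-3, 4.60e-3, 6.05e-3, 7.70e-3)

#' Water photon cross-section table
#'
#' Mass attenuation coefficients of water (density 1 g/cm3) for the three
#' interaction channels the pencil-beam Monte Carlo samples: Compton
#' (incoherent, Klein-Nishina), photoelectric absorption and pair
#' production. Coherent scatter is excluded; the total is the sum of the
#' partials.
#'
#' @param n_energies Number of log-spaced tabulation energies (default 40)
#'   over 0.01-20 MeV.
#' @return A `cross_section_table`: list with `energy_MeV` and the four
#'   coefficient vectors `mu_total`, `mu_compton`, `mu_photoelectric`,
#'   `mu_pair` (cm2/g), plus `density_g_cm3 = 1`.
#' @export
cross_section_table <- function(n_energies = 40) {
  e <- exp(seq(log(0.01), log(20), length.out = n_energies))
  compton <- kn_total_cs(e) * WATER_ELECTRONS_PER_G
  photo <- 4.94 * (0.01 / e)^3
  pair <- numeric(length(e))
  above <- e > 1.022
  pair[above] <- stats::approx(log(.pair_anchor_E), .pair_anchor_mu,
                               xout = pmin(log(e[above]), log(20)),
                               rule = 2)$y
  structure(
    list(energy_MeV = e,
         mu_compton = compton,
         mu_photoelectric = photo,
         mu_pair = pair,
         mu_total = compton + photo + pair,
         density_g_cm3 = 1.0),
    class = "cross_section_table"
  )
}

# log-log interpolation of a coefficient column at arbitrary energies;
# zero entries (pair production below threshold) handled linearly.
xs_lookup <- function(xs, what, E_MeV) {
  y <- xs[[what]]
  if (any(y == 0)) {
    stats::approx(xs$energy_MeV, y, xout = E_MeV, rule = 2)$y
  } else {
    exp(stats::approx(log(xs$energy_MeV), log(y), xout = log(E_MeV),
                      rule = 2)$y)
  }
}

#' Linear attenuation coefficient of water
#' @param xs A [cross_section_table()].
#' @param E_MeV Photon energies (MeV).
#' @param what Coefficient column (default `"mu_total"`).
#' @return mu in 1/cm (density 1 g/cm3).
#' @export
mu_water <- function(xs, E_MeV, what = "mu_total") {
  xs_lookup(xs, what, E_MeV) * xs$density_g_cm3
}
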