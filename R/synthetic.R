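# Seeded generators for every input the analysis chain consumes. Each
# returns the validated container of the consuming module and carries the
# generating ("true") parameters in attr(x, "truth"), so recovery tests
# never re-enter true values by hand. Default designs mirror the study
# conditions: host grids of 0-12 mM, temperatures 278-318 K in 10 K
# steps, TCSPC histograms of 1024 channels / 100 ns / 10,000 peak counts,
# triplicate MTT plates.

#' Synthetic anisotropy titration
#'
#' Generates an anisotropy titration from true binding parameters with
#' additive Gaussian noise.
#'
#' @param K True association constant (dm3 mol-1 for 1:1, dm6 mol-2
#'   overall for 1:2).
#' @param r_free,r_inf True free and fully-complexed anisotropies.
#' @param stoichiometry `"1:1"` or `"1:2"`.
#' @param host_max Largest host concentration, mol dm-3.
#' @param n_points Number of host concentrations (evenly spaced from 0).
#' @param sigma_r Gaussian noise s.d. on the anisotropy (0 = noiseless).
#' @param temperature,medium,guest_total Passed to [titration()].
#' @param seed Optional integer seed.
#' @return A [titration()] with attribute `truth` (list of the generating
#'   parameters) and, when `sigma_r > 0`, a `sigma_r` column.
#' @export
synth_titration <- function(K, r_free = 0.005, r_inf = 0.047,
                            stoichiometry = c("1:1", "1:2"),
                            host_max = 12e-3, n_points = 12,
                            sigma_r = 0.001, temperature = 298.15,
                            medium = "citrate_pH3.5", guest_total = 1e-6,
                            seed = NULL) {
  stoichiometry <- match.arg(stoichiometry)
  if (!is.null(seed)) set.seed(seed)
  h <- seq(0, host_max, length.out = n_points)
  r <- predict_anisotropy_params(K, r_free, r_inf, h, stoichiometry)
  if (sigma_r > 0) r <- r + rnorm(n_points, 0, sigma_r)
  r <- pmin(pmax(r, -0.199), 0.4)
  tit <- titration(h, r, temperature, medium, guest_total,
                   sigma_r = if (sigma_r > 0) rep(sigma_r, n_points))
  attr(tit, "truth") <- list(K = K, r_free = r_free, r_inf = r_inf,
                             stoichiometry = stoichiometry,
                             sigma_r = sigma_r)
  tit
}

#' Synthetic multi-temperature titration series
#'
#' Derives \eqn{K(T)} from true thermodynamic parameters via the van't
#' Hoff relation and generates one titration per temperature, so the
#' isotherm-fitting and thermodynamics stages can be exercised end to
#' end.
#'
#' @param dH True enthalpy, kJ mol-1.
#' @param dS True entropy, J K-1 mol-1.
#' @param temperatures Temperatures, K (default 278.15-318.15 in 10 K
#'   steps, the 5-45 degree design).
#' @inheritParams synth_titration
#' @return A list of [titration()] objects (one per temperature) with a
#'   `truth` attribute carrying `dH`, `dS` and the exact `K_by_T`.
#' @export
synth_titration_series <- function(dH = -26.2, dS = -56.1,
                                   temperatures = seq(278.15, 318.15, 10),
                                   r_free = 0.005, r_inf = 0.057,
                                   stoichiometry = "1:1",
                                   host_max = 12e-3, n_points = 12,
                                   sigma_r = 0.001, medium = "PBS_pH7.4",
                                   guest_total = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K_by_T <- vant_hoff_K(temperatures, dH, dS)
  tits <- lapply(seq_along(temperatures), function(i)
    synth_titration(K_by_T[i], r_free, r_inf, stoichiometry, host_max,
                    n_points, sigma_r, temperatures[i], medium,
                    guest_total, seed = NULL))
  names(tits) <- sprintf("T%.2fK", temperatures)
  attr(tits, "truth") <- list(dH = dH, dS = dS,
                              temperatures = temperatures, K_by_T = K_by_T,
                              r_free = r_free, r_inf = r_inf,
                              stoichiometry = stoichiometry)
  tits
}

#' Synthetic A_L phase-solubility diagram
#'
#' Linear diagram generated from a true stability constant and intrinsic
#' solubility: slope \eqn{= K S_0 / (1 + K S_0)}, intercept \eqn{S_0}.
#'
#' @param K True stability constant, dm3 mol-1.
#' @param S0 Intrinsic solubility, mol dm-3.
#' @param cd_max Largest cyclodextrin concentration, mol dm-3.
#' @param n_points Number of concentrations (from 0).
#' @param sigma_frac Relative Gaussian noise on drug_total (0 = none).
#' @param temperature,pH Passed to [solubility_diagram()].
#' @param curvature Optional quadratic coefficient (mol-1 dm3 units per
#'   concentration squared) to emulate A_P (> 0) or A_N (< 0) diagrams.
#' @param seed Optional integer seed.
#' @return A [solubility_diagram()] with attribute `truth`.
#' @export
synth_solubility <- function(K = 54, S0 = 7.7e-6, cd_max = 14e-3,
                             n_points = 8, sigma_frac = 0,
                             temperature = 298.15, pH = 7.4,
                             curvature = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cd <- seq(0, cd_max, length.out = n_points)
  slope <- K * S0 / (1 + K * S0)
  y <- S0 + slope * cd + curvature * cd^2
  if (sigma_frac > 0) y <- y * (1 + rnorm(n_points, 0, sigma_frac))
  dg <- solubility_diagram(cd, pmax(y, S0 * 1e-3), temperature, pH)
  attr(dg, "truth") <- list(K = K, S0 = S0, slope = slope,
                            curvature = curvature)
  dg
}

#' Synthetic TCSPC decay histogram
#'
#' Multi-exponential decay sampled on a uniform multichannel-analyzer
#' grid (default 1024 channels over 100 ns), scaled to a target peak
#' count and Poisson-noised. The pulse arrives a few ns into the window
#' so that the pre-peak baseline is visible, as in a real histogram.
#'
#' @param amplitudes Relative pre-exponential factors.
#' @param lifetimes Component lifetimes, ns.
#' @param n_channels,window_ns Analyzer geometry.
#' @param peak_counts Counts in the maximum channel.
#' @param background Mean background counts per channel.
#' @param t0_ns Pulse arrival time within the window.
#' @param noise `"poisson"` or `"none"` (counts rounded to integers).
#' @param seed Optional integer seed.
#' @return A [decay_trace()] with attribute `truth`.
#' @export
synth_decay <- function(amplitudes = 1, lifetimes = 4.2,
                        n_channels = 1024, window_ns = 100,
                        peak_counts = 1e4, background = 10, t0_ns = 2,
                        noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  if (length(amplitudes) != length(lifetimes))
    .stop_domain("`amplitudes` and `lifetimes` must have equal length")
  tt <- seq(0, window_ns, length.out = n_channels + 1)[-(n_channels + 1)]
  shape <- rep(0, n_channels)
  after <- tt >= t0_ns
  for (i in seq_along(amplitudes))
    shape[after] <- shape[after] +
      amplitudes[i] * exp(-(tt[after] - t0_ns) / lifetimes[i])
  mu <- background + shape / max(shape) * (peak_counts - background)
  counts <- if (noise == "poisson") rpois(n_channels, mu) else round(mu)
  tr <- decay_trace(tt, counts)
  attr(tr, "truth") <- list(amplitudes = amplitudes, lifetimes = lifetimes,
                            peak_counts = peak_counts,
                            background = background, t0_ns = t0_ns)
  tr
}

#' Synthetic Stern-Volmer quenching series
#'
#' Dynamic quenching with Stern-Volmer constant `K_SV`, optionally with
#' an upward-curving static contribution to the intensity ratio at high
#' quencher concentration:
#' \deqn{I_0/I = 1 + K_{SV}[Q] + c\,([Q] - Q_{on})_+^2,}
#' while \eqn{\tau_0/\tau = 1 + K_{SV}[Q]} stays linear (static
#' contributions do not shorten the lifetime). The deviation is modelled
#' as quadratic beyond an onset concentration because Stern-Volmer plots
#' of this kind are linear in the lowest-concentration region, with
#' static/sphere-of-action effects emerging only as the quencher becomes
#' concentrated — the regime in which analysing the first portion of the
#' curve recovers the dynamic constant.
#'
#' @param K_SV Dynamic Stern-Volmer constant, dm3 mol-1.
#' @param tau0 Unquenched lifetime, ns.
#' @param curvature Static-term curvature \eqn{c}, dm6 mol-2 (0 = purely
#'   dynamic).
#' @param q_onset Concentration above which the static deviation grows,
#'   mol dm-3.
#' @param q_max Largest quencher concentration, mol dm-3.
#' @param n_points Number of concentrations (from 0).
#' @param sigma Gaussian noise s.d. on the ratios.
#' @param seed Optional integer seed.
#' @return A [quench_series()] with both ratio columns and attribute
#'   `truth`.
#' @export
synth_quench <- function(K_SV = 120, tau0 = 4.2, curvature = 0,
                         q_onset = 8e-3, q_max = 0.02, n_points = 12,
                         sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- seq(0, q_max, length.out = n_points)
  dyn <- 1 + K_SV * q
  int <- dyn + curvature * pmax(q - q_onset, 0)^2
  tau <- dyn
  if (sigma > 0) {
    int <- int + rnorm(n_points, 0, sigma)
    tau <- tau + rnorm(n_points, 0, sigma)
    int[q == 0] <- 1
    tau[q == 0] <- 1
  }
  s <- quench_series(q, intensity_ratio = int, lifetime_ratio = tau,
                     tau0 = tau0)
  attr(s, "truth") <- list(K_SV = K_SV, curvature = curvature,
                           q_onset = q_onset, tau0 = tau0,
                           k_q = K_SV / (tau0 * 1e-9))
  s
}

#' Synthetic first-order release trace
#'
#' \eqn{I_t = I_\infty - (I_\infty - I_0)e^{-kt}} sampled on a uniform
#' time grid, with optional Gaussian noise; `stable = TRUE` produces a
#' constant trace (the physiological-pH behaviour).
#'
#' @param k Rate constant, min-1.
#' @param plateau_percent Plateau intensity rise as % of the initial
#'   intensity.
#' @param I0 Initial intensity (arbitrary units).
#' @param t_max Last time point, min.
#' @param n_points Number of time points from 0.
#' @param sigma_frac Noise s.d. as a fraction of `I0`.
#' @param pH Medium pH label.
#' @param stable Generate a no-release (constant) trace?
#' @param seed Optional integer seed.
#' @return A [release_trace()] with attribute `truth`.
#' @export
synth_release <- function(k = 0.0103, plateau_percent = 5.5, I0 = 100,
                          t_max = 600, n_points = 30, sigma_frac = 0,
                          pH = 3.5, stable = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, t_max, length.out = n_points)
  I_inf <- I0 * (1 + plateau_percent / 100)
  I <- if (stable) rep(I0, n_points)
       else I_inf - (I_inf - I0) * exp(-k * tt)
  if (sigma_frac > 0) I <- I + rnorm(n_points, 0, sigma_frac * I0)
  tr <- release_trace(tt, pmax(I, I0 * 1e-3), pH)
  attr(tr, "truth") <- list(k = k, tau_half = log(2) / k,
                            plateau_percent = plateau_percent, I0 = I0,
                            I_inf = I_inf, stable = stable)
  tr
}

#' Synthetic MTT dose-response plate
#'
#' Triplicate survival percentages around a 4PL mean with Gaussian
#' replicate noise.
#'
#' @param ic50 True IC50, mol dm-3.
#' @param hill Hill slope.
#' @param bottom Lower survival asymptote, %.
#' @param doses Dose grid, mol dm-3, including 0 (default: 0 plus a
#'   geometric ladder up to 150 nM, the study's dose range).
#' @param n_replicates Replicates per dose (default 3).
#' @param sigma Gaussian noise s.d. in survival percentage points.
#' @param cell_line,treatment,exposure_h Labels for [dose_response()].
#' @param seed Optional integer seed.
#' @return A [dose_response()] with attribute `truth`.
#' @export
synth_mtt <- function(ic50 = 17e-9, hill = 1.5, bottom = 5,
                      doses = c(0, exp(seq(log(2e-9), log(150e-9),
                                           length.out = 7))),
                      n_replicates = 3, sigma = 5,
                      cell_line = "BT-474", treatment = "free_drug",
                      exposure_h = 48, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- .fourpl(doses, ic50, hill, bottom)
  surv <- sapply(seq_len(n_replicates), function(j) {
    s <- mu + if (sigma > 0) rnorm(length(doses), 0, sigma) else 0
    pmax(s, 0)
  })
  dr <- dose_response(doses, surv, cell_line, treatment, exposure_h)
  attr(dr, "truth") <- list(ic50 = ic50, hill = hill, bottom = bottom,
                            sigma = sigma)
  dr
}

#' Synthetic emission spectrum
#'
#' Single Gaussian emission band on a nanometre grid, used to emulate the
#' drug's lactone (peak near 431 nm) and carboxylate (peak near 445 nm)
#' emission bands.
#'
#' @param center_nm Band maximum, nm.
#' @param width_nm Gaussian standard deviation, nm.
#' @param wavelengths Wavelength grid, nm.
#' @param intensity Peak intensity.
#' @param sigma_frac Relative Gaussian noise (0 = none).
#' @param seed Optional integer seed.
#' @return Data frame with `wavelength` and `intensity`.
#' @export
synth_emission_spectrum <- function(center_nm = 431, width_nm = 35,
                                    wavelengths = seq(380, 625, by = 1),
                                    intensity = 1, sigma_frac = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- intensity * exp(-0.5 * ((wavelengths - center_nm) / width_nm)^2)
  if (sigma_frac > 0)
    I <- I + rnorm(length(I), 0, sigma_frac * intensity)
  data.frame(wavelength = wavelengths, intensity = I)
}
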