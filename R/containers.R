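#' Fluorescence anisotropy titration
#'
#' Bundles one anisotropy-versus-host-concentration series recorded at a
#' fixed temperature in a fixed medium. The host is the cyclodextrin; the
#' guest (the drug, held at constant total concentration) is the
#' fluorophore whose anisotropy \eqn{r} rises as it is complexed.
#'
#' @param host_conc Host (cyclodextrin) concentrations, mol dm-3. Must be
#'   non-negative, strictly increasing and include 0.
#' @param r_obs Observed steady-state anisotropies, dimensionless, one per
#'   host concentration. Physically constrained to (-0.2, 0.4].
#' @param temperature Temperature in kelvin.
#' @param medium Medium label; canonical values are `"citrate_pH3.5"`,
#'   `"PBS_pH7.4"` and `"water_pH7.4"`.
#' @param guest_total Total guest (drug) concentration, mol dm-3.
#' @param sigma_r Optional per-point anisotropy standard deviations used as
#'   weights by [fit_binding_isotherm()].
#'
#' @return A data frame of class `"titration"` with columns `host_conc`,
#'   `r_obs` (and `sigma_r` if given) and attributes `temperature`,
#'   `medium`, `guest_total`.
#' @seealso [fit_binding_isotherm()], [select_stoichiometry()],
#'   [read_titration()]
#' @export
#' @examples
#' h <- seq(0, 12e-3, length.out = 12)
#' r <- predict_anisotropy_params(200, 0.005, 0.047, h)
#' titration(h, r, temperature = 298.15, medium = "citrate_pH3.5",
#'           guest_total = 1e-6)
titration <- function(host_conc, r_obs, temperature, medium = "PBS_pH7.4",
                      guest_total = 1e-6, sigma_r = NULL) {
  .check_numeric_vec(host_conc, "host_conc", 2L)
  .check_numeric_vec(r_obs, "r_obs", 2L)
  if (length(host_conc) != length(r_obs))
    .stop_domain("`host_conc` and `r_obs` must have equal length")
  if (any(host_conc < 0))
    .stop_domain("`host_conc` must be non-negative")
  if (is.unsorted(host_conc, strictly = TRUE))
    .stop_domain("`host_conc` must be strictly increasing")
  if (host_conc[1] != 0)
    .stop_domain("`host_conc` must include a zero-host point")
  if (any(r_obs <= -0.2 | r_obs > 0.4))
    .stop_domain("`r_obs` outside the physical range (-0.2, 0.4]")
  .check_positive(temperature, "temperature")
  .check_positive(guest_total, "guest_total")
  out <- data.frame(host_conc = host_conc, r_obs = r_obs)
  if (!is.null(sigma_r)) {
    .check_numeric_vec(sigma_r, "sigma_r", length(host_conc))
    if (any(sigma_r <= 0)) .stop_domain("`sigma_r` must be positive")
    out$sigma_r <- sigma_r
  }
  structure(out, temperature = temperature, medium = as.character(medium),
            guest_total = guest_total,
            class = c("titration", "data.frame"))
}

#' Time-correlated single photon counting decay trace
#'
#' A photon-count histogram as produced by a TCSPC multichannel analyzer
#' (default instrument geometry: 1024 channels spanning a 100 ns window).
#'
#' @param channel_time Channel times in ns; strictly increasing, uniformly
#'   spaced.
#' @param counts Non-negative integer photon counts per channel.
#' @param irf Optional instrument response function counts, same length.
#' @return A data frame of class `"decay_trace"`.
#' @seealso [fit_decay()], [read_decay()]
#' @export
decay_trace <- function(channel_time, counts, irf = NULL) {
  .check_numeric_vec(channel_time, "channel_time", 2L)
  .check_numeric_vec(counts, "counts", 2L)
  if (length(channel_time) != length(counts))
    .stop_domain("`channel_time` and `counts` must have equal length")
  if (is.unsorted(channel_time, strictly = TRUE))
    .stop_domain("`channel_time` must be strictly increasing")
  dt <- diff(channel_time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    .stop_domain("`channel_time` must be uniformly spaced")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    .stop_domain("`counts` must be non-negative integers")
  out <- data.frame(channel_time = channel_time, counts = round(counts))
  if (!is.null(irf)) {
    .check_numeric_vec(irf, "irf", length(counts))
    if (any(irf < 0)) .stop_domain("`irf` must be non-negative")
    out$irf <- irf
  }
  structure(out, class = c("decay_trace", "data.frame"))
}

#' Stern-Volmer quenching series
#'
#' Intensity and/or lifetime ratios versus quencher concentration, for
#' dynamic-quenching analysis via [stern_volmer_fit()].
#'
#' @param quencher_conc Quencher concentrations, mol dm-3; must include 0.
#' @param intensity_ratio Optional \eqn{I_0/I} series.
#' @param lifetime_ratio Optional \eqn{\tau_0/\tau} series.
#' @param tau0 Unquenched fluorescence lifetime, ns.
#' @param ratio_tol Tolerance for the "ratio at zero quencher equals 1" and
#'   "ratios >= 1" checks (default 0.05, generous to instrument noise).
#' @return A data frame of class `"quench_series"` with attribute `tau0`.
#' @export
quench_series <- function(quencher_conc, intensity_ratio = NULL,
                          lifetime_ratio = NULL, tau0, ratio_tol = 0.05) {
  .check_numeric_vec(quencher_conc, "quencher_conc", 2L)
  if (any(quencher_conc < 0)) .stop_domain("`quencher_conc` must be non-negative")
  if (!any(quencher_conc == 0))
    .stop_domain("`quencher_conc` must include a zero-quencher point")
  .check_positive(tau0, "tau0")
  if (is.null(intensity_ratio) && is.null(lifetime_ratio))
    .stop_domain("at least one of `intensity_ratio`, `lifetime_ratio` is required")
  out <- data.frame(quencher_conc = quencher_conc)
  for (nm in c("intensity_ratio", "lifetime_ratio")) {
    v <- get(nm)
    if (is.null(v)) next
    .check_numeric_vec(v, nm, length(quencher_conc))
    if (any(v < 1 - ratio_tol))
      .stop_domain(sprintf("`%s` has values below 1 beyond tolerance", nm))
    at0 <- v[quencher_conc == 0]
    if (any(abs(at0 - 1) > ratio_tol))
      .stop_domain(sprintf("`%s` at zero quencher must be 1 within tolerance", nm))
    out[[nm]] <- v
  }
  structure(out, tau0 = tau0, class = c("quench_series", "data.frame"))
}

#' Phase-solubility diagram
#'
#' Total dissolved drug versus cyclodextrin concentration, the input for
#' Higuchi-Connors classification and stability-constant estimation.
#'
#' @param cd_conc Cyclodextrin concentrations, mol dm-3; must include 0.
#' @param drug_total Total dissolved drug, mol dm-3, all positive.
#' @param temperature Temperature, K.
#' @param pH Solution pH.
#' @return A data frame of class `"solubility_diagram"`. The intrinsic
#'   solubility `S0` (diagram value at zero cyclodextrin) is stored as an
#'   attribute and taken from the fitted intercept by [classify_diagram()].
#' @export
solubility_diagram <- function(cd_conc, drug_total, temperature = 298.15,
                               pH = 7.4) {
  .check_numeric_vec(cd_conc, "cd_conc", 2L)
  .check_numeric_vec(drug_total, "drug_total", 2L)
  if (length(cd_conc) != length(drug_total))
    .stop_domain("`cd_conc` and `drug_total` must have equal length")
  if (any(cd_conc < 0)) .stop_domain("`cd_conc` must be non-negative")
  if (!any(cd_conc == 0)) .stop_domain("`cd_conc` must include 0")
  if (any(drug_total <= 0)) .stop_domain("`drug_total` must be positive")
  structure(data.frame(cd_conc = cd_conc, drug_total = drug_total),
            temperature = temperature, pH = pH,
            S0 = drug_total[which(cd_conc == 0)[1]],
            class = c("solubility_diagram", "data.frame"))
}

#' Release time course
#'
#' Fluorescence intensity versus time for drug release from liposomes.
#'
#' @param time Times in minutes, strictly increasing, starting at 0.
#' @param intensity Fluorescence intensities (arbitrary units), positive.
#' @param pH Medium pH (7.4 plasma-mimicking, 3.5 lysosomal-mimicking).
#' @return A data frame of class `"release_trace"`.
#' @export
release_trace <- function(time, intensity, pH = 3.5) {
  .check_numeric_vec(time, "time", 2L)
  .check_numeric_vec(intensity, "intensity", 2L)
  if (length(time) != length(intensity))
    .stop_domain("`time` and `intensity` must have equal length")
  if (time[1] != 0) .stop_domain("`time` must start at 0")
  if (is.unsorted(time, strictly = TRUE))
    .stop_domain("`time` must be strictly increasing")
  if (any(intensity <= 0)) .stop_domain("`intensity` must be positive")
  structure(data.frame(time = time, intensity = intensity), pH = pH,
            class = c("release_trace", "data.frame"))
}

#' Dose-response data from an MTT plate
#'
#' Percentage cell survival versus drug dose with replicate columns
#' (triplicates in the standard design).
#'
#' @param dose Doses in mol dm-3, non-negative, including the 0 control.
#' @param survival Matrix (or data frame) of survival percentages, one row
#'   per dose, one column per replicate. The control row defines 100%.
#' @param cell_line,treatment Labels.
#' @param exposure_h Exposure time, hours.
#' @return An object of class `"dose_response"`.
#' @seealso [fit_ic50()], [survival_percent()]
#' @export
dose_response <- function(dose, survival, cell_line = "unknown",
                          treatment = "unknown", exposure_h = 48) {
  .check_numeric_vec(dose, "dose", 2L)
  if (any(dose < 0)) .stop_domain("`dose` must be non-negative")
  if (!any(dose == 0)) .stop_domain("`dose` must include a 0 control")
  survival <- as.matrix(survival)
  if (nrow(survival) != length(dose))
    .stop_domain("`survival` must have one row per dose")
  if (any(!is.finite(survival)) || any(survival < 0))
    .stop_domain("`survival` must be finite and non-negative")
  structure(list(dose = dose, survival = survival,
                 cell_line = cell_line, treatment = treatment,
                 exposure_h = exposure_h),
            class = "dose_response")
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("Anisotropy titration: %d points, T = %.2f K, medium = %s\n",
              nrow(x), attr(x, "temperature"), attr(x, "medium")))
  cat(sprintf("  host 0 to %.3g M, guest total %.3g M\n",
              max(x$host_conc), attr(x, "guest_total")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response: %s / %s, %d doses x %d replicates, %g h\n",
              x$cell_line, x$treatment, length(x$dose), ncol(x$survival),
              x$exposure_h))
  invisible(x)
}
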