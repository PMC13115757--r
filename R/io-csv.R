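# Plain-CSV interchange formats. Every file is an ordinary CSV preceded
# by '# key: value' metadata lines; all concentrations are mol dm-3.

.write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], scientific = FALSE,
                                             trim = TRUE)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_meta <- function(path) {
  if (!file.exists(path)) .stop_domain("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                 stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

#' Read and write titration CSV files
#'
#' Schema: columns `host_conc_M`, `r_obs` (optional `sigma_r`), with
#' `# temperature_K`, `# medium`, `# guest_total_M` metadata lines.
#'
#' @param path File path.
#' @return `read_titration()` returns a [titration()];
#'   `write_titration()` returns `path` invisibly.
#' @export
read_titration <- function(path) {
  x <- .read_csv_meta(path)
  need <- c("host_conc_M", "r_obs")
  if (!all(need %in% names(x$data)))
    .stop_domain(path, ": titration CSV needs columns ",
                 paste(need, collapse = ", "))
  titration(x$data$host_conc_M, x$data$r_obs,
            temperature = x$meta$temperature_K %||% 298.15,
            medium = x$meta$medium %||% "unknown",
            guest_total = x$meta$guest_total_M %||% 1e-6,
            sigma_r = x$data$sigma_r)
}

#' @param tit A [titration()].
#' @rdname read_titration
#' @export
write_titration <- function(tit, path) {
  stopifnot(inherits(tit, "titration"))
  df <- data.frame(host_conc_M = tit$host_conc, r_obs = tit$r_obs)
  if (!is.null(tit$sigma_r)) df$sigma_r <- tit$sigma_r
  .write_csv_meta(df, path, list(temperature_K = attr(tit, "temperature"),
                                 medium = attr(tit, "medium"),
                                 guest_total_M = attr(tit, "guest_total")))
}

#' Read and write TCSPC decay CSV files
#'
#' Schema: columns `time_ns`, `counts` (optional `irf_counts`).
#'
#' @param path File path.
#' @return `read_decay()` returns a [decay_trace()].
#' @export
read_decay <- function(path) {
  x <- .read_csv_meta(path)
  need <- c("time_ns", "counts")
  if (!all(need %in% names(x$data)))
    .stop_domain(path, ": decay CSV needs columns ",
                 paste(need, collapse = ", "))
  decay_trace(x$data$time_ns, x$data$counts, irf = x$data$irf_counts)
}

#' @param trace A [decay_trace()].
#' @rdname read_decay
#' @export
write_decay <- function(trace, path) {
  stopifnot(inherits(trace, "decay_trace"))
  df <- data.frame(time_ns = trace$channel_time, counts = trace$counts)
  if (!is.null(trace$irf)) df$irf_counts <- trace$irf
  .write_csv_meta(df, path)
}

#' Read and write quenching-series CSV files
#'
#' Schema: columns `q_conc_M`, `i0_over_i` (optional `tau0_over_tau`),
#' with a `# tau0_ns` metadata line.
#'
#' @param path File path.
#' @return `read_quench()` returns a [quench_series()].
#' @export
read_quench <- function(path) {
  x <- .read_csv_meta(path)
  if (!"q_conc_M" %in% names(x$data))
    .stop_domain(path, ": quench CSV needs column q_conc_M")
  if (is.null(x$meta$tau0_ns))
    .stop_domain(path, ": quench CSV needs '# tau0_ns' metadata")
  quench_series(x$data$q_conc_M,
                intensity_ratio = x$data$i0_over_i,
                lifetime_ratio = x$data$tau0_over_tau,
                tau0 = x$meta$tau0_ns)
}

#' @param series A [quench_series()].
#' @rdname read_quench
#' @export
write_quench <- function(series, path) {
  stopifnot(inherits(series, "quench_series"))
  df <- data.frame(q_conc_M = series$quencher_conc)
  if (!is.null(series$intensity_ratio)) df$i0_over_i <- series$intensity_ratio
  if (!is.null(series$lifetime_ratio))
    df$tau0_over_tau <- series$lifetime_ratio
  .write_csv_meta(df, path, list(tau0_ns = attr(series, "tau0")))
}

#' Read and write phase-solubility CSV files
#'
#' Schema: columns `cd_conc_M`, `drug_total_M`, with `# temperature_K`,
#' `# pH` (optional `# cosolvent_fraction`) metadata lines.
#'
#' @param path File path.
#' @return `read_solubility()` returns a [solubility_diagram()].
#' @export
read_solubility <- function(path) {
  x <- .read_csv_meta(path)
  need <- c("cd_conc_M", "drug_total_M")
  if (!all(need %in% names(x$data)))
    .stop_domain(path, ": solubility CSV needs columns ",
                 paste(need, collapse = ", "))
  solubility_diagram(x$data$cd_conc_M, x$data$drug_total_M,
                     temperature = x$meta$temperature_K %||% 298.15,
                     pH = x$meta$pH %||% NA_real_)
}

#' @param diagram A [solubility_diagram()].
#' @rdname read_solubility
#' @export
write_solubility <- function(diagram, path) {
  stopifnot(inherits(diagram, "solubility_diagram"))
  .write_csv_meta(data.frame(cd_conc_M = diagram$cd_conc,
                             drug_total_M = diagram$drug_total),
                  path, list(temperature_K = attr(diagram, "temperature"),
                             pH = attr(diagram, "pH")))
}

#' Read and write release-trace CSV files
#'
#' Schema: columns `time_min`, `intensity`, with a `# pH` metadata line.
#'
#' @param path File path.
#' @return `read_release()` returns a [release_trace()].
#' @export
read_release <- function(path) {
  x <- .read_csv_meta(path)
  need <- c("time_min", "intensity")
  if (!all(need %in% names(x$data)))
    .stop_domain(path, ": release CSV needs columns ",
                 paste(need, collapse = ", "))
  release_trace(x$data$time_min, x$data$intensity,
                pH = x$meta$pH %||% NA_real_)
}

#' @param trace A [release_trace()].
#' @rdname read_release
#' @export
write_release <- function(trace, path) {
  stopifnot(inherits(trace, "release_trace"))
  .write_csv_meta(data.frame(time_min = trace$time,
                             intensity = trace$intensity),
                  path, list(pH = attr(trace, "pH")))
}

#' Read and write MTT dose-response CSV files
#'
#' Schema: column `dose_M` plus one `rep<i>_survival_pct` column per
#' replicate, with `# cell_line`, `# treatment`, `# exposure_h` metadata.
#'
#' @param path File path.
#' @return `read_mtt()` returns a [dose_response()].
#' @export
read_mtt <- function(path) {
  x <- .read_csv_meta(path)
  repcols <- grep("^rep[0-9]+_survival_pct$", names(x$data), value = TRUE)
  if (!"dose_M" %in% names(x$data) || length(repcols) == 0)
    .stop_domain(path, ": MTT CSV needs dose_M and rep<i>_survival_pct ",
                 "columns")
  dose_response(x$data$dose_M, as.matrix(x$data[repcols]),
                cell_line = x$meta$cell_line %||% "unknown",
                treatment = x$meta$treatment %||% "unknown",
                exposure_h = x$meta$exposure_h %||% NA_real_)
}

#' @param dr A [dose_response()].
#' @rdname read_mtt
#' @export
write_mtt <- function(dr, path) {
  stopifnot(inherits(dr, "dose_response"))
  df <- data.frame(dose_M = dr$dose)
  for (j in seq_len(ncol(dr$survival)))
    df[[sprintf("rep%d_survival_pct", j)]] <- dr$survival[, j]
  .write_csv_meta(df, path, list(cell_line = dr$cell_line,
                                 treatment = dr$treatment,
                                 exposure_h = dr$exposure_h))
}

#' Read a temperature/constant table for van't Hoff analysis
#'
#' Schema: columns `temperature_K`, `K_assoc` (optional `K_se`).
#'
#' @param path File path.
#' @return A data frame with `temperature_K`, `K_assoc` and `K_se` (if
#'   present).
#' @export
read_k_table <- function(path) {
  x <- .read_csv_meta(path)
  need <- c("temperature_K", "K_assoc")
  if (!all(need %in% names(x$data)))
    .stop_domain(path, ": K table needs columns ",
                 paste(need, collapse = ", "))
  x$data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
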