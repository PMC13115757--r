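#' Validate measurement files against their schemas
#'
#' Infers each file's schema from its column names, runs it through the
#' corresponding reader and container validation, and tabulates the
#' outcome. Unreadable or invalid files produce `error` rows; processing
#' continues across files. Constructor warnings are reported as
#' `warning` rows.
#'
#' @param paths Character vector of CSV paths.
#' @return A data frame with columns `file`, `schema`, `status`
#'   (`"ok"`, `"warning"` or `"error"`) and `message`.
#' @export
validate_inputs <- function(paths) {
  one <- function(p) {
    if (!file.exists(p))
      return(data.frame(file = p, schema = "unknown", status = "error",
                        message = "file not found"))
    schema <- tryCatch({
      cols <- names(.read_csv_meta(p)$data)
      if (all(c("host_conc_M", "r_obs") %in% cols)) "titration"
      else if (all(c("time_ns", "counts") %in% cols)) "decay"
      else if ("q_conc_M" %in% cols) "quench"
      else if (all(c("cd_conc_M", "drug_total_M") %in% cols)) "solubility"
      else if (all(c("time_min", "intensity") %in% cols)) "release"
      else if ("dose_M" %in% cols &&
               any(grepl("^rep[0-9]+_survival_pct$", cols))) "mtt"
      else if (all(c("temperature_K", "K_assoc") %in% cols)) "k_table"
      else "unknown"
    }, error = function(e) "unreadable")
    if (schema %in% c("unknown", "unreadable"))
      return(data.frame(file = p, schema = schema, status = "error",
                        message = "no known schema matches the columns"))
    reader <- switch(schema, titration = read_titration,
                     decay = read_decay, quench = read_quench,
                     solubility = read_solubility, release = read_release,
                     mtt = read_mtt, k_table = read_k_table)
    msg <- "passes schema and invariant checks"
    status <- "ok"
    tryCatch(withCallingHandlers(reader(p), warning = function(w) {
      status <<- "warning"; msg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }), error = function(e) {
      status <<- "error"; msg <<- conditionMessage(e)
    })
    data.frame(file = p, schema = schema, status = status, message = msg)
  }
  do.call(rbind, lapply(paths, one))
}

#' Run the full analysis pipeline
#'
#' Executes the analysis stages in dependency order — isotherm fits then
#' van't Hoff across temperatures; phase-solubility classification and
#' stability constants; quenching, decay, release kinetics; IC50 fits
#' then replicate-level comparisons — on the files named in the
#' configuration, and/or on synthetic scenarios generated on the fly.
#' Writes `results.json` (machine-readable) and `report.txt` (human-
#' readable) into `out_dir`; both are byte-identical across reruns with
#' identical inputs and seed.
#'
#' The configuration is a list (or YAML/JSON file) with optional
#' elements:
#' * `seed` — integer used for synthetic generation;
#' * `synthetic` — list of [generate()] configs; generated files are
#'   routed to their consuming stage automatically;
#' * `stages` — named list (`isotherm`, `solubility`, `quench`, `decay`,
#'   `release`, `mtt`), each with a `files` vector and stage options
#'   (`stoichiometry` = `"auto"`/`"1:1"`/`"1:2"` for `isotherm`,
#'   `n_components` for `decay`).
#'
#' @param config Configuration list or path to a YAML/JSON file.
#' @param out_dir Output directory (created if missing).
#' @return An object of class `"run_report"` (invisibly): list with
#'   `results` (per-stage parameter tables), `provenance` (input file
#'   MD5 hashes, seed, package version), `warnings` and `output_files`.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1)
    config <- .read_config(config)
  if (!is.list(config) || (is.null(config$stages) && is.null(config$synthetic)))
    .stop_domain("empty configuration: provide `stages` and/or `synthetic`")
  seed <- as.integer(config$seed %||% 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- config$stages %||% list()
  warnings_log <- character()
  log_warn <- function(stage, w) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, w))
  }
  quietly <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      log_warn(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      log_warn(stage, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  # synthetic scenarios feed their consuming stage
  stage_of <- c(cmbcd_1to1 = "isotherm", ambcd_1to2 = "isotherm",
                solubility = "solubility", decay = "decay",
                quench = "quench", release = "release", mtt = "mtt")
  data_dir <- file.path(out_dir, "data")
  for (i in seq_along(config$synthetic)) {
    sc <- config$synthetic[[i]]
    sc$seed <- sc$seed %||% (seed + i - 1L)
    gen <- generate(sc, data_dir)
    st <- stage_of[[sc$scenario]]
    stages[[st]]$files <- c(stages[[st]]$files, gen$files)
  }

  all_files <- unlist(lapply(stages, `[[`, "files"), use.names = FALSE)
  missing <- all_files[!file.exists(all_files)]
  if (length(missing))
    .stop_domain("input file(s) not found: ", paste(missing, collapse = ", "))

  results <- list()

  if (!is.null(stages$isotherm)) {
    opt <- stages$isotherm
    stoich <- opt$stoichiometry %||% "auto"
    rows <- lapply(opt$files, function(f) {
      tit <- read_titration(f)
      fit <- quietly("isotherm", {
        if (stoich == "auto") {
          sel <- select_stoichiometry(tit)
          if (sel$selected == "1:1") sel$fit_1to1 else sel$fit_1to2
        } else fit_binding_isotherm(tit, stoich)
      })
      data.frame(file = basename(f), medium = fit$medium,
                 temperature_K = fit$temperature,
                 stoichiometry = fit$stoichiometry, K = fit$K,
                 K_se = fit$std_errors[["K"]], K_sqrt = fit$K_sqrt,
                 r_free = fit$r_free, r_inf = fit$r_inf,
                 residual_ss = fit$residual_ss,
                 flags = paste(fit$warnings, collapse = ";"))
    })
    iso <- do.call(rbind, rows)
    results$isotherm <- iso
    # van't Hoff per medium/stoichiometry group with >= 2 temperatures
    grp <- split(iso, list(iso$medium, iso$stoichiometry), drop = TRUE)
    vh <- lapply(grp, function(g) {
      if (length(unique(g$temperature_K)) < 2) return(NULL)
      fit <- quietly("vant_hoff", vant_hoff_fit(g$temperature_K, g$K))
      data.frame(medium = g$medium[1], stoichiometry = g$stoichiometry[1],
                 dH_kJ_mol = fit$dH, dH_se = fit$std_errors[["dH"]],
                 dS_J_K_mol = fit$dS, dS_se = fit$std_errors[["dS"]],
                 dG_298K_kJ_mol = dG_at(fit, 298.15),
                 K_298K = predict_K(fit, 298.15),
                 n_temperatures = fit$n_temperatures,
                 r_squared = fit$r_squared)
    })
    vh <- do.call(rbind, Filter(Negate(is.null), vh))
    if (!is.null(vh)) { rownames(vh) <- NULL; results$vant_hoff <- vh }
  }

  if (!is.null(stages$solubility)) {
    rows <- lapply(stages$solubility$files, function(f) {
      dg <- read_solubility(f)
      cl <- quietly("solubility", classify_diagram(dg))
      fold <- max(dg$drug_total) / cl$intercept
      data.frame(file = basename(f), type = cl$type, slope = cl$slope,
                 S0 = cl$intercept, r_squared = cl$r_squared,
                 K = cl$K, fold_enhancement = fold)
    })
    results$solubility <- do.call(rbind, rows)
  }

  if (!is.null(stages$quench)) {
    rows <- lapply(stages$quench$files, function(f) {
      qs <- read_quench(f)
      sv <- quietly("quench", stern_volmer_fit(qs, "intensity"))
      data.frame(file = basename(f), K_SV = sv$K_SV, k_q = sv$k_q,
                 n_linear = sv$n_linear, n_points = nrow(qs),
                 r_squared = sv$r_squared,
                 flags = paste(sv$warnings, collapse = ";"))
    })
    results$quench <- do.call(rbind, rows)
  }

  if (!is.null(stages$decay)) {
    nc <- stages$decay$n_components %||% 1
    rows <- lapply(stages$decay$files, function(f) {
      tr <- read_decay(f)
      fit <- quietly("decay", fit_decay(tr, nc))
      data.frame(file = basename(f), n_components = fit$n_components,
                 mean_lifetime_ns = fit$mean_lifetime,
                 tau1_ns = fit$lifetimes[1],
                 chisq_reduced = fit$chisq_reduced)
    })
    results$decay <- do.call(rbind, rows)
  }

  if (!is.null(stages$release)) {
    rows <- lapply(stages$release$files, function(f) {
      tr <- read_release(f)
      fit <- quietly("release", fit_release_first_order(tr))
      data.frame(file = basename(f), stable = fit$stable,
                 k_per_min = fit$k, tau_half_min = fit$tau_half,
                 plateau_percent = fit$plateau_percent,
                 r_squared = fit$r_squared)
    })
    results$release <- do.call(rbind, rows)
  }

  if (!is.null(stages$mtt)) {
    fits <- lapply(stages$mtt$files, function(f) {
      dr <- read_mtt(f)
      quietly("mtt", fit_ic50(dr, per_replicate = TRUE))
    })
    rows <- mapply(function(f, fit) {
      data.frame(file = basename(f), cell_line = fit$data$cell_line,
                 treatment = fit$data$treatment, ic50_M = fit$ic50,
                 ic50_se = fit$ic50_se, hill = fit$hill,
                 bottom = fit$bottom)
    }, stages$mtt$files, fits, SIMPLIFY = FALSE)
    results$ic50 <- do.call(rbind, rows)
    rownames(results$ic50) <- NULL
    if (length(fits) >= 2) {
      pairs <- utils::combn(length(fits), 2)
      cmp <- apply(pairs, 2, function(ij) {
        cc <- quietly("mtt",
                      compare_ic50(fits[[ij[1]]], fits[[ij[2]]]))
        data.frame(group_a = basename(stages$mtt$files[ij[1]]),
                   group_b = basename(stages$mtt$files[ij[2]]),
                   t_statistic = cc$t_statistic, p_value = cc$p_value,
                   significant = cc$significant)
      })
      results$ic50_comparisons <- do.call(rbind, cmp)
    }
  }

  if (length(results) == 0)
    .stop_domain("configuration produced no runnable stage")

  provenance <- list(
    seed = seed,
    package_version = as.character(packageVersion("cyclofit")),
    inputs = as.list(tools::md5sum(sort(unique(all_files)))))

  report <- structure(list(results = results, provenance = provenance,
                           warnings = warnings_log), class = "run_report")

  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(list(results = results, provenance = provenance,
                            warnings = warnings_log),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  txt_path <- file.path(out_dir, "report.txt")
  writeLines(utils::capture.output(print(report)), txt_path)
  report$output_files <- c(json = json_path, text = txt_path)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("cyclofit pipeline report (package version",
      x$provenance$package_version, ", seed", x$provenance$seed, ")\n")
  for (nm in names(x$results)) {
    cat("\n==", nm, "==\n")
    df <- x$results[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, 6)
    print(df, row.names = FALSE)
  }
  cat("\n== provenance ==\n")
  for (f in names(x$provenance$inputs))
    cat(sprintf("  %s  %s\n", x$provenance$inputs[[f]], f))
  if (length(x$warnings)) {
    cat("\n== warnings ==\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
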