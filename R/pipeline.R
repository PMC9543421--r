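cohort_required_cols <- c("id", "age_years", "tilt_deg", "gsu_overall",
                          "gsu_zone_0_2", "gsu_zone_2_6", "gsu_zone_6_10",
                          "gsu_zone_10_12", "gsu_layer_anterior",
                          "gsu_layer_central", "gsu_layer_posterior")

#' Write a cohort table to CSV
#'
#' @param records cohort data.frame (see [simulate_cohort()]); extra columns
#'   are written through unchanged.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(cohort_required_cols, names(records))
  if (length(missing))
    stop("cohort table is missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the required columns and that every numeric column parses;
#' unknown extra columns are preserved and passed through.
#'
#' @param path CSV file in the dialect of [write_cohort_csv()].
#' @return cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cohort_required_cols, names(df))
  if (length(missing))
    stop("cohort CSV '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in setdiff(cohort_required_cols, "id")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad))
        stop("cohort CSV: non-numeric cell in column '", col, "', row ", bad[1])
      df[[col]] <- parsed
    }
    if (anyNA(df[[col]]))
      stop("cohort CSV: missing value in column '", col, "', row ",
           which(is.na(df[[col]]))[1])
  }
  df
}

#' Study configuration
#'
#' All seeds are explicit so every number in the resulting report is
#' reproducible from the configuration alone. Round-trips unchanged through
#' [write_study_config()] / [read_study_config()].
#'
#' @param cohort list: `n` subjects and `seed`, plus optional overrides for
#'   [calibrate_cohort_model()] targets.
#' @param mediation list: `n_boot`, `ci_level`, `seed`.
#' @param cornea list: `n_eyes` synthetic eyes for the tilt-recovery check
#'   (0 disables), `noise_sd_um`, `seed`, plus optional [cornea_spec()]
#'   overrides.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = list(), mediation = list(), cornea = list()) {
  cfg <- list(
    cohort = utils::modifyList(list(n = 86, seed = 20220616), cohort),
    mediation = utils::modifyList(list(n_boot = 5000, ci_level = 0.95,
                                       seed = 20220617), mediation),
    cornea = utils::modifyList(list(n_eyes = 0, noise_sd_um = 0,
                                    seed = 20220618), cornea))
  structure(cfg, class = "study_config")
}

#' Write / read a study configuration (YAML)
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_study_config()` returns the config.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  study_config(cohort = cfg$cohort %||% list(),
               mediation = cfg$mediation %||% list(),
               cornea = cfg$cornea %||% list())
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic study
#'
#' End-to-end orchestration: simulates the calibrated cohort, computes
#' Pearson correlations of densitometry against tilt for every zone and
#' depth layer (plus age-tilt and age-densitometry), runs both simple
#' mediation cases — tilt -> densitometry with age as mediator, and
#' age -> densitometry with tilt as mediator — and optionally generates
#' synthetic eyes to verify tilt recovery. Fully deterministic given the
#' configured seeds.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cc <- config$cohort
  model_args <- cc[setdiff(names(cc), c("n", "seed"))]
  model <- do.call(calibrate_cohort_model, model_args)
  cohort <- simulate_cohort(model, n = cc$n, seed = cc$seed)

  dens_cols <- c(gsu_layer_anterior = "Anterior", gsu_layer_central = "Central",
                 gsu_layer_posterior = "Posterior", gsu_zone_0_2 = "0-2 mm",
                 gsu_zone_2_6 = "2-6 mm", gsu_zone_6_10 = "6-10 mm",
                 gsu_zone_10_12 = "10-12 mm", gsu_overall = "Overall")
  corr_rows <- lapply(names(dens_cols), function(col) {
    ct <- pearson(cohort$tilt_deg, cohort[[col]])
    data.frame(region = dens_cols[[col]],
               mean_gsu = mean(cohort[[col]]), sd_gsu = stats::sd(cohort[[col]]),
               min_gsu = min(cohort[[col]]), max_gsu = max(cohort[[col]]),
               r_vs_tilt = ct$r, p_vs_tilt = ct$p)
  })
  corr_table <- do.call(rbind, corr_rows)
  rownames(corr_table) <- NULL

  r_age_tilt <- pearson(cohort$age_years, cohort$tilt_deg)
  r_age_dens <- pearson(cohort$age_years, cohort$gsu_overall)

  md <- config$mediation
  case1 <- simple_mediation(x = cohort$tilt_deg, m = cohort$age_years,
                            y = cohort$gsu_overall, n_boot = md$n_boot,
                            ci_level = md$ci_level, seed = md$seed,
                            case = "tilt -> densitometry through age")
  case2 <- simple_mediation(x = cohort$age_years, m = cohort$tilt_deg,
                            y = cohort$gsu_overall, n_boot = md$n_boot,
                            ci_level = md$ci_level, seed = md$seed + 1,
                            case = "age -> densitometry through tilt")

  eyes <- NULL
  ce <- config$cornea
  if (ce$n_eyes > 0) {
    eyes <- do.call(rbind, lapply(seq_len(ce$n_eyes), function(i) {
      spec_args <- ce[setdiff(names(ce), c("n_eyes", "seed"))]
      tilt_total <- 2 + 8 * (i - 1) / max(1, ce$n_eyes - 1)
      psi <- 2 * pi * i / ce$n_eyes
      spec_args$tilt_x <- tilt_total * cos(psi)
      spec_args$tilt_y <- tilt_total * sin(psi)
      spec_args$seed <- ce$seed + i
      spec <- do.call(cornea_spec, spec_args)
      eye <- make_cornea(spec)
      truth_axis <- as.numeric(eye$truth$matrix %*% c(0, 0, 1))
      res <- estimate_optical_axis(eye$anterior, eye$posterior)
      data.frame(eye = i,
                 true_alpha_deg = angle_between_axes(truth_axis, c(0, 0, 1)),
                 est_alpha_deg = res$angle_alpha,
                 residual = res$residual_deviation,
                 converged = res$converged)
    }))
  }

  structure(list(
    config = config, config_hash = config_hash(config),
    version = as.character(utils::packageVersion("corneatilt")),
    cohort = cohort,
    summary = list(
      age = c(mean = mean(cohort$age_years), sd = stats::sd(cohort$age_years),
              min = min(cohort$age_years), max = max(cohort$age_years)),
      tilt = c(mean = mean(cohort$tilt_deg), sd = stats::sd(cohort$tilt_deg),
               min = min(cohort$tilt_deg), max = max(cohort$tilt_deg)),
      densitometry = c(mean = mean(cohort$gsu_overall), sd = stats::sd(cohort$gsu_overall),
                       min = min(cohort$gsu_overall), max = max(cohort$gsu_overall))),
    correlations = corr_table,
    r_age_tilt = r_age_tilt, r_age_dens = r_age_dens,
    mediation = list(case1 = case1, case2 = case2),
    tilt_recovery = eyes),
    class = "study_report")
}

#' Render a study report as plain text
#'
#' @param report a [run_study()] result.
#' @return character vector of report lines (no timestamps, so reruns with
#'   the same configuration are byte-identical).
#' @export
format_study_report <- function(report) {
  stopifnot(inherits(report, "study_report"))
  s <- report$summary
  fmt_ms <- function(v, unit)
    sprintf("%.2f +/- %.2f %s, range [%.2f, %.2f]", v["mean"], v["sd"], unit, v["min"], v["max"])
  lines <- c(
    sprintf("corneatilt study report (version %s)", report$version),
    sprintf("config hash: %s", report$config_hash),
    sprintf("cohort: n = %d (one right eye per subject), seed = %d",
            nrow(report$cohort), report$config$cohort$seed),
    "",
    sprintf("age:          %s", fmt_ms(s$age, "y")),
    sprintf("corneal tilt: %s", fmt_ms(s$tilt, "deg")),
    sprintf("densitometry: %s", fmt_ms(s$densitometry, "GSU")),
    "",
    sprintf("r(age, tilt)         = %.3f (p = %.3g)", report$r_age_tilt$r, report$r_age_tilt$p),
    sprintf("r(age, densitometry) = %.3f (p = %.3g)", report$r_age_dens$r, report$r_age_dens$p),
    "",
    "densitometry by region (mean +/- SD GSU; r vs tilt):")
  ct <- report$correlations
  lines <- c(lines, sprintf("  %-10s %5.1f +/- %4.1f  [%5.1f, %5.1f]  r = %.3f (p = %.3g)",
                            ct$region, ct$mean_gsu, ct$sd_gsu, ct$min_gsu, ct$max_gsu,
                            ct$r_vs_tilt, ct$p_vs_tilt))
  for (nm in c("case1", "case2")) {
    m <- report$mediation[[nm]]
    lines <- c(lines, "",
               sprintf("mediation %s: %s", nm, m$case),
               sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f, indirect = %.4f",
                       m$a, m$b, m$c, m$c_prime, m$indirect),
               sprintf("  %.1f%% direct, %.1f%% mediated; %d%% CI for indirect [%.4f, %.4f]%s",
                       m$percent_direct, m$percent_mediated, round(100 * m$ci_level),
                       m$ci[1], m$ci[2],
                       if (m$significant_indirect) " (significant)" else ""))
  }
  if (!is.null(report$tilt_recovery)) {
    tr <- report$tilt_recovery
    lines <- c(lines, "", "synthetic-eye tilt recovery:",
               sprintf("  eye %d: true %.3f deg, estimated %.3f deg (residual %.2g, converged %s)",
                       tr$eye, tr$true_alpha_deg, tr$est_alpha_deg, tr$residual, tr$converged))
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_study_report(x), sep = "\n")
  invisible(x)
}

#' Write all study artifacts to a directory
#'
#' Writes `report.txt` (plain-text report), `cohort.csv`,
#' `correlations.csv`, `mediation.json` and `config.yml`. Never mutates its
#' inputs.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(format_study_report(report), file.path(dir, "report.txt"))
  write_cohort_csv(report$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  med <- lapply(report$mediation, function(m)
    m[c("case", "a", "b", "c", "c_prime", "indirect", "percent_direct",
        "percent_mediated", "ci_level", "ci", "significant_indirect",
        "p_a", "p_b", "p_c", "p_c_prime", "n", "n_boot")])
  jsonlite::write_json(med, file.path(dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_study_config(report$config, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Scatter plot of densitometry against corneal tilt, coloured by age
#'
#' @param cohort cohort data.frame.
#' @return a ggplot object.
#' @export
plot_densitometry_tilt <- function(cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_densitometry_tilt requires the ggplot2 package")
  ggplot2::ggplot(cohort, ggplot2::aes(x = tilt_deg, y = gsu_overall,
                                       colour = age_years)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "Age (y)") +
    ggplot2::labs(x = "Corneal tilt, angle alpha (deg)",
                  y = "Overall corneal densitometry (GSU)") +
    ggplot2::theme_minimal()
}
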