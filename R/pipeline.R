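#' Build a run configuration
#'
#' A single serializable list driving the whole simulate-measure-fit-test
#' chain. Every open analysis choice (noise level, perimeter convention,
#' compactness tolerance, tie rules) is surfaced here with its documented
#' default. A run re-executed from the same configuration and seed reproduces
#' identical outputs.
#'
#' @param seed master integer seed.
#' @param profiles named list of [subtype_profile] objects.
#' @param n_spheroids spheroids imaged per time point.
#' @param d0_mean,d0_sd initial equivalent-diameter distribution (um).
#' @param pixel_size um per pixel for simulated imaging.
#' @param count_times days at which cell counts are taken.
#' @param count_n0 initial cells per biosphere.
#' @param count_noise_cv coefficient of variation of count noise.
#' @param perimeter perimeter estimator (`"crofton"` or `"contour"`).
#' @param window_policy `"auto"` (log-linear window search) or `"all"`.
#' @param kappa_star compactness tolerance factor.
#' @param alpha significance level used when reporting rejections.
#' @param cohort cohort settings: a list with `n_tumors`, `volume_median`,
#'   `volume_log_sd`, `sphericity_volume_coupling`, `irregularity_base`,
#'   `voxel_size`.
#' @param out_dir directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 0L,
                       profiles = default_profiles(),
                       n_spheroids = 200L,
                       d0_mean = 40, d0_sd = 8,
                       pixel_size = 0.5,
                       count_times = seq(0, 21, by = 3),
                       count_n0 = 4e4,
                       count_noise_cv = 0.05,
                       perimeter = "crofton",
                       window_policy = "auto",
                       kappa_star = 1.5,
                       alpha = 0.01,
                       cohort = list(n_tumors = 100L, volume_median = 29.09,
                                     volume_log_sd = 0.8,
                                     sphericity_volume_coupling = 0.06,
                                     irregularity_base = 0.78,
                                     voxel_size = 1),
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), profiles = profiles,
              n_spheroids = n_spheroids, d0_mean = d0_mean, d0_sd = d0_sd,
              pixel_size = pixel_size, count_times = count_times,
              count_n0 = count_n0, count_noise_cv = count_noise_cv,
              perimeter = perimeter, window_policy = window_policy,
              kappa_star = kappa_star, alpha = alpha, cohort = cohort,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Default subtype profiles
#'
#' Two profiles bracketing the in-vitro phenotypes: a fast-growing
#' `mesenchymal-like` profile forming compact spheroids with size-independent
#' boundary irregularity, and a slower `proneural-like` profile whose
#' spheroid growth lags the count-derived spherical prediction and whose
#' irregularity increases with area.
#'
#' @return Named list of [subtype_profile] objects.
#' @export
default_profiles <- function() {
  list(
    mesenchymal_like = subtype_profile(
      "mesenchymal-like", tau = 3, irregularity_base = 0.12,
      irregularity_slope = 0, growth_coupling = 1,
      imaging_times = c(3, 8, 16)),
    proneural_like = subtype_profile(
      "proneural-like", tau = 6, irregularity_base = 0.12,
      irregularity_slope = 0.15, growth_coupling = 0.5,
      imaging_times = c(1, 7, 14, 18)))
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file path; format picked by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  profs <- purrr::map(raw$profiles, function(p) {
    subtype_profile(p$name, p$tau,
                    irregularity_base = p$irregularity_base %||% 0.12,
                    irregularity_slope = p$irregularity_slope %||% 0,
                    growth_coupling = p$growth_coupling %||% 1,
                    slope_heterogeneity = p$slope_heterogeneity %||% 1,
                    imaging_times = unlist(p$imaging_times) %||% c(3, 8, 16))
  })
  args <- raw[setdiff(names(raw), "profiles")]
  args$profiles <- profs
  do.call(run_config, args)
}

#' Serialize a run configuration
#'
#' @param config a `run_config`.
#' @param path output file (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  ser$profiles <- purrr::map(config$profiles, unclass)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(ser, path)
  }
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the in-vitro analysis chain for every configured subtype profile
#'
#' For each profile: simulate a cell-count series and a spheroid imaging
#' time course, measure every mask, fit the exponential growth model inside
#' the selected window, score compactness against the spherical prediction,
#' and run the circularity-variance test across size strata.
#'
#' @param config a [run_config].
#' @return An object of class `run_report`: `$cultures` is a named list with,
#'   per profile, `counts`, `fit`, `measures`, `compactness`,
#'   `variance_test`; `$config_hash` and `$seed` record provenance. Artifact
#'   files are written when `config$out_dir` is set.
#' @export
run_invitro_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$profiles) == 0L)
    abort("`config$profiles` must name at least one subtype profile.")
  seeds <- draw_subseeds(config$seed, 2L * length(config$profiles))
  cultures <- list()
  for (i in seq_along(config$profiles)) {
    prof <- config$profiles[[i]]
    nm <- names(config$profiles)[i] %||% prof$name
    counts <- run_stage(paste0("counts:", nm), generate_count_series(
      n0 = config$count_n0, tau = prof$tau, times = config$count_times,
      noise_cv = config$count_noise_cv, seed = seeds[2L * i - 1L],
      culture_id = prof$name))
    fit <- run_stage(paste0("fit:", nm), fit_exponential(
      counts, window = if (identical(config$window_policy, "auto")) "auto" else NULL))
    tc <- run_stage(paste0("simulate:", nm), generate_biosphere_timecourse(
      prof, n_spheroids = config$n_spheroids,
      d0_mean = config$d0_mean, d0_sd = config$d0_sd,
      pixel_size = config$pixel_size, seed = seeds[2L * i]))
    measures <- run_stage(paste0("measure:", nm),
                          measure_shapes(tc, perimeter = config$perimeter))
    compact <- run_stage(paste0("compactness:", nm),
                         compactness_report(measures, fit,
                                            kappa_star = config$kappa_star))
    vartest <- run_stage(paste0("circvar:", nm),
                         circularity_variance_test(measures))
    cultures[[nm]] <- list(profile = prof, counts = counts, fit = fit,
                           truth = dplyr::select(tc, -dplyr::any_of("mask")),
                           measures = measures, compactness = compact,
                           variance_test = vartest)
  }
  report <- structure(
    list(kind = "invitro", cultures = cultures, seed = config$seed,
         alpha = config$alpha, config_hash = hash(serialize_config(config))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report_artifacts(report, config)
  report
}

#' Run the tumor-cohort sphericity analysis
#'
#' Simulates the volume cohort, measures sphericity on every voxel mask,
#' splits the cohort at the median volume, and compares the sphericity of
#' the small and large groups with the Mann-Whitney test.
#'
#' @param config a [run_config]; the `cohort` entry holds the generator
#'   settings.
#' @return A `run_report` with `$cohort` (per-tumor tibble), `$split`,
#'   `$rank_test`.
#' @export
run_cohort_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  gen <- run_stage("simulate:cohort", generate_cohort(
    n_tumors = cc$n_tumors, volume_median = cc$volume_median,
    volume_log_sd = cc$volume_log_sd,
    sphericity_volume_coupling = cc$sphericity_volume_coupling,
    irregularity_base = cc$irregularity_base %||% 0.72,
    voxel_size = cc$voxel_size, seed = config$seed))
  recs <- run_stage("sphericity:cohort",
                    dplyr::bind_rows(purrr::map(gen$volumes, sphericity)))
  truth <- dplyr::rename(gen$table, volume_target_cm3 = "volume_cm3")
  tab <- dplyr::left_join(truth, recs, by = "tumor_id")
  strat <- run_stage("stratify:cohort",
                     stratify_by_median(tab, volume_cm3, id = tumor_id))
  tab$size_group <- strat$assignment$group
  rt <- run_stage("ranktest:cohort",
                  mann_whitney(tab, sphericity, size_group))
  report <- structure(
    list(kind = "cohort", cohort = tab, split = strat, rank_test = rt,
         seed = config$seed, alpha = config$alpha,
         config_hash = hash(serialize_config(config))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report_artifacts(report, config)
  report
}

serialize_config <- function(config) {
  ser <- unclass(config)
  ser$profiles <- purrr::map(config$profiles, unclass)
  ser$out_dir <- NULL
  ser
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s analysis, seed %d\n", x$kind, x$seed))
  if (x$kind == "invitro") {
    for (nm in names(x$cultures)) {
      cu <- x$cultures[[nm]]
      cat(sprintf(
        "  %s: tau = %.3g d, verdict %s, circularity-variance p = %.3g\n",
        nm, cu$fit$tau, cu$compactness$verdict,
        cu$variance_test$test$p_value))
    }
  } else {
    cat(sprintf("  cohort n = %d, threshold %.4g cm^3, Mann-Whitney p = %.3g\n",
                nrow(x$cohort), x$split$threshold, x$rank_test$p_value))
    cat(sprintf("  median sphericity small %.4f / large %.4f\n",
                median(x$cohort$sphericity[x$cohort$size_group == "small"]),
                median(x$cohort$sphericity[x$cohort$size_group == "large"])))
  }
  invisible(x)
}

write_report_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  if (report$kind == "invitro") {
    for (nm in names(report$cultures)) {
      cu <- report$cultures[[nm]]
      readr::write_csv(cu$counts, file.path(od, paste0(nm, "_counts.csv")))
      readr::write_csv(cu$measures, file.path(od, paste0(nm, "_measures.csv")))
      readr::write_csv(cu$compactness$table,
                       file.path(od, paste0(nm, "_compactness.csv")))
      jsonlite::write_json(
        list(fit = glance(cu$fit),
             verdict = cu$compactness$verdict,
             variance_test = tidy(cu$variance_test$test)),
        file.path(od, paste0(nm, "_report.json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  } else {
    readr::write_csv(report$cohort, file.path(od, "cohort.csv"))
    jsonlite::write_json(
      list(threshold_cm3 = report$split$threshold,
           rank_test = tidy(report$rank_test)),
      file.path(od, "cohort_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(list(seed = report$seed, hash = report$config_hash),
                       file.path(od, "provenance.json"), auto_unbox = TRUE)
  invisible(od)
}
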