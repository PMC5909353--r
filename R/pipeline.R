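# ---- reference summary table -------------------------------------------

#' Published per-tumour dispersion summaries
#'
#' The bundled per-tumour summary table (mean, SD, SD/mean, min, max of
#' maximum diameter in mm and area in cm^2 for 6 liver and 7 lung
#' metastases, pooled over 20 readers and both segmentation methods) that
#' the dispersion regressions can be fitted to when raw contours are not
#' available.
#'
#' @return data frame with columns `organ`, `tumour`, `metric`, `mean`,
#'   `sd`, `sd_over_mean`, `min`, `max`.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "liver_lung_summary.csv",
                      package = "recistvar", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit dispersion regressions to a summary table
#'
#' One SD-vs-size regression per organ x metric.  The default forms are
#' `linear` for diameter and `through_origin` for area: a linear fit to
#' the area SDs yields a negative intercept, i.e. negative predicted
#' dispersion over part of the observed range, whereas the proportional
#' (constant-CV) form respects positivity and matches the roughly
#' constant SD/mean of the area summaries.
#'
#' @param summary summary table in the shape of [reference_summary()]
#'   (columns `organ`, `metric`, `mean`, `sd`) or of
#'   [summarize_cohort()].
#' @param forms named list `metric -> form` (or `organ.metric -> form`)
#'   overriding the defaults.
#' @return named list of `sd_regression` objects, keys `organ.metric`.
#' @export
fit_summary_models <- function(summary, forms = NULL) {
  default_forms <- list(diameter_mm = "linear", area_cm2 = "through_origin")
  models <- list()
  for (organ in unique(summary$organ)) {
    for (metric in unique(summary$metric)) {
      sub <- summary[summary$organ == organ & summary$metric == metric, ,
                     drop = FALSE]
      if (nrow(sub) < 3L) next
      key <- paste(organ, metric, sep = ".")
      form <- forms[[key]] %||% forms[[metric]] %||%
        default_forms[[metric]] %||% "linear"
      models[[key]] <- fit_sd_regression(sub$mean, sub$sd, form = form,
                                         organ = organ, metric = metric)
    }
  }
  if (length(models) == 0L) stop("no organ/metric stratum had >= 3 tumours")
  models
}

# ---- pipeline ----------------------------------------------------------

#' Run the full segmentation-variability pipeline
#'
#' Ingest -> measurement -> aberrant-contour exclusion -> per-tumour
#' dispersion summaries -> agreement and group/method tests -> SD-vs-size
#' regressions -> 95% band overlap report.  Input is either a contour CSV
#' or a cohort configuration to simulate.
#'
#' @param contours a `contour_set`, or a path to a contour CSV.
#' @param config optional `cohort_config` used to simulate contours when
#'   `contours` is NULL.
#' @param reference optional reference regions for the wrong-target check
#'   (see [flag_aberrant()]).
#' @param z band quantile (default 1.96).
#' @param variant band construction variant, see [ci_band()].
#' @param forms regression form overrides, see [fit_summary_models()].
#' @param area_pr area PR multiplier choice, see [recist_limits()].
#' @param out_dir optional output directory; when given, all report
#'   artefacts are written there (see Details).
#' @details With `out_dir` set the pipeline writes `summary.csv`
#'   (per-tumour dispersion table), `measurements.csv`, `exclusions.csv`,
#'   `agreement.json`, `tests.json`, `models.json`, `cutoffs.csv` and one
#'   `band_<organ>_<metric>.csv` per fitted model.
#' @return object of class `recist_report`: list with `measurements`,
#'   `exclusions`, `summary`, `agreement`, `tests`, `models`, `cutoffs`,
#'   `config`.
#' @export
run_pipeline <- function(contours = NULL, config = NULL, reference = NULL,
                         z = 1.96, variant = c("evaluated", "scaled"),
                         forms = NULL, area_pr = c("squared", "printed"),
                         out_dir = NULL) {
  variant <- match.arg(variant)
  area_pr <- match.arg(area_pr)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  contours <- stage("ingest", {
    if (is.character(contours)) read_contours(contours)
    else if (inherits(contours, "contour_set")) contours
    else if (!is.null(config)) simulate_cohort(config)$contours
    else stop("supply contours (object or CSV path) or a cohort config")
  })
  measurements <- stage("measure", measure_contours(contours))
  flags <- stage("exclusion",
                 flag_aberrant(contours, reference = reference,
                               quiet = TRUE))
  measurements <- apply_exclusions(measurements, flags)
  summary <- stage("summaries", summarize_cohort(measurements))
  agreement <- stage("agreement", {
    inc <- measurements[!measurements$excluded, , drop = FALSE]
    lapply(c(diameter_mm = "diameter_mm", area_cm2 = "area_cm2"),
           function(metric) {
             # reader x tumour matrix of per-reader means over the
             # included readings (method 2 is never excluded, so every
             # cell has at least one reading)
             m <- tapply(inc[[metric]],
                         list(inc$reader_id, inc$tumour_id), mean)
             icc_agreement(m)
           })
  })
  tests <- stage("tests", {
    out <- list(
      method = compare_groups(measurements, compare = "method",
                              on_unmatched = "drop"),
      reader_group = compare_groups(measurements,
                                    compare = "reader_group",
                                    on_unmatched = "drop"))
    # group independence of the aberrant / adequate split
    grp <- measurements$reader_group[measurements$method == 1L]
    exc <- measurements$excluded[measurements$method == 1L]
    tab <- table(factor(grp, c("physician", "scientist")),
                 factor(exc, c(TRUE, FALSE)))
    out$aberrant_by_group <- if (all(rowSums(tab) > 0) &&
                                 all(colSums(tab) > 0))
      chi2_yates(tab) else NULL
    out
  })
  models <- stage("regression", {
    dia <- summary[summary$metric == "diameter_mm", , drop = FALSE]
    fit_summary_models(rbind(
      data.frame(organ = dia$organ, metric = dia$metric, mean = dia$mean,
                 sd = dia$sd, stringsAsFactors = FALSE),
      {
        ar <- summary[summary$metric == "area_cm2", , drop = FALSE]
        data.frame(organ = ar$organ, metric = ar$metric, mean = ar$mean,
                   sd = ar$sd, stringsAsFactors = FALSE)
      }), forms = forms)
  })
  cutoffs <- stage("cutoffs",
                   overlap_report(models, z = z, variant = variant,
                                  area_pr = area_pr))
  report <- structure(list(measurements = measurements,
                           exclusions = flags, summary = summary,
                           agreement = agreement, tests = tests,
                           models = models, cutoffs = cutoffs,
                           config = list(z = z, variant = variant,
                                         area_pr = area_pr)),
                      class = "recist_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.recist_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}

# ---- report output -----------------------------------------------------

#' Write all report artefacts to a directory
#'
#' @param report a `recist_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "recist_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  wcsv(report$measurements[, setdiff(names(report$measurements),
                                     "vertices")], "measurements.csv")
  wcsv(report$exclusions, "exclusions.csv")
  wcsv(report$summary, "summary.csv")
  wcsv(report$cutoffs, "cutoffs.csv")
  agreement <- lapply(report$agreement, function(a)
    a[c("icc", "icc_pct", "icc_class", "between_subject_sd",
        "within_subject_sd", "type")])
  jsonlite::write_json(agreement, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tests <- list(method = report$tests$method,
                reader_group = report$tests$reader_group)
  if (!is.null(report$tests$aberrant_by_group))
    tests$aberrant_by_group <-
      unclass(report$tests$aberrant_by_group)
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  models <- lapply(report$models, function(m)
    list(organ = m$organ, metric = m$metric, form = m$form,
         coefficients = as.list(m$coefficients),
         residual_sd = m$residual_sd, n_points = m$n_points))
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(report$models)) {
    m <- report$models[[key]]
    lim <- recist_limits(m$metric, area_pr = report$config$area_pr)
    xs <- seq(m$size_range[1L], m$size_range[2L], length.out = 200L)
    curves <- do.call(rbind, lapply(
      c(stable = 1, pd = lim$k_pd, pr = lim$k_pr),
      function(k) band_curve(m, k, xs, z = report$config$z,
                             variant = report$config$variant)))
    curves$line <- rep(c("stable", "pd", "pr"), each = length(xs))
    wcsv(curves, paste0("band_", gsub("\\.", "_", key), ".csv"))
  }
  invisible(out_dir)
}

#' Render the per-tumour dispersion and cut-off tables as text
#'
#' Formats the per-tumour table in the conventional layout (mean, SD,
#' SD/mean, min, max per tumour and metric, two decimal places; values
#' are rounded for display only) followed by the band-overlap table.
#'
#' @param report a `recist_report`, or a summary data frame from
#'   [summarize_cohort()].
#' @return character vector of lines.
#' @export
render_tables <- function(report) {
  summary <- if (inherits(report, "recist_report")) report$summary
             else report
  need <- c("organ", "tumour_id", "metric", "mean", "sd", "cv",
            "min", "max")
  miss <- setdiff(need, names(summary))
  if (length(miss)) stop("incomplete report: missing ",
                         paste(miss, collapse = ", "))
  f2 <- function(x) sprintf("%.2f", x)
  lines <- character(0)
  for (metric in unique(summary$metric)) {
    lines <- c(lines, sprintf("== %s ==", metric),
               sprintf("%-12s %10s %8s %8s %8s %8s",
                       "tumour", "mean", "SD", "SD/mean", "min", "max"))
    for (organ in c("liver", "lung")) {
      sub <- summary[summary$metric == metric & summary$organ == organ, ,
                     drop = FALSE]
      if (nrow(sub) == 0L) {
        lines <- c(lines, sprintf("(no %s tumours)", organ))
        next
      }
      for (i in seq_len(nrow(sub)))
        lines <- c(lines, sprintf("%-12s %10s %8s %8s %8s %8s",
                                  sub$tumour_id[i], f2(sub$mean[i]),
                                  f2(sub$sd[i]), f2(sub$cv[i]),
                                  f2(sub$min[i]), f2(sub$max[i])))
    }
    lines <- c(lines, "")
  }
  if (inherits(report, "recist_report")) {
    lines <- c(lines, "== band overlap ==",
               sprintf("%-8s %-12s %-4s %-14s %10s", "organ", "metric",
                       "lim", "overlap", "cutoff"))
    co <- report$cutoffs
    for (i in seq_len(nrow(co)))
      lines <- c(lines, sprintf("%-8s %-12s %-4s %-14s %10s",
                                co$organ[i], co$metric[i], co$limit[i],
                                co$overlap[i],
                                ifelse(is.na(co$cutoff[i]), "-",
                                       f2(co$cutoff[i]))))
  }
  lines
}
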