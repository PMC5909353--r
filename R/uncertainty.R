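# ---- SD-vs-size regression ---------------------------------------------

#' Fit a dispersion-versus-size regression
#'
#' Ordinary least squares of per-tumour segmentation SD on per-tumour mean
#' size, per organ and metric.  Supported forms: `linear` (a + b*s, the
#' default), `through_origin` (b*s, proportional dispersion / constant
#' CV), `quadratic` (a + b*s + c*s^2) and `power` (exp(a) * s^b, fitted on
#' the log scale).  Predicted dispersion is clamped at zero.
#'
#' @param sizes per-tumour mean sizes (mm or cm^2); positive, distinct.
#' @param sds per-tumour segmentation SDs (same units).
#' @param form regression form.
#' @param organ,metric optional labels carried into the result.
#' @return object of class `sd_regression`: list with `coefficients`
#'   (named a, b[, c]), `residual_sd`, `n_points`, `form`, `fit` (the
#'   underlying `lm`), `organ`, `metric`, `size_range`.
#' @export
fit_sd_regression <- function(sizes, sds,
                              form = c("linear", "through_origin",
                                       "quadratic", "power"),
                              organ = NA_character_,
                              metric = NA_character_) {
  form <- match.arg(form)
  if (length(sizes) != length(sds)) stop("sizes and sds differ in length")
  if (length(sizes) < 3L) stop("at least 3 points are required")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("sizes must be finite and positive")
  if (any(!is.finite(sds)) || any(sds < 0)) stop("sds must be finite, >= 0")
  if (length(unique(sizes)) < 2L)
    stop("degenerate design: all sizes identical")
  df <- data.frame(s = sizes, y = sds)
  fit <- switch(form,
    linear = stats::lm(y ~ s, data = df),
    through_origin = stats::lm(y ~ s - 1, data = df),
    quadratic = stats::lm(y ~ s + I(s^2), data = df),
    power = {
      if (any(sds <= 0)) stop("power form requires strictly positive sds")
      stats::lm(log(y) ~ log(s), data = df)
    })
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("degenerate design: collinear predictors")
  coefficients <- switch(form,
    linear = c(a = unname(cf[1L]), b = unname(cf[2L])),
    through_origin = c(a = 0, b = unname(cf[1L])),
    quadratic = c(a = unname(cf[1L]), b = unname(cf[2L]),
                  c = unname(cf[3L])),
    power = c(a = unname(cf[1L]), b = unname(cf[2L])))
  structure(list(coefficients = coefficients,
                 residual_sd = stats::sigma(fit),
                 n_points = length(sizes), form = form, fit = fit,
                 organ = organ, metric = metric,
                 size_range = range(sizes)),
            class = "sd_regression")
}

#' Predicted dispersion at a size
#'
#' Evaluates the fitted dispersion law; negative fitted values are clamped
#' to zero.
#'
#' @param object an `sd_regression`.
#' @param sizes sizes at which to predict (positive).
#' @param ... unused.
#' @return predicted SDs, same length as `sizes`.
#' @export
predict.sd_regression <- function(object, sizes, ...) {
  if (any(sizes < 0)) stop("sizes must be non-negative")
  cf <- object$coefficients
  raw <- switch(object$form,
    linear = cf["a"] + cf["b"] * sizes,
    through_origin = cf["b"] * sizes,
    quadratic = cf["a"] + cf["b"] * sizes + cf["c"] * sizes^2,
    power = exp(cf["a"]) * sizes^cf["b"])
  unname(pmax(0, raw))
}

#' @export
print.sd_regression <- function(x, ...) {
  cat(sprintf("sd_regression [%s/%s, %s]: %s; residual SD %.4g (n = %d)\n",
              x$organ, x$metric, x$form,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$residual_sd, x$n_points))
  invisible(x)
}

# ---- RECIST limit lines ------------------------------------------------

#' RECIST 1.1 response limit multipliers
#'
#' Progressive disease (PD) is a >= 20% diameter increase and partial
#' response (PR) a >= 30% diameter decrease, so the diameter limit lines
#' are y = 1.2 x and y = 0.7 x.  For area the multipliers follow from
#' A = pi r^2: the squares 1.44 and 0.49.  `area_pr = "printed"` selects
#' the alternative 0.47 PR line sometimes quoted for area.
#'
#' @param metric "diameter_mm" or "area_cm2".
#' @param pd_multiplier,pr_multiplier diameter multipliers (defaults 1.2,
#'   0.7).
#' @param area_pr "squared" (0.7^2 = 0.49, default) or "printed" (0.47).
#' @return list of class `recist_limits` with `metric`, `k_pd`, `k_pr`,
#'   `k_stable = 1`.
#' @export
recist_limits <- function(metric = c("diameter_mm", "area_cm2"),
                          pd_multiplier = 1.2, pr_multiplier = 0.7,
                          area_pr = c("squared", "printed")) {
  metric <- match.arg(metric)
  area_pr <- match.arg(area_pr)
  if (!(pd_multiplier > 1 && 1 > pr_multiplier && pr_multiplier > 0))
    stop("need pd_multiplier > 1 > pr_multiplier > 0")
  if (metric == "diameter_mm") {
    k_pd <- pd_multiplier; k_pr <- pr_multiplier
  } else {
    k_pd <- pd_multiplier^2
    k_pr <- if (area_pr == "squared") pr_multiplier^2 else 0.47
  }
  structure(list(metric = metric, k_pd = k_pd, k_pr = k_pr, k_stable = 1),
            class = "recist_limits")
}

#' Limit line slopes for a metric
#'
#' @param limits a `recist_limits`.
#' @return named numeric vector: `stable`, `pd`, `pr`.
#' @export
limit_lines <- function(limits) {
  stopifnot(inherits(limits, "recist_limits"))
  c(stable = limits$k_stable, pd = limits$k_pd, pr = limits$k_pr)
}

# ---- confidence bands --------------------------------------------------

#' Half-width of the 95% confidence band at a size
#'
#' The band around a measurement of a lesion of size `size` has half-width
#' `z * sigma(size)` with `sigma` the fitted dispersion law.  For the band
#' around a limit line y = k x at baseline x, the dispersion is evaluated
#' at the limit value k x (`variant = "evaluated"`, default) or scaled as
#' k * sigma(x) (`variant = "scaled"`); the variants differ only through
#' the regression intercept.
#'
#' @param model an `sd_regression`.
#' @param size baseline sizes (> 0 allowed; 0 gives 0).
#' @param z normal quantile (default 1.96 for a 95% band).
#' @param k limit line slope (default 1, the stable line).
#' @param variant band construction for limit lines.
#' @return half-widths in metric units.
#' @export
ci_band <- function(model, size, z = 1.96, k = 1,
                    variant = c("evaluated", "scaled")) {
  variant <- match.arg(variant)
  if (any(size < 0)) stop("size must be non-negative")
  if (z < 0) stop("z must be non-negative")
  if (variant == "evaluated") z * predict(model, k * size)
  else z * k * predict(model, size)
}

#' Band curves for plotting or export
#'
#' @param model an `sd_regression`.
#' @param k line slope (1 = stable, or a limit multiplier).
#' @param xs baseline sizes.
#' @param z quantile (default 1.96).
#' @param variant see [ci_band()].
#' @return data frame `x`, `y`, `lower`, `upper`.
#' @export
band_curve <- function(model, k, xs, z = 1.96,
                       variant = c("evaluated", "scaled")) {
  variant <- match.arg(variant)
  hw <- ci_band(model, xs, z = z, k = k, variant = variant)
  data.frame(x = xs, y = k * xs, lower = k * xs - hw, upper = k * xs + hw)
}

# ---- overlap and cut-off detection -------------------------------------

# Gap between the stable-disease band and a limit band at baseline x:
#   PD (k > 1): gap = (k x - z*B_limit) - (x + z*sigma(x))
#   PR (k < 1): gap = (x - z*sigma(x)) - (k x + z*B_limit)
# both reduce to g(x) = |k - 1| x - z (sigma(x) + B_limit(x)/z); bands
# overlap where g(x) <= 0.
#' @keywords internal
band_gap <- function(model, k, x, z, variant) {
  hw_stable <- ci_band(model, x, z = z, k = 1)
  hw_limit <- ci_band(model, x, z = z, k = k, variant = variant)
  abs(k - 1) * x - hw_stable - hw_limit
}

#' Solve for the size at which response bands start to overlap
#'
#' Finds where the 95% band around the stable-disease line y = x meets the
#' 95% band around a RECIST limit line y = k x.  For a linear dispersion
#' law the root of the gap function is closed-form; otherwise (or when the
#' zero-clamp of the dispersion law is active near the root) it is found
#' by bisection.  Overlap over the evaluated size range is classified as
#' `none`, `above_cutoff`, `below_cutoff` or `everywhere`.
#'
#' @param model an `sd_regression`.
#' @param limits a `recist_limits` for the model's metric.
#' @param limit "PD" or "PR".
#' @param z quantile (default 1.96).
#' @param range evaluation interval of baseline sizes; defaults to the
#'   model's observed size range.
#' @param variant band construction, see [ci_band()].
#' @param n_grid grid resolution for overlap classification.
#' @return object of class `cutoff_result`: list with `organ`, `metric`,
#'   `limit`, `overlap`, `cutoff` (NA when no single crossing), `z`,
#'   `range`, `in_range` (FALSE when the crossing lies outside `range`).
#' @export
solve_cutoff <- function(model, limits, limit = c("PD", "PR"), z = 1.96,
                         range = NULL,
                         variant = c("evaluated", "scaled"),
                         n_grid = 4001L) {
  limit <- match.arg(limit)
  variant <- match.arg(variant)
  stopifnot(inherits(model, "sd_regression"),
            inherits(limits, "recist_limits"))
  k <- if (limit == "PD") limits$k_pd else limits$k_pr
  if (is.null(range)) range <- model$size_range
  if (range[1L] <= 0 || range[2L] <= range[1L])
    stop("range must be a positive, increasing interval")
  xs <- seq(range[1L], range[2L], length.out = n_grid)
  g <- band_gap(model, k, xs, z, variant)
  neg <- g <= 0
  res <- list(organ = model$organ, metric = model$metric, limit = limit,
              z = z, range = range, variant = variant,
              cutoff = NA_real_, in_range = TRUE)
  if (!any(neg)) {
    res$overlap <- "none"
    # even with no overlap on the range, report an out-of-range crossing
    root <- cutoff_root(model, k, z, variant, range, widen = TRUE)
    if (!is.na(root)) {
      res$cutoff <- root
      res$in_range <- FALSE
      warning("band crossing at ", signif(root, 4),
              " lies outside the evaluated range")
    }
  } else if (all(neg)) {
    res$overlap <- "everywhere"
  } else {
    root <- cutoff_root(model, k, z, variant, range)
    res$cutoff <- root
    # overlap side: negative gap above or below the crossing
    res$overlap <- if (g[n_grid] <= 0) "above_cutoff" else "below_cutoff"
  }
  structure(res, class = "cutoff_result")
}

# Root of the gap function.  Closed form for an unclamped linear law:
#   g(x) = |k-1| x - z (2a + b (1+k) x)        [evaluated]
#   g(x) = |k-1| x - z (1+k)(a + b x)          [scaled]
# falls back to bisection when the form is not linear, the clamp is
# active at the candidate root, or no closed form applies.
#' @keywords internal
cutoff_root <- function(model, k, z, variant, range, widen = FALSE) {
  if (model$form %in% c("linear", "through_origin")) {
    a <- model$coefficients["a"]; b <- model$coefficients["b"]
    den <- abs(k - 1) - z * b * (1 + k)
    num <- if (variant == "evaluated") 2 * z * a else z * (1 + k) * a
    if (den != 0) {
      root <- unname(num / den)
      clamp_free <- root > 0 &&
        predict(model, root) == (a + b * root) &&
        predict(model, k * root) == (a + b * k * root)
      if (clamp_free && (widen || (root >= range[1L] && root <= range[2L])))
        return(root)
      if (clamp_free && !widen) return(NA_real_)
    }
  }
  lo <- if (widen) max(1e-9, range[1L] / 10) else range[1L]
  hi <- if (widen) range[2L] * 10 else range[2L]
  xs <- seq(lo, hi, length.out = 20001L)
  g <- band_gap(model, k, xs, z, variant)
  sgn <- sign(g)
  flip <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0L) {
    exact0 <- which(g == 0)
    return(if (length(exact0)) xs[exact0[1L]] else NA_real_)
  }
  i <- flip[1L]
  stats::uniroot(function(x) band_gap(model, k, x, z, variant),
                 lower = xs[i], upper = xs[i + 1L],
                 tol = 1e-10)$root
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("%s/%s %s: overlap %s%s (z = %.3g, range %.4g-%.4g)\n",
              x$organ, x$metric, x$limit, x$overlap,
              if (is.na(x$cutoff)) "" else
                sprintf(", cutoff %.4g%s", x$cutoff,
                        if (x$in_range) "" else " [outside range]"),
              x$z, x$range[1L], x$range[2L]))
  invisible(x)
}

#' Overlap report across organs and metrics
#'
#' Runs [solve_cutoff()] for PD and PR on every fitted model.
#'
#' @param models list of `sd_regression` objects (any order; the report is
#'   sorted by organ, metric and limit).
#' @param z quantile (default 1.96).
#' @param ranges optional named list `organ.metric -> c(lo, hi)`
#'   overriding each model's observed size range.
#' @param variant band construction, see [ci_band()].
#' @param area_pr area PR multiplier choice, see [recist_limits()].
#' @return data frame with one row per model x limit: `organ`, `metric`,
#'   `limit`, `overlap`, `cutoff`, `in_range`, `z`.
#' @export
overlap_report <- function(models, z = 1.96, ranges = NULL,
                           variant = c("evaluated", "scaled"),
                           area_pr = c("squared", "printed")) {
  variant <- match.arg(variant)
  area_pr <- match.arg(area_pr)
  rows <- list()
  for (model in models) {
    if (!inherits(model, "sd_regression")) {
      message("skipping non-model entry in overlap report")
      next
    }
    lim <- recist_limits(model$metric, area_pr = area_pr)
    key <- paste(model$organ, model$metric, sep = ".")
    rng <- if (!is.null(ranges) && !is.null(ranges[[key]]))
      ranges[[key]] else NULL
    for (side in c("PD", "PR")) {
      co <- suppressWarnings(
        solve_cutoff(model, lim, side, z = z, range = rng,
                     variant = variant))
      rows[[length(rows) + 1L]] <-
        data.frame(organ = model$organ, metric = model$metric,
                   limit = side, overlap = co$overlap,
                   cutoff = co$cutoff, in_range = co$in_range, z = z,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no models supplied")
  out <- do.call(rbind, rows)
  out <- out[order(out$organ, out$metric, out$limit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
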