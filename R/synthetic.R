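# ---- cohort configuration ----------------------------------------------

#' Configuration for a synthetic multi-reader segmentation cohort
#'
#' Defaults emulate the study design the package analyses: 13 metastases
#' (6 liver, 7 lung), 20 readers in two groups of 10 (physicians and
#' scientists), two segmentation methods (1 = free slice choice,
#' 2 = imposed slice), organ-specific size-dependent contour noise, and a
#' 2.5% aberrant-segmentation rate (all aberrant contours arise under
#' method 1 as off-slice segmentations).
#'
#' Noise laws give the between-reader SD of the measured diameter as a
#' linear function of true diameter, sigma(d) = a + b d (mm).  The liver
#' default (a = -3, b = 0.17) makes dispersion grow with lesion size; the
#' lung default (a = 0.3, b = 0) is small and size-independent,
#' reproducing the qualitative organ contrast (liver bands overlap the
#' response limits at large sizes, lung bands do not).
#'
#' @param n_liver,n_lung lesion counts (defaults 6, 7).
#' @param n_readers_per_group readers per group (default 10).
#' @param size_range_liver,size_range_lung true-diameter ranges in mm.
#' @param noise_liver,noise_lung c(a, b) of sigma(d) = a + b d in mm.
#' @param aberrant_rate fraction of all contours planted as aberrant
#'   (default 0.025); must be in [0, 0.5).
#' @param aberrant_mode "binomial" draws the aberrant count as
#'   Binomial(n_contours, rate); "fixed" plants exactly
#'   round(rate * n_contours) for deterministic headline counts.
#' @param slice_jitter probabilities of slice offsets -1, 0, +1 for
#'   non-aberrant method-1 contours.
#' @param vertex_jitter_sd per-vertex radial jitter SD in mm.
#' @param n_vertices polygon resolution.
#' @param seed integer RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_liver = 6L, n_lung = 7L,
                          n_readers_per_group = 10L,
                          size_range_liver = c(18, 77),
                          size_range_lung = c(7, 49),
                          noise_liver = c(a = -3, b = 0.17),
                          noise_lung = c(a = 0.3, b = 0),
                          aberrant_rate = 0.025,
                          aberrant_mode = c("binomial", "fixed"),
                          slice_jitter = c(0.15, 0.7, 0.15),
                          vertex_jitter_sd = 0.1,
                          n_vertices = 64L,
                          seed = 1L) {
  aberrant_mode <- match.arg(aberrant_mode)
  # YAML round-trips deliver lists; coerce vector-valued fields
  num <- function(x) as.numeric(unlist(x))
  size_range_liver <- num(size_range_liver)
  size_range_lung <- num(size_range_lung)
  noise_liver <- num(noise_liver)
  noise_lung <- num(noise_lung)
  slice_jitter <- num(slice_jitter)
  if (n_liver < 0 || n_lung < 0 || n_liver + n_lung < 1)
    stop("at least one lesion is required")
  if (n_readers_per_group < 1) stop("need at least one reader per group")
  if (aberrant_rate < 0 || aberrant_rate >= 0.5)
    stop("aberrant_rate must be in [0, 0.5)")
  if (length(slice_jitter) != 3L || any(slice_jitter < 0) ||
      abs(sum(slice_jitter) - 1) > 1e-8)
    stop("slice_jitter must be probabilities over offsets -1, 0, +1")
  for (org in c("liver", "lung")) {
    n <- if (org == "liver") n_liver else n_lung
    if (n == 0) next
    rng <- if (org == "liver") size_range_liver else size_range_lung
    law <- if (org == "liver") noise_liver else noise_lung
    if (any(law[1L] + law[2L] * rng < 0))
      stop("infeasible ", org, " noise law: sigma < 0 within size range")
  }
  structure(list(n_liver = as.integer(n_liver), n_lung = as.integer(n_lung),
                 n_readers_per_group = as.integer(n_readers_per_group),
                 size_range_liver = size_range_liver,
                 size_range_lung = size_range_lung,
                 noise_liver = stats::setNames(noise_liver, c("a", "b")),
                 noise_lung = stats::setNames(noise_lung, c("a", "b")),
                 aberrant_rate = aberrant_rate,
                 aberrant_mode = aberrant_mode,
                 slice_jitter = slice_jitter,
                 vertex_jitter_sd = vertex_jitter_sd,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Read or write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_cohort_config`, a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  v <- yaml::read_yaml(path)
  v$aberrant_mode <- v$aberrant_mode %||% "binomial"
  do.call(cohort_config, v)
}

#' @rdname read_cohort_config
#' @param config a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ground-truth lesions ----------------------------------------------

# Star-convex lesion outline: unit radial function
# r(theta) = 1 + sum_m c_m cos(m theta + phi_m), low-order harmonics with
# small amplitudes so r > 0 everywhere.
#' @keywords internal
lesion_radial <- function(coefs, phases, theta) {
  r <- rep(1, length(theta))
  for (m in seq_along(coefs))
    r <- r + coefs[m] * cos((m + 1) * theta + phases[m])
  r
}

#' Generate ground-truth lesions for a synthetic cohort
#'
#' Lesion outlines are star-convex: a circle perturbed by two or three
#' low-order Fourier harmonics.  True diameters are drawn uniformly
#' within the per-organ size range; each outline is rescaled so its
#' maximum chord (at the polygon resolution used throughout) equals the
#' drawn diameter.
#'
#' @param config a `cohort_config`; `config$seed` makes the cohort
#'   deterministic.
#' @return data frame of class `lesion_set` with columns `tumour_id`,
#'   `organ`, `true_diameter_mm`, `true_slice`, and list-columns
#'   `shape_coefs`, `shape_phases`, `base_vertices` (the ground-truth
#'   polygon in mm, centred at the origin).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  organs <- c(rep("liver", config$n_liver), rep("lung", config$n_lung))
  n <- length(organs)
  ids <- paste0(organs, "_", c(seq_len(config$n_liver),
                               seq_len(config$n_lung)))
  theta <- 2 * pi * (seq_len(config$n_vertices) - 1L) / config$n_vertices
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rng <- if (organs[i] == "liver") config$size_range_liver
           else config$size_range_lung
    d <- stats::runif(1L, rng[1L], rng[2L])
    n_harm <- sample(2:3, 1L)
    coefs <- stats::runif(n_harm, 0.01, 0.08)
    phases <- stats::runif(n_harm, 0, 2 * pi)
    r <- lesion_radial(coefs, phases, theta)
    v <- cbind(r * cos(theta), r * sin(theta))
    scale <- d / max(stats::dist(v))
    v <- v * scale
    rows[[i]] <- list(tumour_id = ids[i], organ = organs[i],
                      true_diameter_mm = d,
                      true_slice = sample(20:80, 1L),
                      shape_coefs = coefs, shape_phases = phases,
                      base_vertices = v)
  }
  out <- data.frame(tumour_id = vapply(rows, `[[`, "", "tumour_id"),
                    organ = vapply(rows, `[[`, "", "organ"),
                    true_diameter_mm = vapply(rows, `[[`, 0,
                                              "true_diameter_mm"),
                    true_slice = vapply(rows, function(r)
                      as.integer(r$true_slice), integer(1L)),
                    stringsAsFactors = FALSE)
  out$shape_coefs <- lapply(rows, `[[`, "shape_coefs")
  out$shape_phases <- lapply(rows, `[[`, "shape_phases")
  out$base_vertices <- lapply(rows, `[[`, "base_vertices")
  class(out) <- c("lesion_set", "data.frame")
  out
}

#' @keywords internal
organ_noise_sd <- function(config, organ, d) {
  law <- if (organ == "liver") config$noise_liver else config$noise_lung
  max(0, unname(law["a"] + law["b"] * d))
}

#' Simulate one reader's contour of a lesion
#'
#' The reader's outline is the ground-truth radial function scaled by
#' (1 + eps) with eps ~ Normal(0, sigma(d)/d) — so the measured diameter
#' is d (1 + eps) and its between-reader SD matches the organ noise law —
#' plus independent per-vertex radial jitter.  Under method 1 the slice
#' is additionally jittered by the configured offset distribution;
#' `aberrant = TRUE` (method 1 only) instead displaces the slice by 2-4
#' slices and inflates the outline, emulating a segmentation of the wrong
#' structure.
#'
#' @param lesion one row of a `lesion_set`.
#' @param reader_id,reader_group,method contour metadata.
#' @param config the `cohort_config`.
#' @param aberrant plant this contour as aberrant (method 1 only).
#' @return list with `meta` (one-row data frame) and `vertices`.
#' @export
simulate_reader_contour <- function(lesion, reader_id, reader_group,
                                    method, config, aberrant = FALSE) {
  d <- lesion$true_diameter_mm
  sigma <- organ_noise_sd(config, lesion$organ, d)
  eps <- if (sigma > 0) stats::rnorm(1L, 0, sigma / d) else 0
  v <- lesion$base_vertices[[1L]] * (1 + eps)
  if (config$vertex_jitter_sd > 0) {
    nv <- nrow(v)
    rad <- sqrt(rowSums(v^2))
    jit <- stats::rnorm(nv, 0, config$vertex_jitter_sd)
    v <- v * (rad + jit) / rad
  }
  slice <- lesion$true_slice
  if (aberrant) {
    if (method != 1L) stop("aberrant contours only arise under method 1")
    slice <- slice + sample(c(-1L, 1L), 1L) * sample(2:4, 1L)
    v <- v * stats::runif(1L, 1.2, 1.6) +
      matrix(rep(stats::runif(2L, 1.5, 3) * d, each = nrow(v)), ncol = 2L)
  } else if (method == 1L) {
    slice <- slice + sample(-1:1, 1L, prob = config$slice_jitter)
  }
  list(meta = data.frame(tumour_id = lesion$tumour_id,
                         organ = lesion$organ,
                         reader_id = reader_id,
                         reader_group = reader_group,
                         method = method, slice_index = slice,
                         stringsAsFactors = FALSE),
       vertices = v)
}

#' Simulate the full multi-reader contour set for a cohort
#'
#' Every reader contours every lesion under both methods.  Aberrant
#' contours are planted among the method-1 contours: their count is
#' Binomial(n_contours, aberrant_rate) (`aberrant_mode = "binomial"`) or
#' exactly round(rate * n_contours) (`"fixed"`).
#'
#' @param lesions a `lesion_set` from [generate_cohort()].
#' @param config the `cohort_config` (the RNG state continues from
#'   [generate_cohort()] when called in sequence; call
#'   `set.seed(config$seed)` yourself for standalone determinism).
#' @return list with `contours` (a `contour_set`), `planted` (contour ids
#'   planted as aberrant) and `lesions`.
#' @export
simulate_cohort_contours <- function(lesions, config) {
  stopifnot(inherits(lesions, "lesion_set"))
  n_read <- 2L * config$n_readers_per_group
  readers <- data.frame(
    reader_id = sprintf("R%02d", seq_len(n_read)),
    reader_group = rep(c("physician", "scientist"),
                       each = config$n_readers_per_group),
    stringsAsFactors = FALSE)
  n_total <- nrow(lesions) * n_read * 2L
  n_m1 <- n_total %/% 2L
  n_aberrant <- if (config$aberrant_mode == "fixed")
    round(config$aberrant_rate * n_total)
  else stats::rbinom(1L, n_total, config$aberrant_rate)
  n_aberrant <- min(n_aberrant, n_m1)
  aberrant_m1 <- sort(sample.int(n_m1, n_aberrant))
  meta <- vector("list", n_total)
  verts <- vector("list", n_total)
  planted <- character(0)
  idx <- 0L; idx_m1 <- 0L
  for (li in seq_len(nrow(lesions))) {
    lesion <- lesions[li, , drop = FALSE]
    for (ri in seq_len(n_read)) {
      for (method in c(1L, 2L)) {
        idx <- idx + 1L
        ab <- FALSE
        if (method == 1L) {
          idx_m1 <- idx_m1 + 1L
          ab <- idx_m1 %in% aberrant_m1
        }
        sim <- simulate_reader_contour(lesion, readers$reader_id[ri],
                                       readers$reader_group[ri],
                                       method, config, aberrant = ab)
        meta[[idx]] <- sim$meta
        verts[[idx]] <- sim$vertices
        if (ab) planted <- c(planted,
                             paste(lesion$tumour_id, readers$reader_id[ri],
                                   method, sep = "/"))
      }
    }
  }
  field <- function(nm) vapply(meta, function(m) m[[nm]][1L],
                               if (nm %in% c("method", "slice_index"))
                                 integer(1L) else character(1L))
  meta_df <- data.frame(tumour_id = field("tumour_id"),
                        organ = field("organ"),
                        reader_id = field("reader_id"),
                        reader_group = field("reader_group"),
                        method = field("method"),
                        slice_index = field("slice_index"),
                        stringsAsFactors = FALSE)
  contours <- contour_set(meta_df, verts, validate = FALSE)
  list(contours = contours, planted = planted, lesions = lesions)
}

#' Simulate a complete cohort in one call
#'
#' Seeds the RNG from the config, generates ground-truth lesions and the
#' full multi-reader contour set.
#'
#' @param config a `cohort_config`.
#' @return see [simulate_cohort_contours()].
#' @export
simulate_cohort <- function(config) {
  lesions <- generate_cohort(config)   # seeds the RNG
  simulate_cohort_contours(lesions, config)
}

#' Write the ground-truth sidecar table
#'
#' @param lesions a `lesion_set`.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(lesions, path) {
  utils::write.csv(
    as.data.frame(lesions)[, c("tumour_id", "organ", "true_diameter_mm",
                               "true_slice")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulated cohort's contours as CSV
#'
#' Thin wrapper over [write_contours()] kept for symmetry with the
#' simulation entry points; round-trips losslessly through
#' [read_contours()] up to numeric printing precision.
#'
#' @param contours a `contour_set`.
#' @param path output CSV path.
#' @export
export_cohort <- function(contours, path) {
  write_contours(contours, path)
}
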