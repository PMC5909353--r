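# Shared fixture builders.  All randomness uses the calling test's RNG
# state; tests set their own seeds.

# Regular n-gon with circumradius r (mm), centred at the origin.
regular_polygon <- function(n, r = 10) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(th), r * sin(th))
}

# Random simple polygon: star-shaped about the origin (sorted angles,
# positive radii), optionally rotated and translated.
random_star_polygon <- function(n, r_range = c(0.5, 2)) {
  th <- sort(runif(n, 0, 2 * pi))
  # guard against coincident angles producing duplicate vertices
  while (any(diff(th) < 1e-6)) th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_range[1L], r_range[2L])
  cbind(r * cos(th), r * sin(th))
}

rotate_polygon <- function(v, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  v %*% t(R)
}

# Brute-force polygon diameter: maximum over all vertex pairs.
brute_force_diameter <- function(v) max(stats::dist(v))

# A small contour set: `slices` gives one method-1 slice index per
# reader for a single tumour; polygons are unit squares (geometry is
# irrelevant for slice-rule tests).
slice_fixture <- function(slices, tumour_id = "t1", organ = "liver") {
  n <- length(slices)
  meta <- data.frame(
    tumour_id = tumour_id, organ = organ,
    reader_id = sprintf("R%02d", seq_len(n)),
    reader_group = rep(c("physician", "scientist"), length.out = n),
    method = 1L, slice_index = as.integer(slices),
    stringsAsFactors = FALSE)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  contour_set(meta, replicate(n, sq, simplify = FALSE))
}

# Measurement records built directly (no contours), for stats-level
# tests: one row per tumour x reader x method.
synthetic_measurements <- function(diam_fun, n_tumours = 13L,
                                   n_readers = 20L, organ = "liver") {
  grid <- expand.grid(t = seq_len(n_tumours), r = seq_len(n_readers),
                      m = 1:2)
  df <- data.frame(
    contour_id = paste(grid$t, grid$r, grid$m, sep = "/"),
    tumour_id = paste0("t", grid$t),
    organ = organ,
    reader_id = sprintf("R%02d", grid$r),
    reader_group = ifelse(grid$r <= n_readers / 2,
                          "physician", "scientist"),
    method = grid$m,
    slice_index = 40L,
    stringsAsFactors = FALSE)
  df$diameter_mm <- diam_fun(grid$t, grid$r, grid$m)
  df$area_cm2 <- pi * (df$diameter_mm / 20)^2 * 0.9
  df$excluded <- FALSE
  df$exclusion_reason <- NA_character_
  df
}

# Reference liver diameter dispersion model fitted to the bundled
# summary table (used in several uncertainty tests).
liver_diameter_model <- function() {
  ref <- reference_summary()
  sub <- ref[ref$organ == "liver" & ref$metric == "diameter_mm", ]
  fit_sd_regression(sub$mean, sub$sd, form = "linear",
                    organ = "liver", metric = "diameter_mm")
}
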