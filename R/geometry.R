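# ---- polygon primitives ------------------------------------------------

#' Clean a polygon vertex list
#'
#' Drops a repeated closing vertex and collapses identical consecutive
#' vertices.  Coordinates must be finite.
#'
#' @param vertices two-column numeric matrix of (x, y) coordinates in mm,
#'   implicitly closed (first vertex is not repeated at the end).
#' @return cleaned two-column matrix.
#' @keywords internal
clean_vertices <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("vertices must be a two-column numeric matrix of (x, y) in mm")
  if (any(!is.finite(v)))
    stop("vertices must be finite")
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  n <- nrow(v)
  if (n >= 2L) {
    dup <- c(FALSE, rowSums(abs(v[-1L, , drop = FALSE] -
                                  v[-n, , drop = FALSE])) == 0)
    v <- v[!dup, , drop = FALSE]
  }
  v
}

#' Polygon area in cm-squared
#'
#' Shoelace (surveyor's) formula on an implicitly closed polygon with
#' vertex coordinates in mm.  The absolute value is taken, so the result
#' does not depend on vertex orientation; mm^2 are converted to cm^2.
#'
#' @param vertices two-column numeric matrix of (x, y) in mm.
#' @return area in cm^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))  # 1 cm^2
#' @export
polygon_area <- function(vertices) {
  v <- clean_vertices(vertices)
  if (nrow(unique(v)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2 / 100
}

#' Maximum diameter of a polygon in mm
#'
#' The longest chord of a polygon is attained between two vertices, and
#' those vertices lie on the convex hull.  The hull is found with
#' [grDevices::chull()] and the diameter with the rotating-calipers scan
#' over antipodal vertex pairs, which agrees with the brute-force maximum
#' over all vertex pairs but runs in linear time in the hull size.
#'
#' @param vertices two-column numeric matrix of (x, y) in mm.
#' @return maximum pairwise vertex distance in mm.
#' @examples
#' max_diameter(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))  # 10*sqrt(2)
#' @export
max_diameter <- function(vertices) {
  v <- clean_vertices(vertices)
  if (nrow(unique(v)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  h <- grDevices::chull(v[, 1L], v[, 2L])
  hv <- v[rev(h), , drop = FALSE]   # chull is clockwise; calipers wants CCW
  rotating_calipers_diameter(hv)
}

# Rotating calipers on a counter-clockwise convex polygon (matrix of
# vertices, no repeats).  For every edge the antipodal pointer advances
# while the triangle area keeps growing; candidate diameters are the
# distances from both edge endpoints to the antipodal vertex.
#' @keywords internal
rotating_calipers_diameter <- function(hv) {
  h <- nrow(hv)
  if (h < 2L) stop("degenerate hull")
  if (h <= 3L) return(max(stats::dist(hv)))
  x <- hv[, 1L]; y <- hv[, 2L]
  # twice the (unsigned) triangle area spanned by vertices i, i2 and p
  tri2 <- function(i, i2, p)
    abs((x[i2] - x[i]) * (y[p] - y[i]) - (y[i2] - y[i]) * (x[p] - x[i]))
  d2 <- function(i, j) (x[i] - x[j])^2 + (y[i] - y[j])^2
  nxt <- function(i) i %% h + 1L
  best <- 0
  j <- 2L
  for (i in seq_len(h)) {
    i2 <- nxt(i)
    steps <- 0L
    while (tri2(i, i2, nxt(j)) > tri2(i, i2, j) && steps < 2L * h) {
      j <- nxt(j)
      steps <- steps + 1L
    }
    best <- max(best, d2(i, j), d2(i2, j))
  }
  sqrt(best)
}

# Proper-crossing test for segments p1-p2 and p3-p4 (shared endpoints not
# counted).  Used to reject self-intersecting contours after cleanup.
#' @keywords internal
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L]))
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Test whether a cleaned polygon is simple (non-self-intersecting)
#'
#' @param vertices two-column numeric matrix, already cleaned.
#' @return logical scalar.
#' @export
is_simple_polygon <- function(vertices) {
  v <- clean_vertices(vertices)
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(v[idx[i, 1L], ], v[idx[i, 2L], ],
                         v[idx[j, 1L], ], v[idx[j, 2L], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Validate contour vertices
#'
#' Cleans the vertex list (de-duplication only) and rejects polygons that
#' remain degenerate or self-intersecting; no further repair is attempted.
#'
#' @param vertices two-column numeric matrix of (x, y) in mm.
#' @return cleaned vertex matrix, invisibly usable downstream.
#' @export
validate_contour <- function(vertices) {
  v <- clean_vertices(vertices)
  if (nrow(unique(v)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  if (!is_simple_polygon(v))
    stop("polygon is self-intersecting after vertex de-duplication")
  v
}

# ---- contour sets ------------------------------------------------------

#' Build a contour set
#'
#' A contour set is the package's container for multi-reader segmentations:
#' a data frame with one row per contour, carrying the identifying metadata
#' and the polygon as a list-column of vertex matrices (mm).
#'
#' @param meta data frame with columns `tumour_id`, `organ` ("liver" or
#'   "lung"), `reader_id`, `reader_group` ("physician" or "scientist"),
#'   `method` (1 or 2), `slice_index` (integer).
#' @param vertices list of two-column matrices, one per row of `meta`.
#' @param validate validate each polygon (default TRUE).
#' @return object of class `contour_set`.
#' @export
contour_set <- function(meta, vertices, validate = TRUE) {
  meta <- as.data.frame(meta)
  req <- c("tumour_id", "organ", "reader_id", "reader_group",
           "method", "slice_index")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("missing contour metadata: ",
                         paste(miss, collapse = ", "))
  if (!all(meta$organ %in% c("liver", "lung")))
    stop("organ must be 'liver' or 'lung'")
  if (!all(meta$reader_group %in% c("physician", "scientist")))
    stop("reader_group must be 'physician' or 'scientist'")
  if (!all(meta$method %in% c(1L, 2L)))
    stop("method must be 1 or 2")
  if (length(vertices) != nrow(meta))
    stop("one vertex matrix is required per contour")
  vertices <- if (validate) lapply(vertices, validate_contour)
              else lapply(vertices, clean_vertices)
  meta$contour_id <- paste(meta$tumour_id, meta$reader_id, meta$method,
                           sep = "/")
  meta$vertices <- vertices
  class(meta) <- c("contour_set", "data.frame")
  meta
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d contours, %d tumours, %d readers\n",
              nrow(x), length(unique(x$tumour_id)),
              length(unique(x$reader_id))))
  invisible(x)
}

# ---- measurement -------------------------------------------------------

#' Measure contours
#'
#' Extracts the two RECIST metrics from every contour: maximum diameter
#' (mm) and area (cm^2).
#'
#' @param contours a `contour_set`.
#' @return data frame of measurement records (one row per contour) with
#'   columns `contour_id`, `tumour_id`, `organ`, `reader_id`,
#'   `reader_group`, `method`, `slice_index`, `diameter_mm`, `area_cm2`,
#'   `excluded` (FALSE; set by [apply_exclusions()]), `exclusion_reason`.
#' @export
measure_contours <- function(contours) {
  stopifnot(inherits(contours, "contour_set"))
  out <- as.data.frame(contours)[, c("contour_id", "tumour_id", "organ",
                                     "reader_id", "reader_group",
                                     "method", "slice_index")]
  out$diameter_mm <- vapply(contours$vertices, max_diameter, numeric(1L))
  out$area_cm2 <- vapply(contours$vertices, polygon_area, numeric(1L))
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  rownames(out) <- NULL
  out
}

# ---- aberrant-segmentation rule ----------------------------------------

# Modal slice with ties broken towards the median slice, then the lower
# index.  The consensus slice is the one most readers picked.
#' @keywords internal
modal_slice <- function(slices) {
  tab <- table(slices)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (length(cand) > 1L) {
    med <- stats::median(slices)
    cand <- cand[abs(cand - med) == min(abs(cand - med))]
    cand <- min(cand)
  }
  cand
}

#' Flag aberrant segmentations
#'
#' Contours drawn with free slice choice (method 1) are checked against the
#' consensus slice of each tumour: a contour at least two slices away from
#' the slice most often selected by all readers is flagged `slice_offset`.
#' When a per-tumour reference bounding region is supplied, a contour whose
#' bounding box does not intersect it is flagged `wrong_target` (a proxy
#' for a contour drawn on the wrong structure).  Method-2 contours (imposed
#' slice) are never flagged.
#'
#' @param contours a `contour_set`.
#' @param reference optional data frame of reference regions with columns
#'   `tumour_id`, `xmin`, `xmax`, `ymin`, `ymax` (mm).  When absent the
#'   wrong-target check is skipped (a message is emitted once).
#' @param min_offset slice distance at which a contour counts as aberrant;
#'   default 2 ("at least two slices away", inclusive).
#' @param quiet suppress the skipped-check message.
#' @return data frame with columns `contour_id`, `tumour_id`, `reason`
#'   ("slice_offset" or "wrong_target"), one row per flagged contour.
#' @export
flag_aberrant <- function(contours, reference = NULL, min_offset = 2L,
                          quiet = FALSE) {
  stopifnot(inherits(contours, "contour_set"))
  if (nrow(contours) == 0L) stop("empty contour set")
  m1 <- contours[contours$method == 1L, , drop = FALSE]
  flagged <- list()
  for (tid in unique(m1$tumour_id)) {
    sub <- m1[m1$tumour_id == tid, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("tumour ", tid, ": at least two method-1 contours are needed ",
           "to define a consensus slice")
    mode_sl <- modal_slice(sub$slice_index)
    off <- abs(sub$slice_index - mode_sl) >= min_offset
    if (any(off))
      flagged[[length(flagged) + 1L]] <-
        data.frame(contour_id = sub$contour_id[off], tumour_id = tid,
                   reason = "slice_offset", stringsAsFactors = FALSE)
  }
  if (!is.null(reference)) {
    for (tid in unique(m1$tumour_id)) {
      ref <- reference[reference$tumour_id == tid, , drop = FALSE]
      if (nrow(ref) == 0L) next
      sub <- m1[m1$tumour_id == tid, , drop = FALSE]
      already <- unlist(lapply(flagged, `[[`, "contour_id"))
      for (i in seq_len(nrow(sub))) {
        if (sub$contour_id[i] %in% already) next
        v <- sub$vertices[[i]]
        hit <- max(v[, 1L]) >= ref$xmin[1L] && min(v[, 1L]) <= ref$xmax[1L] &&
               max(v[, 2L]) >= ref$ymin[1L] && min(v[, 2L]) <= ref$ymax[1L]
        if (!hit)
          flagged[[length(flagged) + 1L]] <-
            data.frame(contour_id = sub$contour_id[i], tumour_id = tid,
                       reason = "wrong_target", stringsAsFactors = FALSE)
      }
    }
  } else if (!quiet) {
    message("no reference regions supplied; wrong-target check skipped")
  }
  if (length(flagged) == 0L)
    return(data.frame(contour_id = character(), tumour_id = character(),
                      reason = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flagged)
  rownames(out) <- NULL
  out
}

#' Apply an exclusion table to measurement records
#'
#' @param measurements data frame from [measure_contours()].
#' @param flags data frame from [flag_aberrant()].
#' @return `measurements` with `excluded` / `exclusion_reason` filled in.
#' @export
apply_exclusions <- function(measurements, flags) {
  i <- match(measurements$contour_id, flags$contour_id)
  measurements$excluded <- !is.na(i)
  measurements$exclusion_reason <- flags$reason[i]
  measurements
}

# ---- contour CSV dialect -----------------------------------------------

#' Write a contour set to CSV
#'
#' One vertex per row:
#' `tumour_id,organ,reader_id,reader_group,method,slice_index,vertex_index,x_mm,y_mm`.
#'
#' @param contours a `contour_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  if (nrow(contours) == 0L) stop("refusing to write an empty contour set")
  rows <- lapply(seq_len(nrow(contours)), function(i) {
    v <- contours$vertices[[i]]
    data.frame(tumour_id = contours$tumour_id[i],
               organ = contours$organ[i],
               reader_id = contours$reader_id[i],
               reader_group = contours$reader_group[i],
               method = contours$method[i],
               slice_index = contours$slice_index[i],
               vertex_index = seq_len(nrow(v)),
               x_mm = v[, 1L], y_mm = v[, 2L],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write contour CSV at ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a contour set from CSV
#'
#' @param path contour CSV in the dialect written by [write_contours()].
#' @param validate validate each polygon (default TRUE).
#' @return a `contour_set`.
#' @export
read_contours <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("contour CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$tumour_id, df$reader_id, df$method, sep = "/")
  ord <- order(key, df$vertex_index)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  meta <- df[first, c("tumour_id", "organ", "reader_id", "reader_group",
                      "method", "slice_index"), drop = FALSE]
  verts <- lapply(split(seq_len(nrow(df)), factor(key, levels = key[first])),
                  function(i) cbind(df$x_mm[i], df$y_mm[i]))
  contour_set(meta, unname(verts), validate = validate)
}
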