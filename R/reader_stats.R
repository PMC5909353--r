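# ---- per-tumour summaries ----------------------------------------------

#' Summarise one tumour's readings
#'
#' Sample mean, sample SD (n - 1 denominator), min, max and the
#' coefficient of variation (SD divided by the mean) of one metric across
#' readers, as in a per-tumour dispersion table.
#'
#' @param values numeric vector of readings, all finite and positive.
#' @return one-row data frame with `mean`, `sd`, `cv`, `min`, `max`,
#'   `n_readings`.
#' @examples
#' summarize_tumor(c(1, 2, 3))  # mean 2, sd 1, cv 0.5
#' @export
summarize_tumor <- function(values) {
  if (length(values) < 2L) stop("at least two readings are required")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("readings must be finite and positive")
  m <- mean(values); s <- stats::sd(values)
  data.frame(mean = m, sd = s, cv = s / m,
             min = min(values), max = max(values),
             n_readings = length(values))
}

#' Per-tumour dispersion table
#'
#' Applies [summarize_tumor()] per tumour and metric over the included
#' (non-excluded) measurement records, pooling readers, groups and methods.
#'
#' @param measurements measurement records from [measure_contours()],
#'   optionally after [apply_exclusions()].
#' @return data frame with one row per tumour x metric: `organ`,
#'   `tumour_id`, `metric` ("diameter_mm" or "area_cm2"), and the
#'   [summarize_tumor()] columns.
#' @export
summarize_cohort <- function(measurements) {
  inc <- measurements[!measurements$excluded, , drop = FALSE]
  if (nrow(inc) == 0L) stop("no included measurements")
  rows <- list()
  for (metric in c("diameter_mm", "area_cm2")) {
    for (tid in unique(inc$tumour_id)) {
      sub <- inc[inc$tumour_id == tid, , drop = FALSE]
      s <- summarize_tumor(sub[[metric]])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(organ = sub$organ[1L], tumour_id = tid,
                         metric = metric, stringsAsFactors = FALSE), s)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$organ, out$tumour_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- inter-observer agreement ------------------------------------------

#' Intraclass correlation from repeated-measures ANOVA
#'
#' Two-way random-effects ANOVA with tumours as subjects and readers as
#' raters, computed from the mean squares.  The default is the
#' absolute-agreement single-rater coefficient ICC(2,1); the consistency
#' coefficient ICC(3,1) is available via `type = "consistency"`.
#' Agreement is classed as poor (< 0.50), moderate (0.50-0.75),
#' good (0.75-0.90) or excellent (>= 0.90); boundary values go to the
#' higher class.
#'
#' @param readings numeric matrix, readers in rows, tumours in columns;
#'   no missing cells.
#' @param type "agreement" for ICC(2,1) (default) or "consistency" for
#'   ICC(3,1).
#' @return object of class `icc_agreement`: list with `icc`, `icc_pct`,
#'   `icc_class`, `between_subject_sd`, `within_subject_sd`, `type`,
#'   `n_readers`, `n_subjects` and the ANOVA mean squares `ms`.
#' @export
icc_agreement <- function(readings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  y <- as.matrix(readings)
  if (any(is.na(y))) stop("readings matrix must be complete (no NA cells)")
  k <- nrow(y)   # readers (raters)
  n <- ncol(y)   # tumours (subjects)
  if (k < 2L || n < 2L) stop("need at least 2 readers and 2 tumours")
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  if (ss_total == 0) stop("zero total variance: ICC undefined")
  subj_means <- colMeans(y)
  rater_means <- rowMeans(y)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)                 # between-subject (tumour) MS
  msc <- ss_rater / (k - 1)                # between-rater MS
  mse <- ss_err / ((n - 1) * (k - 1))      # residual MS
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  cls <- if (icc < 0.50) "poor" else if (icc < 0.75) "moderate"
         else if (icc < 0.90) "good" else "excellent"
  # one-way decomposition for the reported variability components
  msw <- (ss_rater + ss_err) / (n * (k - 1))
  structure(list(
    icc = icc, icc_pct = 100 * icc, icc_class = cls,
    between_subject_sd = sqrt(max((msr - msw) / k, 0)),
    within_subject_sd = sqrt(msw),
    type = if (type == "agreement") "ICC(2,1)" else "ICC(3,1)",
    n_readers = k, n_subjects = n,
    ms = c(MSR = msr, MSC = msc, MSE = mse)
  ), class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("%s = %.4f (%.1f%%), agreement %s; %d readers x %d tumours\n",
              x$type, x$icc, x$icc_pct, x$icc_class,
              x$n_readers, x$n_subjects))
  invisible(x)
}

# ---- hypothesis tests --------------------------------------------------

#' Yates-corrected chi-squared test of independence on a 2x2 table
#'
#' Continuity-corrected Pearson chi-squared with terms
#' max(0, |O - E| - 1/2)^2 / E and one degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @param correct apply the Yates correction (default TRUE).
#' @return list of class `recist_test` with `test`, `statistic`,
#'   `p_value`, `n`.
#' @export
chi2_yates <- function(table, correct = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  # small expected counts are routine for aberrant-count tables; the
  # approximation warning is not actionable here
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(test = if (correct) "chi2_yates" else "chi2",
                 statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 n = sum(tab)),
            class = "recist_test")
}

#' @export
print.recist_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %d)\n",
              x$test, x$statistic, x$p_value, x$n))
  invisible(x)
}

# Exact null distribution of the positive-rank sum for (possibly tied)
# midranks, by dynamic programming over the doubled ranks (integers).
# Returns P(W <= w) and P(W >= w) under random signs.
#' @keywords internal
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  # counts[s + 1] = number of sign assignments with doubled rank sum s
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  idx <- round(w2) + 1L
  c(lower = sum(counts[seq_len(idx)]),
    upper = sum(counts[idx:length(counts)]))
}

#' Wilcoxon signed rank test for paired readings
#'
#' Two-sided test on paired differences.  Zero differences are dropped.
#' For 25 or fewer informative pairs the p-value is exact, from the full
#' enumeration of sign assignments over the (mid)ranks; above that a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y paired numeric vectors, or `x` a vector of differences when
#'   `y` is NULL.
#' @param exact_max largest n for which the exact enumeration is used
#'   (default 25).
#' @return list of class `recist_test` with `test`, `statistic` (positive
#'   rank sum W), `p_value`, `n` (informative pairs).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences are zero")
  n <- length(d)
  if (n < 5L) stop("fewer than 5 informative (non-zero) pairs")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p2 <- signed_rank_exact_p(round(2 * r), 2 * w)
    p <- min(1, 2 * min(p2))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(test = "wilcoxon_signed_rank", statistic = w,
                 p_value = p, n = n),
            class = "recist_test")
}

# ---- stratified group / method comparisons -----------------------------

#' Compare reader groups or segmentation methods per organ and metric
#'
#' Runs a paired Wilcoxon signed rank test in every organ x metric
#' stratum.  For `compare = "method"` the pairing unit is the individual
#' reader x tumour reading (method 1 vs method 2).  For
#' `compare = "reader_group"` the two arms are paired either by tumour
#' (per-tumour arm means; `pairing = "tumour"`, default) or by reader rank
#' within group (per-reader means over tumours; `pairing = "reader"`,
#' requires equally sized groups).
#'
#' @param measurements measurement records (excluded rows are dropped).
#' @param compare "method" or "reader_group".
#' @param pairing pairing unit for the group comparison.
#' @param on_unmatched "error" (default) aborts listing pairing units
#'   present in only one arm; "drop" silently restricts to the common
#'   units (used by the pipeline, where exclusions legitimately remove
#'   single method-1 readings).
#' @return data frame with one row per organ x metric: `organ`, `metric`,
#'   `n_pairs`, `statistic`, `p_value`.
#' @export
compare_groups <- function(measurements,
                           compare = c("method", "reader_group"),
                           pairing = c("tumour", "reader"),
                           on_unmatched = c("error", "drop")) {
  compare <- match.arg(compare)
  pairing <- match.arg(pairing)
  on_unmatched <- match.arg(on_unmatched)
  inc <- measurements[!measurements$excluded, , drop = FALSE]
  rows <- list()
  for (organ in unique(inc$organ)) {
    for (metric in c("diameter_mm", "area_cm2")) {
      sub <- inc[inc$organ == organ, , drop = FALSE]
      if (compare == "method") {
        key <- paste(sub$tumour_id, sub$reader_id, sep = "/")
        a1 <- tapply(sub[[metric]][sub$method == 1L],
                     key[sub$method == 1L], mean)
        a2 <- tapply(sub[[metric]][sub$method == 2L],
                     key[sub$method == 2L], mean)
        common <- intersect(names(a1), names(a2))
        missing <- union(setdiff(names(a1), names(a2)),
                         setdiff(names(a2), names(a1)))
        if (length(missing) && on_unmatched == "error")
          stop("unmatched pairing units for ", organ, "/", metric, ": ",
               paste(missing, collapse = ", "))
        x <- a1[common]; y <- a2[common]
      } else if (pairing == "tumour") {
        g1 <- sub[sub$reader_group == "physician", , drop = FALSE]
        g2 <- sub[sub$reader_group == "scientist", , drop = FALSE]
        a1 <- tapply(g1[[metric]], g1$tumour_id, mean)
        a2 <- tapply(g2[[metric]], g2$tumour_id, mean)
        common <- intersect(names(a1), names(a2))
        missing <- union(setdiff(names(a1), names(a2)),
                         setdiff(names(a2), names(a1)))
        if (length(missing) && on_unmatched == "error")
          stop("unmatched pairing units for ", organ, "/", metric, ": ",
               paste(missing, collapse = ", "))
        x <- a1[common]; y <- a2[common]
      } else {
        g1 <- sub[sub$reader_group == "physician", , drop = FALSE]
        g2 <- sub[sub$reader_group == "scientist", , drop = FALSE]
        a1 <- sort(tapply(g1[[metric]], g1$reader_id, mean))
        a2 <- sort(tapply(g2[[metric]], g2$reader_id, mean))
        if (length(a1) != length(a2))
          stop("reader pairing requires equally sized groups (",
               length(a1), " vs ", length(a2), ")")
        x <- a1; y <- a2
      }
      t <- wilcoxon_signed_rank(as.numeric(x), as.numeric(y))
      rows[[length(rows) + 1L]] <-
        data.frame(organ = organ, metric = metric, compare = compare,
                   n_pairs = t$n, statistic = t$statistic,
                   p_value = t$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
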