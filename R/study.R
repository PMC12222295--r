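#' Assemble a tidy study frame of per-image measurements
#'
#' One row per image-level measurement: mouse id, mouse line, day in
#' culture, hippocampal region, metric name and value.
#'
#' @param mouse mouse identifier.
#' @param line mouse line, \code{"wild_type"} or
#'   \code{"tnf_overexpressing"}.
#' @param day day in culture (3, 7 or 14 in the reference design).
#' @param region hippocampal region (e.g. \code{"CA3"}).
#' @param metric metric name (e.g. \code{"area_fraction_microglia"},
#'   \code{"process_count"}).
#' @param value finite numeric measurement.
#' @return data.frame of class \code{studyFrame}.
#' @export
studyFrame <- function(mouse, line, day, region, metric, value) {
  if (any(!is.finite(value))) stop("metric values must be finite")
  out <- data.frame(mouse = as.character(mouse), line = as.character(line),
                    day = as.integer(day), region = as.character(region),
                    metric = as.character(metric), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  class(out) <- c("studyFrame", "data.frame")
  out
}

#' Aggregate per-image values to per-mouse means
#'
#' The unit of analysis is the mouse: the mean over all images of one
#' mouse is taken within each (mouse, line, day, region, metric) cell.
#'
#' @param frame a \code{\link{studyFrame}}.
#' @return data.frame with the same grouping columns and the per-mouse
#'   mean in \code{value}.
#' @export
aggregateStudy <- function(frame) {
  if (nrow(frame) == 0L) stop("empty study frame")
  out <- stats::aggregate(value ~ mouse + line + day + region + metric,
                          data = frame, FUN = mean)
  out[order(out$metric, out$region, out$day, out$line, out$mouse), ,
      drop = FALSE]
}

# Shapiro-Wilk gate on within-group-centred residuals; returns the
# (possibly log-transformed) values plus the gate report.
.normalityGate <- function(values, groups, alpha = 0.05) {
  centred <- unlist(lapply(split(values, groups), function(v) v - mean(v)),
                    use.names = FALSE)
  p_raw <- tryCatch(stats::shapiro.test(centred)$p.value,
                    error = function(e) NA_real_)
  if (!is.na(p_raw) && p_raw < alpha) {
    if (any(values <= 0))
      stop("non-normal data contain non-positive values; cannot log-transform")
    lv <- log(values)
    centredL <- unlist(lapply(split(lv, groups), function(v) v - mean(v)),
                       use.names = FALSE)
    p_log <- tryCatch(stats::shapiro.test(centredL)$p.value,
                      error = function(e) NA_real_)
    list(values = lv, transformed = TRUE, shapiro_p = p_raw,
         shapiro_p_log = p_log)
  } else {
    list(values = values, transformed = FALSE, shapiro_p = p_raw,
         shapiro_p_log = NA_real_)
  }
}

#' Compare the two mouse lines for one metric, day and region
#'
#' Per-mouse means are gated through a Shapiro-Wilk normality test on
#' the within-group-centred residuals; when non-normal (p < 0.05) the
#' values are natural-log transformed and re-tested, and the comparison
#' proceeds on the transformed scale. The two-sample comparison itself
#' is Welch's t-test.
#'
#' @param table per-mouse table from \code{\link{aggregateStudy}}.
#' @param metric,day,region the cell of the design to compare.
#' @param minPerGroup minimum mice per line (default 3).
#' @return list: \code{transformed} flag, \code{shapiro_p},
#'   \code{shapiro_p_log}, group means on the analysis scale,
#'   \code{t}, \code{df}, \code{p.value}, group sizes.
#' @export
compareLines <- function(table, metric, day, region, minPerGroup = 3L) {
  sub <- table[table$metric == metric & table$day == day &
               table$region == region, , drop = FALSE]
  lines <- sort(unique(sub$line))
  if (length(lines) != 2L)
    stop("need exactly two mouse lines present, found: ",
         paste(lines, collapse = ", "))
  n <- table(sub$line)
  if (any(n < minPerGroup))
    stop("each line needs >= ", minPerGroup, " mice")
  gate <- .normalityGate(sub$value, sub$line)
  v <- gate$values
  tt <- stats::t.test(v[sub$line == lines[1L]], v[sub$line == lines[2L]])
  list(metric = metric, day = day, region = region, lines = lines,
       transformed = gate$transformed, shapiro_p = gate$shapiro_p,
       shapiro_p_log = gate$shapiro_p_log,
       means = tapply(v, sub$line, mean),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, n = as.vector(n))
}

#' Time-course analysis within one line and region
#'
#' Per-day means plus all pairwise day-versus-day comparisons using the
#' same normality-gate + Welch procedure as \code{\link{compareLines}};
#' pairwise p-values are reported both unadjusted and Holm-adjusted.
#'
#' @param table per-mouse table from \code{\link{aggregateStudy}}.
#' @param metric,line,region the slice of the design to analyse.
#' @return list: \code{dayMeans} (data.frame day, n, mean) and
#'   \code{pairwise} (data.frame day1, day2, transformed, t, df, p,
#'   p_holm).
#' @export
timeCourse <- function(table, metric, line, region) {
  sub <- table[table$metric == metric & table$line == line &
               table$region == region, , drop = FALSE]
  days <- sort(unique(sub$day))
  if (length(days) < 2L) stop("need at least two days present")
  dayMeans <- do.call(rbind, lapply(days, function(d) {
    v <- sub$value[sub$day == d]
    data.frame(day = d, n = length(v), mean = mean(v))
  }))
  pairs <- utils::combn(days, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    d1 <- pairs[1, k]; d2 <- pairs[2, k]
    s <- sub[sub$day %in% c(d1, d2), , drop = FALSE]
    gate <- .normalityGate(s$value, s$day)
    v <- gate$values
    tt <- stats::t.test(v[s$day == d1], v[s$day == d2])
    data.frame(day1 = d1, day2 = d2, transformed = gate$transformed,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  list(metric = metric, line = line, region = region,
       dayMeans = dayMeans, pairwise = pw)
}
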