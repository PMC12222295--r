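#' Published calibration table of the nucleus-area activity states
#'
#' The reference training set behind the activity-state classifier: 197
#' microglia visually categorised into the four activity states, with
#' per-state mean relative nucleus area (percent of total image area)
#' and two-sided 95\% confidence interval of the mean.
#'
#' @return data.frame with columns \code{label}, \code{n}, \code{mean},
#'   \code{ci_low}, \code{ci_high}.
#' @examples
#' sum(referenceNucleusAreaStates()$n)  # 197 categorised cells
#' @export
referenceNucleusAreaStates <- function() {
  data.frame(
    label = c("ramified", "hyper_ramified", "bushy", "amoeboid"),
    n = c(14L, 102L, 68L, 13L),
    mean = c(0.20, 0.16, 0.41, 0.70),
    ci_low = c(0.15, 0.15, 0.39, 0.59),
    ci_high = c(0.25, 0.18, 0.44, 0.81),
    stringsAsFactors = FALSE)
}

#' Fit per-state nucleus-area intervals
#'
#' For each labelled activity state, computes the sample size, mean
#' relative nucleus area and the two-sided t-based 95\% confidence
#' interval of the mean (mean +/- t[0.975, n-1] * s / sqrt(n)).
#'
#' @param relArea numeric per-cell relative nucleus areas (percent of
#'   image area).
#' @param state character activity-state label per cell.
#' @param conf confidence level (default 0.95).
#' @return data.frame (label, n, mean, ci_low, ci_high) ordered by mean.
#' @export
fitStateIntervals <- function(relArea, state, conf = 0.95) {
  if (length(relArea) != length(state))
    stop("relArea and state must have equal length")
  if (any(!is.finite(relArea))) stop("relArea must be finite")
  lv <- unique(state)
  ns <- table(state)
  if (any(ns < 2L))
    stop("each state needs at least 2 samples (violated by: ",
         paste(names(ns)[ns < 2L], collapse = ", "), ")")
  out <- do.call(rbind, lapply(lv, function(s) {
    v <- relArea[state == s]
    n <- length(v)
    m <- mean(v)
    half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n)
    data.frame(label = s, n = n, mean = m, ci_low = m - half,
               ci_high = m + half, stringsAsFactors = FALSE)
  }))
  out[order(out$mean), , drop = FALSE]
}

#' Merge activity states with overlapping confidence intervals
#'
#' States whose confidence intervals overlap are merged into one group
#' (transitive closure of pairwise overlap); each merged group spans the
#' union of its members' intervals, and decision boundaries between
#' adjacent groups sit at the midpoint of the inter-interval gap. With
#' the published calibration table this yields three groups: ramified
#' merged with hyper-ramified, bushy, and amoeboid.
#'
#' @param states data.frame as returned by
#'   \code{\link{fitStateIntervals}} or
#'   \code{\link{referenceNucleusAreaStates}}.
#' @return a \code{\linkS4class{MergedClassifier}}.
#' @examples
#' cls <- mergeOverlapping(referenceNucleusAreaStates())
#' nrow(activityGroups(cls))  # 3
#' @export
mergeOverlapping <- function(states) {
  if (nrow(states) == 0L) stop("need at least one state")
  st <- states[order(states$mean), , drop = FALSE]
  k <- nrow(st)
  grp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (grp[i] != grp[j] &&
          st$ci_low[i] <= st$ci_high[j] && st$ci_low[j] <= st$ci_high[i]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  gids <- unique(grp)
  groups <- do.call(rbind, lapply(gids, function(g) {
    sel <- st[grp == g, , drop = FALSE]
    data.frame(label = paste(sel$label, collapse = "+"),
               members = I(list(sel$label)),
               low = min(sel$ci_low), high = max(sel$ci_high),
               n = sum(sel$n), stringsAsFactors = FALSE)
  }))
  groups <- groups[order(groups$low), , drop = FALSE]
  rownames(groups) <- NULL
  ng <- nrow(groups)
  boundaries <- if (ng > 1L)
    (groups$high[-ng] + groups$low[-1L]) / 2 else numeric(0)
  new("MergedClassifier", states = st, groups = groups,
      boundaries = boundaries)
}

#' Accessors for MergedClassifier objects
#'
#' @param x a \code{\linkS4class{MergedClassifier}}.
#' @name MergedClassifier-accessors
#' @aliases activityGroups decisionBoundaries
NULL

#' @rdname MergedClassifier-accessors
setMethod("activityGroups", "MergedClassifier", function(x) x@groups)

#' @rdname MergedClassifier-accessors
setMethod("decisionBoundaries", "MergedClassifier",
          function(x) x@boundaries)

setMethod("show", "MergedClassifier", function(object) {
  g <- object@groups
  cat(sprintf("MergedClassifier: %d state(s) -> %d group(s)\n",
              nrow(object@states), nrow(g)))
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-28s [%.3f, %.3f]  n = %d\n", g$label[i], g$low[i],
                g$high[i], g$n[i]))
  if (length(object@boundaries))
    cat("boundaries:", paste(sprintf("%.3f", object@boundaries),
                             collapse = ", "), "\n")
})

#' Classify a cell into a merged activity group
#'
#' A total, monotone step function of the relative nucleus area: values
#' inside a group interval map to that group; values in a gap go to the
#' nearer boundary's group, a value exactly on a boundary to the lower
#' group; values beyond the extreme intervals clamp to the end groups.
#'
#' @param relArea numeric relative nucleus area(s), percent of image
#'   area; must be finite.
#' @param classifier a \code{\linkS4class{MergedClassifier}}.
#' @return character vector of merged-group labels.
#' @examples
#' cls <- mergeOverlapping(referenceNucleusAreaStates())
#' classifyCell(c(0.70, 0.41), cls)
#' @export
classifyCell <- function(relArea, classifier) {
  if (any(!is.finite(relArea))) stop("relArea must be finite")
  b <- classifier@boundaries
  idx <- 1L + vapply(relArea, function(v) sum(v > b), numeric(1))
  classifier@groups$label[idx]
}

#' Nonparametric validation of state separation
#'
#' Kruskal-Wallis test over all states followed by all pairwise
#' rank-sum (Wilcoxon) comparisons, reported with unadjusted and
#' Holm-adjusted p-values.
#'
#' @param relArea numeric per-cell relative nucleus areas.
#' @param state character state label per cell; at least two states with
#'   at least two samples each.
#' @return list with \code{kruskal} (statistic, df, p.value) and
#'   \code{pairwise} (data.frame: state1, state2, W, p, p_holm).
#' @export
validateSeparation <- function(relArea, state) {
  ns <- table(state)
  if (length(ns) < 2L || any(ns < 2L))
    stop("need >= 2 states with >= 2 samples each")
  if (length(unique(relArea)) == 1L)
    stop("degenerate data: all values tied")
  kw <- stats::kruskal.test(relArea, factor(state))
  lv <- names(ns)
  pairs <- utils::combn(lv, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- relArea[state == pairs[1, k]]
    b <- relArea[state == pairs[2, k]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(state1 = pairs[1, k], state2 = pairs[2, k],
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       pairwise = pw)
}

#' Serialise a merged classifier to JSON
#'
#' @param classifier a \code{\linkS4class{MergedClassifier}}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
classifierToJSON <- function(classifier, path = NULL) {
  obj <- list(
    states = classifier@states,
    groups = data.frame(label = classifier@groups$label,
                        low = classifier@groups$low,
                        high = classifier@groups$high,
                        n = classifier@groups$n),
    boundaries = classifier@boundaries)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a merged classifier from JSON
#'
#' @param path file path or JSON string produced by
#'   \code{\link{classifierToJSON}}.
#' @return a \code{\linkS4class{MergedClassifier}}.
#' @export
classifierFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  groups <- obj$groups
  groups$members <- I(lapply(strsplit(groups$label, "+", fixed = TRUE),
                             identity))
  groups <- groups[, c("label", "members", "low", "high", "n")]
  new("MergedClassifier", states = obj$states, groups = groups,
      boundaries = as.numeric(obj$boundaries))
}

#' Flag rod-shaped cells
#'
#' Rod cells are not part of the activity-state label set; they are
#' flagged as metadata via the eccentricity of the nucleus pixel set
#' (eccentricity > threshold).
#'
#' @param pixels 2-column (row, col) nucleus pixel matrix.
#' @param threshold eccentricity threshold (default 0.95).
#' @return logical.
#' @export
isRodCandidate <- function(pixels, threshold = 0.95) {
  if (nrow(pixels) < 3L) return(FALSE)
  cv <- stats::cov(pixels)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1L] <= 0) return(FALSE)
  ecc <- sqrt(1 - ev[2L] / ev[1L])
  is.finite(ecc) && ecc > threshold
}
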