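# --- rasterisation helpers (row/col pixel coordinates, 1-based) ---------

.diskIdx <- function(centre, r, dm) {
  rr <- max(1L, floor(centre[1L] - r)):min(dm[1L], ceiling(centre[1L] + r))
  cc <- max(1L, floor(centre[2L] - r)):min(dm[2L], ceiling(centre[2L] + r))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - centre[1L])^2 + (g$col - centre[2L])^2 <= r^2
  (g$col[keep] - 1L) * dm[1L] + g$row[keep]
}

.annulusIdx <- function(centre, r0, r1, dm) {
  rr <- max(1L, floor(centre[1L] - r1)):min(dm[1L], ceiling(centre[1L] + r1))
  cc <- max(1L, floor(centre[2L] - r1)):min(dm[2L], ceiling(centre[2L] + r1))
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - centre[1L])^2 + (g$col - centre[2L])^2
  keep <- d2 > r0^2 & d2 <= r1^2
  (g$col[keep] - 1L) * dm[1L] + g$row[keep]
}

# straight radial arm: rectangle from radius rIn to rIn + len along
# direction `angle`, full width `width`
.armIdx <- function(centre, rIn, len, width, angle, dm) {
  u <- c(cos(angle), sin(angle))
  reach <- rIn + len + width
  rr <- max(1L, floor(centre[1L] - reach)):min(dm[1L], ceiling(centre[1L] + reach))
  cc <- max(1L, floor(centre[2L] - reach)):min(dm[2L], ceiling(centre[2L] + reach))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - centre[1L]; dc <- g$col - centre[2L]
  t <- dr * u[1L] + dc * u[2L]
  s <- -dr * u[2L] + dc * u[1L]
  keep <- t >= rIn & t <= rIn + len & abs(s) <= width / 2
  (g$col[keep] - 1L) * dm[1L] + g$row[keep]
}

# persistent random-walk filament; returns linear indices
.filamentIdx <- function(dm, nSteps = 300L, turnSd = 0.25, width = 2L) {
  p <- c(stats::runif(1, 1, dm[1L]), stats::runif(1, 1, dm[2L]))
  ang <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, nSteps, 2L)
  for (k in seq_len(nSteps)) {
    ang <- ang + stats::rnorm(1, 0, turnSd)
    p <- p + c(cos(ang), sin(ang))
    if (p[1L] < 1 || p[1L] > dm[1L] || p[2L] < 1 || p[2L] > dm[2L]) break
    pts[k, ] <- p
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) == 0L) return(integer(0))
  idx <- integer(0)
  for (dr in 0:(width - 1L)) for (dc in 0:(width - 1L)) {
    r <- pmin(pmax(round(pts[, 1L]) + dr, 1L), dm[1L])
    c <- pmin(pmax(round(pts[, 2L]) + dc, 1L), dm[2L])
    idx <- c(idx, (c - 1L) * dm[1L] + r)
  }
  unique(idx)
}

# straight tract crossing the whole image at orientation `angle` with a
# perpendicular offset, thickness 2 px
.tractIdx <- function(dm, angle, offset, width = 2L) {
  diag <- sqrt(sum(dm^2))
  t <- seq(-diag, diag, by = 0.5)
  ctr <- dm / 2
  u <- c(cos(angle), sin(angle))
  v <- c(-sin(angle), cos(angle))
  r <- ctr[1L] + t * u[1L] + offset * v[1L]
  c <- ctr[2L] + t * u[2L] + offset * v[2L]
  idx <- integer(0)
  for (dw in seq(0, width - 1L)) {
    rr <- round(r + dw * v[1L]); cc <- round(c + dw * v[2L])
    keep <- rr >= 1L & rr <= dm[1L] & cc >= 1L & cc <= dm[2L]
    idx <- c(idx, (cc[keep] - 1L) * dm[1L] + rr[keep])
  }
  unique(idx)
}

# --- class-conditional nucleus-area parameters ---------------------------

#' Class-conditional nucleus-area distribution parameters
#'
#' Normal distribution parameters for the relative nucleus area (percent
#' of image area) of each activity state, taken from the published
#' calibration table; the standard deviation is back-computed from the
#' printed confidence half-width: s = sqrt(n) * (ci_high - mean) /
#' t[0.975, n-1].
#'
#' @return data.frame with columns \code{label}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
classAreaParameters <- function() {
  ref <- referenceNucleusAreaStates()
  sd <- sqrt(ref$n) * (ref$ci_high - ref$mean) /
    stats::qt(0.975, ref$n - 1)
  data.frame(label = ref$label, mean = ref$mean, sd = sd, n = ref$n,
             stringsAsFactors = FALSE)
}

# default arm-count means per class (processes get fewer with activation)
.CLASS_ARMS <- c(ramified = 5, hyper_ramified = 6, bushy = 3, amoeboid = 1)

# --- scene specification --------------------------------------------------

#' Specify a synthetic scene
#'
#' Builds a \code{\linkS4class{SceneSpec}}. Cells may be given fully
#' (explicit positions, areas and arm counts), partially, or just as a
#' vector of class labels; anything missing is sampled at generation
#' time from the class-conditional distributions, deterministically
#' under the spec's seed.
#'
#' @param dim image shape (rows, cols), default c(512, 512).
#' @param seed integer RNG seed.
#' @param classes character vector of activity-state labels, one cell
#'   each (ignored when \code{cells} is given).
#' @param cells optional data.frame of per-cell parameters (see
#'   \code{\linkS4class{SceneSpec}}).
#' @param nAstrocyteFilaments,nNeuriteTracts counts of astrocyte
#'   filaments and neurite tracts.
#' @param neuriteDispersion orientation dispersion (radians) of the
#'   tracts; 0 renders perfectly parallel tracts.
#' @param noiseSd Gaussian noise sd as a fraction of the dynamic range
#'   (default 0.05).
#' @param poissonNoise add Poisson shot noise (default FALSE).
#' @param background background level (default 0.05).
#' @param somaAnnulusPx width of the bright soma rim around each nucleus
#'   (default 3).
#' @param minSeparationPx minimum centre-to-centre distance between
#'   cells; \code{NA} (default) derives it from the soma radii so that
#'   somata never overlap.
#' @return a \code{\linkS4class{SceneSpec}}.
#' @export
sceneSpec <- function(dim = c(512L, 512L), seed = 1L, classes = character(0),
                      cells = NULL, nAstrocyteFilaments = 0L,
                      nNeuriteTracts = 0L, neuriteDispersion = 0.1,
                      noiseSd = 0.05, poissonNoise = FALSE,
                      background = 0.05, somaAnnulusPx = 3L,
                      minSeparationPx = NA_real_) {
  if (is.null(cells)) {
    cells <- if (length(classes))
      data.frame(class = as.character(classes), stringsAsFactors = FALSE)
    else data.frame(class = character(0), stringsAsFactors = FALSE)
  }
  new("SceneSpec", dim = as.integer(dim), seed = as.integer(seed),
      cells = cells, nAstrocyteFilaments = as.integer(nAstrocyteFilaments),
      nNeuriteTracts = as.integer(nNeuriteTracts),
      neuriteDispersion = neuriteDispersion, noiseSd = noiseSd,
      poissonNoise = poissonNoise, background = background,
      somaAnnulusPx = as.integer(somaAnnulusPx),
      minSeparationPx = minSeparationPx)
}

.col <- function(cells, name, default) {
  if (name %in% names(cells)) {
    v <- cells[[name]]
    ifelse(is.na(v), default, v)
  } else rep(default, nrow(cells))
}

# --- scene generation -----------------------------------------------------

#' Render a synthetic multi-channel scene with planted ground truth
#'
#' Renders the four channels of a fluorescence scene: the nucleus
#' channel holds rasterised disks; the microglia channel a bright soma
#' annulus around each nucleus (guaranteeing the green border the
#' detection criterion requires) plus straight radial arms at jittered,
#' minimum-separated angles so the ring-crossing count is analytically
#' known; the astrocyte channel persistent random-walk filaments; and
#' the neurofilament channel parallel tracts whose orientation scatter
#' is set by the dispersion parameter. Gaussian (optionally Poisson)
#' noise is applied last; all ground truth is recorded pre-noise.
#' Identical spec and seed give bit-identical scenes.
#'
#' @param spec a \code{\linkS4class{SceneSpec}}.
#' @param armLengthPx default radial arm length beyond the soma
#'   (default 35, long enough to fully cross the default counting ring).
#' @param armWidthPx default arm thickness (default 3).
#' @return a \code{\linkS4class{SyntheticScene}}.
#' @export
generateScene <- function(spec, armLengthPx = 35, armWidthPx = 3) {
  set.seed(spec@seed)
  dm <- spec@dim
  A <- prod(dm)
  pars <- classAreaParameters()
  cells <- spec@cells
  n <- nrow(cells)

  if (n > 0L) {
    cls <- as.character(cells$class)
    bad <- setdiff(unique(cls), pars$label)
    if (length(bad)) stop("unknown activity class: ",
                          paste(bad, collapse = ", "))
    rel <- .col(cells, "rel_area_pct", NA_real_)
    for (i in seq_len(n)) if (is.na(rel[i])) {
      p <- pars[pars$label == cls[i], ]
      repeat {
        v <- stats::rnorm(1, p$mean, p$sd)
        if (v >= 0.02) break
      }
      rel[i] <- v
    }
    radius <- sqrt(rel / 100 * A / pi)
    armN <- .col(cells, "arms", NA_real_)
    for (i in seq_len(n)) if (is.na(armN[i]))
      armN[i] <- stats::rpois(1, .CLASS_ARMS[[cls[i]]])
    armLen <- .col(cells, "arm_length_px", armLengthPx)
    armWid <- .col(cells, "arm_width_px", armWidthPx)
    ann <- spec@somaAnnulusPx

    # placement: explicit positions, or dart throwing with a margin that
    # keeps each nucleus, soma rim and counting ring inside the image
    rows <- .col(cells, "row", NA_real_)
    cols <- .col(cells, "col", NA_real_)
    minSep <- spec@minSeparationPx
    margin <- radius + ann + 25
    for (i in seq_len(n)) if (is.na(rows[i])) {
      if (dm[1L] - 2 * margin[i] < 1 || dm[2L] - 2 * margin[i] < 1)
        stop("infeasible geometry: cell does not fit inside the image")
      ok <- FALSE
      for (try in seq_len(8000L)) {
        cand <- c(stats::runif(1, 1 + margin[i], dm[1L] - margin[i]),
                  stats::runif(1, 1 + margin[i], dm[2L] - margin[i]))
        prev <- which(!is.na(rows[seq_len(i - 1L)]))
        # pair-specific default separation: somata (incl. rim) must not touch
        sep <- if (is.na(minSep))
          radius[i] + radius[prev] + 2 * ann + 2 else rep(minSep, length(prev))
        if (!length(prev) ||
            all((rows[prev] - cand[1L])^2 + (cols[prev] - cand[2L])^2 >=
                sep^2)) {
          rows[i] <- cand[1L]; cols[i] <- cand[2L]; ok <- TRUE; break
        }
      }
      if (!ok) stop("infeasible geometry: could not place ", n,
                    " non-overlapping cells in a ", dm[1L], " x ", dm[2L],
                    " image")
    }
  }

  channels <- c("nucleus", "microglia", "astrocyte", "neurofilament")
  truth <- stats::setNames(lapply(channels, function(ch)
    matrix(0L, dm[1L], dm[2L])), channels)
  units <- list()
  cellRows <- list()

  if (n > 0L) for (i in seq_len(n)) {
    ctr <- c(rows[i], cols[i])
    nucIdx <- .diskIdx(ctr, radius[i], dm)
    somaIdx <- .annulusIdx(ctr, radius[i], radius[i] + spec@somaAnnulusPx, dm)
    k <- armN[i]
    armsIdx <- integer(0)
    if (k > 0) {
      base <- 2 * pi * (seq_len(k) - 1L) / k + stats::runif(1, 0, 2 * pi)
      jit <- min(0.25 * 2 * pi / k, 0.3)
      angles <- base + stats::runif(k, -jit, jit)
      for (a in angles)
        armsIdx <- c(armsIdx, .armIdx(ctr, radius[i] + 1, armLen[i],
                                      armWid[i], a, dm))
      armsIdx <- unique(armsIdx)
    }
    glVal <- unique(c(somaIdx, armsIdx))
    truth$nucleus[nucIdx] <- 1L
    truth$microglia[glVal] <- 1L
    units[[length(units) + 1L]] <- list(
      id = sprintf("cell%d", i),
      parts = list(list(channel = "nucleus", idx = nucIdx, intensity = 0.9),
                   list(channel = "microglia", idx = glVal,
                        intensity = 0.85)))
    cellRows[[i]] <- data.frame(
      id = i, row = ctr[1L], col = ctr[2L], radius = radius[i],
      nucleus_area_px = length(nucIdx),
      rel_area_pct = 100 * length(nucIdx) / A,
      planted_rel_area_pct = rel[i], arms = as.integer(k),
      class = cls[i], stringsAsFactors = FALSE)
  }

  if (spec@nAstrocyteFilaments > 0L)
    for (j in seq_len(spec@nAstrocyteFilaments)) {
      idx <- .filamentIdx(dm)
      if (!length(idx)) next
      truth$astrocyte[idx] <- 1L
      units[[length(units) + 1L]] <- list(
        id = sprintf("astro%d", j),
        parts = list(list(channel = "astrocyte", idx = idx,
                          intensity = 0.8)))
    }

  if (spec@nNeuriteTracts > 0L) {
    theta0 <- stats::runif(1, 0, pi)
    offsets <- seq(-0.4, 0.4, length.out = spec@nNeuriteTracts) *
      min(dm) + stats::rnorm(spec@nNeuriteTracts, 0, 2)
    for (j in seq_len(spec@nNeuriteTracts)) {
      ang <- theta0 + stats::rnorm(1, 0, spec@neuriteDispersion)
      idx <- .tractIdx(dm, ang, offsets[j])
      if (!length(idx)) next
      truth$neurofilament[idx] <- 1L
      units[[length(units) + 1L]] <- list(
        id = sprintf("neuro%d", j),
        parts = list(list(channel = "neurofilament", idx = idx,
                          intensity = 0.8)))
    }
  }

  noiseFree <- stats::setNames(lapply(channels, function(ch)
    matrix(spec@background, dm[1L], dm[2L])), channels)
  for (u in units) for (p in u$parts)
    noiseFree[[p$channel]][p$idx] <- pmax(noiseFree[[p$channel]][p$idx],
                                          p$intensity)

  noisy <- lapply(noiseFree, function(m) {
    if (spec@noiseSd > 0)
      m <- m + stats::rnorm(length(m), 0, spec@noiseSd)
    if (spec@poissonNoise)
      m <- stats::rpois(length(m), pmax(m, 0) * 100) / 100
    matrix(pmin(pmax(m, 0), 1), dm[1L], dm[2L])
  })

  cellsOut <- if (length(cellRows)) do.call(rbind, cellRows) else
    data.frame(id = integer(0), row = numeric(0), col = numeric(0),
               radius = numeric(0), nucleus_area_px = integer(0),
               rel_area_pct = numeric(0), planted_rel_area_pct = numeric(0),
               arms = integer(0), class = character(0),
               stringsAsFactors = FALSE)

  new("SyntheticScene",
      projection = Projection(noisy),
      truthRasters = truth, cells = cellsOut, spec = spec,
      entities = list(units = units, noiseFree = noiseFree))
}

setMethod("show", "SyntheticScene", function(object) {
  d <- object@spec@dim
  cat(sprintf(
    "SyntheticScene: %d x %d px, %d cell(s), %d filament(s), %d tract(s), seed %d\n",
    d[1L], d[2L], nrow(object@cells), object@spec@nAstrocyteFilaments,
    object@spec@nNeuriteTracts, object@spec@seed))
})

#' Noise-free rendering of a synthetic scene
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @return a \code{\linkS4class{Projection}} of the pre-noise channels.
#' @export
noiseFreeProjection <- function(scene)
  Projection(scene@entities$noiseFree)

#' Ground-truth binary raster of one channel
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param channel channel label.
#' @return a \code{\linkS4class{SegmentationMask}} of the planted
#'   objects (pre-noise).
#' @export
truthMask <- function(scene, channel)
  SegmentationMask(scene@truthRasters[[channel]], channel = channel)

#' Ground-truth cell table of a synthetic scene
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @return data.frame of per-cell planted truth.
#' @export
truthCells <- function(scene) scene@cells

# --- Z-stack rendering ----------------------------------------------------

#' Render a synthetic scene as a Z-stack
#'
#' Distributes the scene's structures over Z planes: each unit (cell,
#' filament, tract) receives a Gaussian axial intensity profile centred
#' on a randomly drawn plane, with the peak exactly on that plane, so
#' the maximum-intensity projection of the stack reproduces the
#' noise-free 2-D scene up to quantisation. The draw is seeded from the
#' scene's seed, so rendering is deterministic.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param nPlanes number of planes (>= 1, default 30).
#' @param spacingUm plane spacing along Z in micrometres (default 0.24).
#' @param axialSigmaPlanes sd of the axial profile in planes (default 2).
#' @return a \code{\linkS4class{ChannelStack}}.
#' @export
renderZstack <- function(scene, nPlanes = 30L, spacingUm = 0.24,
                         axialSigmaPlanes = 2) {
  nPlanes <- as.integer(nPlanes)
  if (nPlanes < 1L) stop("nPlanes must be >= 1")
  if (!is.finite(spacingUm) || spacingUm <= 0)
    stop("spacingUm must be positive")
  dm <- scene@spec@dim
  units <- scene@entities$units
  set.seed((scene@spec@seed %% 1000000000L) + 10007L)
  zc <- if (length(units))
    sample.int(nPlanes, length(units), replace = TRUE) else integer(0)
  channels <- names(scene@entities$noiseFree)
  bg <- scene@spec@background
  stack <- stats::setNames(lapply(channels, function(ch)
    array(bg, c(dm[1L], dm[2L], nPlanes))), channels)
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    w <- exp(-((seq_len(nPlanes) - zc[ui])^2) / (2 * axialSigmaPlanes^2))
    for (p in u$parts) for (z in seq_len(nPlanes)) {
      v <- p$intensity * w[z]
      if (v <= bg) next
      pl <- stack[[p$channel]][, , z]
      pl[p$idx] <- pmax(pl[p$idx], v)
      stack[[p$channel]][, , z] <- pl
    }
  }
  ChannelStack(stack, planeSpacingUm = spacingUm,
               maxPlanes = max(30L, nPlanes))
}

# --- study-level generation ----------------------------------------------

#' Generate a synthetic study with planted group effects
#'
#' Emulates the reference study design -- two mouse lines, fixation days
#' in culture, one hippocampal region, up to 9 mice per cell -- by
#' sampling, per image, a cell population from the class-conditional
#' mixtures, with per-mouse lognormal random effects and multiplicative
#' planted effects on the second line. Per-image metrics
#' (\code{microglia_count}, \code{process_count},
#' \code{rel_nucleus_area}) are derived from the planted truth; scene
#' specifications are returned so any image can additionally be rendered
#' with \code{\link{generateScene}}.
#'
#' @param lines character(2), mouse-line labels; effects apply to the
#'   second one.
#' @param days integer vector of fixation days.
#' @param nMice mice per line and day (capped at 9, the reference
#'   design's maximum).
#' @param imagesPerMouse images per mouse (default 3).
#' @param region region label (default "CA3").
#' @param effects list of multiplicative planted effects on the second
#'   line: \code{armCountRatio}, \code{cellCountRatio},
#'   \code{nucleusAreaRatio} (default 1 = no effect).
#' @param meanCellsPerImage expected microglia per image (default 8).
#' @param mouseEffectSd sd of the lognormal per-mouse random effect
#'   (default 0.1).
#' @param classMix mixing proportions over activity states (default: the
#'   calibration table's frequencies).
#' @param seed integer RNG seed.
#' @param sceneDim image shape for the per-image scene specs.
#' @param render when TRUE, every image's scene is rendered (slow); the
#'   scenes are returned alongside the frame.
#' @return list: \code{frame} (a \code{\link{studyFrame}} of per-image
#'   metrics), \code{truth} (per-image truth summaries), \code{specs}
#'   (list of \code{\linkS4class{SceneSpec}}), \code{scenes} (list of
#'   rendered scenes, when \code{render = TRUE}).
#' @export
generateStudy <- function(lines = c("wild_type", "tnf_overexpressing"),
                          days = c(3L, 7L, 14L), nMice = 5L,
                          imagesPerMouse = 3L, region = "CA3",
                          effects = list(), meanCellsPerImage = 8,
                          mouseEffectSd = 0.1, classMix = NULL,
                          seed = 1L, sceneDim = c(256L, 256L),
                          render = FALSE) {
  if (length(lines) != 2L) stop("need exactly two mouse lines")
  if (length(days) < 1L || nMice < 1L || imagesPerMouse < 1L)
    stop("empty design")
  nMice <- min(as.integer(nMice), 9L)
  eff <- utils::modifyList(list(armCountRatio = 1, cellCountRatio = 1,
                                nucleusAreaRatio = 1), effects)
  pars <- classAreaParameters()
  if (is.null(classMix)) classMix <- pars$n / sum(pars$n)
  set.seed(seed)
  rows <- list(); truthRows <- list(); specs <- list(); scenes <- list()
  img <- 0L
  for (li in seq_along(lines)) for (d in days) for (m in seq_len(nMice)) {
    mouseId <- sprintf("%s_m%02d", substr(lines[li], 1, 2), m)
    mult <- exp(stats::rnorm(3, 0, mouseEffectSd))   # mouse random effects
    for (k in seq_len(imagesPerMouse)) {
      img <- img + 1L
      lam <- meanCellsPerImage * mult[1L] *
        if (li == 2L) eff$cellCountRatio else 1
      nc <- max(1L, stats::rpois(1, lam))
      cls <- sample(pars$label, nc, replace = TRUE, prob = classMix)
      armMean <- .CLASS_ARMS[cls] * mult[2L] *
        if (li == 2L) eff$armCountRatio else 1
      arms <- stats::rpois(nc, armMean)
      relArea <- numeric(nc)
      for (i in seq_len(nc)) {
        p <- pars[pars$label == cls[i], ]
        sc <- mult[3L] * if (li == 2L) eff$nucleusAreaRatio else 1
        repeat {
          v <- stats::rnorm(1, p$mean * sc, p$sd * sc)
          if (v >= 0.02) break
        }
        relArea[i] <- v
      }
      specSeed <- sample.int(.Machine$integer.max - 1L, 1L)
      sp <- sceneSpec(dim = sceneDim, seed = specSeed,
                      cells = data.frame(class = cls, arms = arms,
                                         rel_area_pct = relArea,
                                         stringsAsFactors = FALSE))
      specs[[img]] <- sp
      if (render) scenes[[img]] <- generateScene(sp)
      truthRows[[img]] <- data.frame(
        image = img, mouse = mouseId, line = lines[li], day = d,
        region = region, n_cells = nc, mean_arms = mean(arms),
        mean_rel_area = mean(relArea), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- studyFrame(
        mouse = rep(mouseId, 3), line = rep(lines[li], 3),
        day = rep(d, 3), region = rep(region, 3),
        metric = c("microglia_count", "process_count",
                   "rel_nucleus_area"),
        value = c(nc, mean(arms), mean(relArea)))
    }
  }
  frame <- do.call(rbind, rows)
  class(frame) <- c("studyFrame", "data.frame")
  list(frame = frame, truth = do.call(rbind, truthRows), specs = specs,
       scenes = if (render) scenes else NULL)
}
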