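## Synthetic paired IMS/MxIF data with planted ground truth.
##
## The generator emulates the study design downstream stages are built for:
## a field of glomeruli imaged by fine-pitch MxIF (1 um) and coarser-pitch
## picked-peak lipid IMS (5 um) on the same section, with a small affine
## misalignment between the frames, multiplicative lognormal fluorescence
## noise, scaled-Poisson ion-count noise, partial-volume mixing of cell-type
## lipid profiles inside each IMS footprint, one planted discriminative
## lipid marker per cell type, and a deep/superficial covariate that
## multiplicatively shifts a few features in deep glomeruli.

#' Canonical cell types of the synthetic glomerulus
#' @return character vector (level order used by cell maps).
#' @export
cellTypeLevels <- function()
  c("background", "podocyte", "mesangial", "endothelial",
    "basement_membrane", "other_substructure")

#' Generate a synthetic glomerular layout and ROI mask
#'
#' Glomeruli are discs on a jittered grid: a thin outer basement-membrane
#' ring, a peripheral podocyte band, and an interior split between mesangial
#' lobules (seeded random blobs) and endothelial capillary annuli around
#' open lumina; remaining interior pixels are unspecific substructure. Each
#' glomerulus gets an ROI disc slightly larger than the tuft (so measurement
#' regions include a rim of background) and a depth class drawn to match
#' `depthFractions`.
#'
#' @param nGlomeruli number of glomeruli (>= 1).
#' @param radiusUm tuft radius in micrometres (default 60).
#' @param pitchUm cell-map pitch in micrometres (default 1).
#' @param depthFractions named numeric, fractions for `deep` and
#'   `superficial` (largest-remainder rounding; 0.5/0.5 over 60 glomeruli
#'   gives exactly 30 + 30).
#' @param seed integer seed.
#' @param roiMarginUm ROI radius margin beyond the tuft (default 5).
#' @return list with `cellMap` (integer matrix, values index
#'   [cellTypeLevels()]) and `roi` (an [ROIMask-class]).
#' @export
generateLayout <- function(nGlomeruli, radiusUm = 60, pitchUm = 1,
                           depthFractions = c(deep = 0.5, superficial = 0.5),
                           seed = 1, roiMarginUm = 5) {
  stopifnot(nGlomeruli >= 1)
  if (radiusUm <= 3 * pitchUm)
    stop("radius_um must exceed 3x the cell-map pitch", call. = FALSE)
  gbmT <- 4; podT <- 12
  innerR <- radiusUm - gbmT - podT
  if (innerR < 18)
    stop("radius too small to fit all subglomerular zones", call. = FALSE)
  margin <- roiMarginUm; spacing <- 8
  cellUm <- 2 * (radiusUm + margin) + spacing
  ncols <- ceiling(sqrt(nGlomeruli))
  nrows <- ceiling(nGlomeruli / ncols)
  H <- as.integer(round(nrows * cellUm / pitchUm))
  W <- as.integer(round(ncols * cellUm / pitchUm))
  lv <- cellTypeLevels()
  code <- setNames(seq_along(lv), lv)
  cellMap <- matrix(code[["background"]], H, W)
  roiLab <- matrix(0L, H, W)
  withr::with_seed(seed, {
    for (g in seq_len(nGlomeruli)) {
      gi <- (g - 1L) %/% ncols; gj <- (g - 1L) %% ncols
      cx <- (gj + 0.5) * cellUm + runif(1, -4, 4)
      cy <- (gi + 0.5) * cellUm + runif(1, -4, 4)
      ## interior features (physical um, relative to glomerulus center)
      nCap <- 4L
      capAng <- runif(nCap, 0, 2 * pi)
      capR <- 0.55 * innerR
      capX <- cx + capR * cos(capAng); capY <- cy + capR * sin(capAng)
      lumenR <- 4; endoT <- 4
      nLob <- 3L
      lobAng <- runif(nLob, 0, 2 * pi)
      lobX <- cx + 0.35 * innerR * cos(lobAng)
      lobY <- cy + 0.35 * innerR * sin(lobAng)
      lobRad <- runif(nLob, 8, 12)
      ## raster over the bounding box of the ROI disc
      rext <- radiusUm + margin
      c0 <- max(0L, floor((cx - rext) / pitchUm))
      c1 <- min(W - 1L, ceiling((cx + rext) / pitchUm))
      r0 <- max(0L, floor((cy - rext) / pitchUm))
      r1 <- min(H - 1L, ceiling((cy + rext) / pitchUm))
      cols <- c0:c1; rows <- r0:r1
      px <- (cols + 0.5) * pitchUm; py <- (rows + 0.5) * pitchUm
      dx <- outer(rep(1, length(rows)), px - cx)
      dy <- outer(py - cy, rep(1, length(cols)))
      rr <- sqrt(dx^2 + dy^2)
      sub <- cellMap[rows + 1L, cols + 1L]
      inRoi <- rr <= rext
      roiSub <- roiLab[rows + 1L, cols + 1L]
      roiSub[inRoi] <- g
      roiLab[rows + 1L, cols + 1L] <- roiSub
      sub[rr <= radiusUm] <- code[["other_substructure"]]
      ## interior: mesangial lobules, then endothelial annuli + open lumina
      interior <- rr <= innerR
      for (l in seq_len(nLob)) {
        dl <- sqrt((dx + cx - lobX[l])^2 + (dy + cy - lobY[l])^2)
        sub[interior & dl <= lobRad[l]] <- code[["mesangial"]]
      }
      for (cp in seq_len(nCap)) {
        dc <- sqrt((dx + cx - capX[cp])^2 + (dy + cy - capY[cp])^2)
        sub[interior & dc <= lumenR + endoT] <- code[["endothelial"]]
        sub[interior & dc <= lumenR] <- code[["other_substructure"]]
      }
      ## peripheral bands override interior structures
      sub[rr > innerR & rr <= innerR + podT] <- code[["podocyte"]]
      sub[rr > innerR + podT & rr <= radiusUm] <- code[["basement_membrane"]]
      cellMap[rows + 1L, cols + 1L] <- sub
    }
  })
  ## depth classes by largest-remainder rounding, seeded assignment order
  fr <- depthFractions / sum(depthFractions)
  nDeep <- floor(fr[["deep"]] * nGlomeruli)
  if ((fr[["deep"]] * nGlomeruli - nDeep) >= 0.5) nDeep <- nDeep + 1L
  ord <- withr::with_seed(seed + 1L, sample.int(nGlomeruli))
  depth <- data.frame(
    roi_id = seq_len(nGlomeruli),
    depth_class = ifelse(seq_len(nGlomeruli) %in% ord[seq_len(nDeep)],
                         "deep", "superficial"))
  list(cellMap = cellMap,
       roi = ROIMask(roiLab, pitchUm = pitchUm, originUm = c(0, 0),
                     depth = depth))
}

#' Default cell-type mean fluorescence matrix for the packaged panel
#'
#' Mean channel intensities (arbitrary fluorescence units) per canonical
#' cell type, in the channel order of [glomerularPanel()]: podocytes bright
#' in podocalyxin/synaptopodin/nestin, mesangial cells in tensin/
#' fibronectin/collagen IV a1-2, endothelium in CD31, basement membrane in
#' collagen IV a5 with moderate matrix signal, unspecific substructure a
#' uniform autofluorescence-like floor, background near-dark.
#'
#' @return numeric matrix `6 cell types x 10 channels`.
#' @export
defaultExpressionMatrix <- function() {
  ch <- c("Collagen IV a1/2", "Collagen IV a5", "Tensin", "Podocalyxin",
          "Fibronectin", "CD31", "Synaptopodin", "Nestin", "aSMA", "AQP1")
  E <- rbind(
    background         = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
    podocyte           = c(10, 20, 10, 200, 10, 10, 180, 160, 10, 10),
    mesangial          = c(150, 20, 200, 10, 150, 10, 10, 10, 20, 10),
    endothelial        = c(10, 15, 10, 10, 15, 200, 10, 10, 15, 10),
    basement_membrane  = c(40, 180, 35, 20, 80, 10, 15, 10, 10, 10),
    other_substructure = c(30, 30, 30, 30, 30, 30, 30, 30, 30, 30))
  colnames(E) <- ch
  E[cellTypeLevels(), ]
}

#' Build the planted cell-type lipid profile matrix
#'
#' Every feature gets a lognormal baseline intensity; each cell type's
#' profile varies around the baselines with a modest lognormal spread
#' (cell-type lipidome differences), and one planted marker per cell type
#' is enriched `markerFold`-fold. Two features are fixed at m/z 703.575
#' (planted podocyte-positive) and m/z 810.600 (planted
#' endothelial-positive and podocyte-depleted), so the worked example reads
#' like the sphingomyelin / phosphatidylcholine pair of the real tissue.
#'
#' @param nFeatures number of m/z features (default 40).
#' @param seed integer seed.
#' @param markerFold enrichment of each planted marker (default 4).
#' @param typeSpread lognormal sigma of per-type baseline variation
#'   (default 0.25).
#' @return list: `lipidMatrix` (6 x nFeatures), `mz`, `plantedMarkers`
#'   (data.frame `cell_type`, `feature`, `mz`, `sign`).
#' @export
defaultLipidMatrix <- function(nFeatures = 40, seed = 1, markerFold = 4,
                               typeSpread = 0.25) {
  stopifnot(nFeatures >= 8)
  lv <- cellTypeLevels()
  withr::with_seed(seed, {
    mz <- sort(round(runif(nFeatures * 3, 600, 900), 3))
    mz <- setdiff(unique(mz), c(703.575, 810.600))[seq_len(nFeatures - 2L)]
    mz <- sort(c(703.575, 810.600, mz))
    base <- exp(rnorm(nFeatures, log(100), 0.4))
    L <- matrix(0, length(lv), nFeatures, dimnames = list(lv, mzLabel(mz)))
    ## type-to-type lipidome variation is truncated at 2 sigma so no random
    ## fluctuation can rival a planted marker's fold change
    for (t in seq_along(lv)) {
      e <- rnorm(nFeatures, 0, typeSpread)
      L[t, ] <- base * exp(pmin(pmax(e, -2 * typeSpread), 2 * typeSpread))
    }
    jPod <- match(703.575, mz); jEnd <- match(810.600, mz)
    free <- setdiff(seq_len(nFeatures), c(jPod, jEnd))
    others <- setdiff(lv, c("podocyte", "endothelial"))
    jOther <- sample(free, length(others))
    marker <- setNames(integer(length(lv)), lv)
    marker["podocyte"] <- jPod
    marker["endothelial"] <- jEnd
    marker[others] <- jOther
    for (t in lv) L[t, marker[[t]]] <- base[marker[[t]]] * markerFold
    L["podocyte", jEnd] <- base[jEnd] / markerFold  # podocyte-depleted PC-like
  })
  list(lipidMatrix = L, mz = mz,
       plantedMarkers = data.frame(cell_type = lv, feature = unname(marker),
                                   mz = mz[marker], sign = 1L))
}

#' Render the MxIF raster from a cell map
#'
#' Pixel intensity in channel c is
#' `expression[cell_type, c] * LogNormal(mean 1, cv = noiseCv) +
#' backgroundLevel`; with `noiseCv = 0` the multiplier is exactly 1.
#'
#' @param cellMap integer matrix of cell-type codes
#'   (see [cellTypeLevels()]).
#' @param panel [AntibodyPanel-class] defining channel order.
#' @param expressionMatrix cell types x channels mean fluorescence; row
#'   names must cover the codes present in `cellMap`.
#' @param noiseCv lognormal coefficient of variation (>= 0).
#' @param backgroundLevel additive offset applied everywhere.
#' @param seed integer seed.
#' @param pitchUm,originUm raster geometry.
#' @return an [MxIFImage-class].
#' @export
renderMxIF <- function(cellMap, panel, expressionMatrix = defaultExpressionMatrix(),
                       noiseCv = 0.2, backgroundLevel = 2, seed = 1,
                       pitchUm = 1, originUm = c(0, 0)) {
  if (noiseCv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  lv <- cellTypeLevels()
  present <- lv[sort(unique(as.vector(cellMap)))]
  if (!all(present %in% rownames(expressionMatrix)))
    stop("expression matrix rows must cover all cell types present",
         call. = FALSE)
  ents <- panelTable(panel)
  if (!all(ents$target %in% colnames(expressionMatrix)))
    stop("expression matrix must have one column per panel target",
         call. = FALSE)
  h <- nrow(cellMap); w <- ncol(cellMap); nch <- nrow(ents)
  sigma <- sqrt(log(1 + noiseCv^2))
  arr <- array(0, c(h, w, nch))
  typeOfPixel <- lv[as.vector(cellMap)]
  withr::with_seed(seed, {
    for (ch in seq_len(nch)) {
      mu <- expressionMatrix[typeOfPixel, ents$target[ch]]
      mult <- if (noiseCv == 0) 1 else rlnorm(h * w, -sigma^2 / 2, sigma)
      arr[, , ch] <- matrix(mu * mult + backgroundLevel, h, w)
    }
  })
  MxIFImage(arr, panel, pitchUm = pitchUm, originUm = originUm)
}

#' Render the IMS peak table from a cell map
#'
#' Maps every cell-map pixel center through `trueTransform` into the IMS
#' physical frame and bins it into a 5 um-pitch (configurable) grid with
#' the same half-open footprint rule registration uses. Each IMS pixel's
#' expected spectrum is the partial-volume mixture (member-count-weighted
#' mean) of the lipid profiles of the cell types inside its footprint,
#' multiplied by `depthEffects` folds when the pixel's majority ROI is
#' deep, then noised. Grid cells of the bounding rectangle whose footprint
#' contains no cell-map pixel are dropped with a logged count.
#'
#' @param cellMap integer matrix of cell-type codes.
#' @param lipidMatrix cell types x features mean ion intensities.
#' @param mz m/z axis (one value per feature).
#' @param imsPitchUm IMS pixel pitch (>= cell-map pitch; default 5).
#' @param noiseModel list: `type` one of `"poisson"` (scaled Poisson,
#'   `scale` = variance-to-mean ratio), `"lognormal"` (`cv`), `"none"`.
#' @param depthEffects data.frame (`feature`, `fold`) or NULL.
#' @param roiMask [ROIMask-class] aligned with `cellMap` (for ROI ids and
#'   depth classes); NULL for no ROI information.
#' @param trueTransform [RegistrationTransform-class] MxIF physical ->
#'   IMS physical (identity = perfectly aligned frames).
#' @param seed integer seed.
#' @param pitchUm,originUm cell-map raster geometry.
#' @return an [IMSDataset-class].
#' @export
renderIMS <- function(cellMap, lipidMatrix, mz, imsPitchUm = 5,
                      noiseModel = list(type = "poisson", scale = 2),
                      depthEffects = NULL, roiMask = NULL,
                      trueTransform = RegistrationTransform(), seed = 1,
                      pitchUm = 1, originUm = c(0, 0)) {
  if (imsPitchUm < pitchUm)
    stop("IMS pitch must be >= the cell-map pitch", call. = FALSE)
  h <- nrow(cellMap); w <- ncol(cellMap)
  px <- expand.grid(row = 0:(h - 1L), col = 0:(w - 1L))
  centers <- pixelCenters(px$row, px$col, pitchUm, originUm)
  mapped <- transformPoints(trueTransform, centers)
  ox <- floor(min(mapped[, 1L]) / imsPitchUm) * imsPitchUm
  oy <- floor(min(mapped[, 2L]) / imsPitchUm) * imsPitchUm
  gc_ <- floor((mapped[, 1L] - ox) / imsPitchUm)
  gr_ <- floor((mapped[, 2L] - oy) / imsPitchUm)
  ncc <- max(gc_) + 1L; nrr <- max(gr_) + 1L
  bin <- gr_ * ncc + gc_ + 1L           # 1-based bin over bounding rectangle
  nbins <- nrr * ncc
  counts <- tabulate(bin, nbins)
  nEmpty <- sum(counts == 0L)
  if (nEmpty > 0L)
    message(sprintf("renderIMS: dropped %d empty-footprint IMS grid cells", nEmpty))
  keep <- which(counts > 0L)
  idxOf <- integer(nbins); idxOf[keep] <- seq_along(keep)
  nIms <- length(keep)
  ## partial-volume mixture weights: member count per (IMS pixel, cell type)
  lv <- cellTypeLevels()
  Wm <- matrix(0, nIms, length(lv))
  cm <- as.vector(cellMap)
  for (t in seq_along(lv)) {
    sel <- cm == t
    if (any(sel)) Wm[, t] <- tabulate(bin[sel], nbins)[keep]
  }
  Wm <- Wm / rowSums(Wm)
  mu <- Wm %*% lipidMatrix[lv, , drop = FALSE]
  ## majority ROI id per IMS pixel; deep ROIs get the depth fold applied
  roiId <- integer(nIms)
  if (!is.null(roiMask)) {
    rl <- as.vector(roiMask@labels)
    ids <- sort(unique(rl[rl > 0L]))
    cnt <- matrix(0L, nIms, length(ids) + 1L)
    cnt[, 1L] <- tabulate(bin[rl == 0L], nbins)[keep]
    for (i in seq_along(ids))
      cnt[, i + 1L] <- tabulate(bin[rl == ids[i]], nbins)[keep]
    best <- max.col(cnt, ties.method = "first")
    roiId <- c(0L, ids)[best]
    if (!is.null(depthEffects) && nrow(roiMask@depth)) {
      deepIds <- roiMask@depth$roi_id[roiMask@depth$depth_class == "deep"]
      isDeep <- roiId %in% deepIds
      for (i in seq_len(nrow(depthEffects)))
        mu[isDeep, depthEffects$feature[i]] <-
          mu[isDeep, depthEffects$feature[i]] * depthEffects$fold[i]
    }
  }
  ## noise
  inten <- withr::with_seed(seed, switch(
    noiseModel$type,
    none = mu,
    poisson = {
      s <- noiseModel$scale %||% 1
      matrix(s * rpois(length(mu), mu / s), nrow(mu), ncol(mu))
    },
    lognormal = {
      sg <- sqrt(log(1 + (noiseModel$cv %||% 0.2)^2))
      mu * matrix(rlnorm(length(mu), -sg^2 / 2, sg), nrow(mu), ncol(mu))
    },
    stop("unknown noise model: ", noiseModel$type, call. = FALSE)))
  b0 <- keep - 1L
  IMSDataset(inten, mz = mz,
             coords = data.frame(row = b0 %/% ncc, col = b0 %% ncc),
             roiId = roiId, pitchUm = imsPitchUm, originUm = c(ox, oy))
}

#' Default simulation configuration
#'
#' The paired-dataset conditions used throughout the package's examples and
#' validation: 20 glomeruli of 60 um radius, 1 um MxIF / 5 um IMS pitch,
#' 40 m/z features with one 4-fold planted marker per cell type, 20 percent
#' lognormal fluorescence noise over a floor of 2, scaled-Poisson ion noise
#' (variance twice the mean), a 1 degree / (3.2, -2.1) um frame
#' misalignment, equal deep/superficial fractions and three 2-fold
#' deep-glomerulus features.
#'
#' @return named list of simulation parameters.
#' @export
defaultSimConfig <- function() {
  list(n_glomeruli = 20, radius_um = 60, mxif_pitch_um = 1, ims_pitch_um = 5,
       n_features = 40, marker_fold = 4, type_spread = 0.25,
       noise_cv = 0.2, background_level = 2,
       ims_noise = list(type = "poisson", scale = 2),
       depth_fractions = c(deep = 0.5, superficial = 0.5),
       misalignment = list(rotation_deg = 1, offset_um = c(3.2, -2.1)),
       n_depth_features = 3, depth_fold = 2)
}

#' Simulate a paired IMS/MxIF dataset with known ground truth
#'
#' Runs [generateLayout()], [renderMxIF()] and [renderIMS()] under one
#' config (see [defaultSimConfig()]); per-stage seeds are derived from
#' `seed` with [stageSeed()]. Also exports four corner landmark pairs
#' mapped through the true transform, for registration.
#'
#' @param config list of simulation parameters; missing entries take
#'   [defaultSimConfig()] values.
#' @param seed integer global seed.
#' @return list: `truth` ([SyntheticTruth-class]), `mxif`
#'   ([MxIFImage-class]), `ims` ([IMSDataset-class]), `roi`
#'   ([ROIMask-class]), `landmarks` (list of `mxif`/`ims` corner pairs).
#' @examples
#' sim <- simulateGlomeruli(list(n_glomeruli = 2), seed = 7)
#' sim$truth
#' @export
simulateGlomeruli <- function(config = list(), seed = 1) {
  cfg <- modifyList(defaultSimConfig(), config)
  lay <- generateLayout(cfg$n_glomeruli, cfg$radius_um, cfg$mxif_pitch_um,
                        cfg$depth_fractions, seed = stageSeed(seed, "layout"))
  panel <- glomerularPanel()
  E <- defaultExpressionMatrix()
  lip <- defaultLipidMatrix(cfg$n_features, seed = stageSeed(seed, "lipids"),
                            markerFold = cfg$marker_fold,
                            typeSpread = cfg$type_spread)
  mxif <- renderMxIF(lay$cellMap, panel, E, noiseCv = cfg$noise_cv,
                     backgroundLevel = cfg$background_level,
                     seed = stageSeed(seed, "mxif"),
                     pitchUm = cfg$mxif_pitch_um)
  th <- cfg$misalignment$rotation_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  trueT <- RegistrationTransform(A, cfg$misalignment$offset_um)
  nonMarker <- setdiff(seq_len(cfg$n_features), lip$plantedMarkers$feature)
  depthFeat <- withr::with_seed(stageSeed(seed, "depth"),
                                sort(sample(nonMarker, cfg$n_depth_features)))
  depthEffects <- data.frame(feature = depthFeat, mz = lip$mz[depthFeat],
                             fold = cfg$depth_fold)
  ims <- renderIMS(lay$cellMap, lip$lipidMatrix, lip$mz,
                   imsPitchUm = cfg$ims_pitch_um, noiseModel = cfg$ims_noise,
                   depthEffects = depthEffects, roiMask = lay$roi,
                   trueTransform = trueT, seed = stageSeed(seed, "ims"),
                   pitchUm = cfg$mxif_pitch_um)
  ext <- c(ncol(lay$cellMap), nrow(lay$cellMap)) * cfg$mxif_pitch_um
  lmM <- rbind(c(0, 0), c(ext[1], 0), c(0, ext[2]), ext)
  landmarks <- list(mxif = lmM, ims = transformPoints(trueT, lmM))
  truth <- new("SyntheticTruth", cellMap = lay$cellMap,
               cellTypes = cellTypeLevels(),
               expressionMatrix = E, lipidMatrix = lip$lipidMatrix,
               plantedMarkers = lip$plantedMarkers,
               depthEffects = depthEffects, trueTransform = trueT,
               seed = as.integer(seed))
  list(truth = truth, mxif = mxif, ims = ims, roi = lay$roi,
       landmarks = landmarks)
}
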