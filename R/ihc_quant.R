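# Automated DAB image analysis: tissue masking by RGB color detection,
# motor-neuron detection by the three-step threshold / close-open with
# reconstruction / watershed procedure, positive-pixel brown detection
# with a minimum cluster-size cutoff, percent-area normalization, and
# automated-vs-manual count calibration.

#' Quantification configuration
#'
#' All radii and areas are physical (micrometres); they are converted to
#' pixels internally with `um_per_pixel`. The structural steps are the
#' algorithm; the numeric defaults here were tuned once against the
#' synthetic DAB palette of [scene_config()] and are instrument-specific,
#' not claims about any original acquisition.
#'
#' @param um_per_pixel physical scale.
#' @param tissue_rule per-channel RGB intervals (`lo`, `hi` triples); a
#'   pixel is tissue-colored when every channel lies inside its interval.
#'   The default accepts counterstained and stained tissue and rejects
#'   near-white slide background.
#' @param tissue_close_radius_um,tissue_open_radius_um closing/opening
#'   radii for the tissue mask (fill pinholes, remove speckle).
#' @param min_component_um2 connected components below this area are
#'   dropped from the tissue mask.
#' @param erode_margin_um default edge-effect erosion for stain area
#'   analysis.
#' @param cell_rule per-channel RGB intervals selecting strongly stained
#'   somata.
#' @param open_radius_um opening radius of detection step (a).
#' @param reconstruct_radius_um structuring radius of the close-open with
#'   reconstruction, step (b).
#' @param ws_smooth_sigma_px Gaussian smoothing of the watershed
#'   landscape (the distance transform of the candidate mask), step (c).
#' @param ws_tolerance_px minimum basin depth separating watershed
#'   objects.
#' @param dilate_radius_um post-watershed dilation recovering the blob
#'   margin eroded by the opening.
#' @param min_cell_area_um2,max_cell_area_um2 inclusive size filter for
#'   accepted cells.
#' @param brown_rule list `blue_ratio_max` (pixel is brown-candidate when
#'   `B/(R+G+B)` is below this) and `intensity_max` (mean channel
#'   intensity must be below this, excluding white background; a zero
#'   R+G+B sum is never brown).
#' @param brown_smooth_radius_um radius of the opening-closing that
#'   filters and merges neighboring positive pixels.
#' @param min_cluster_area_um2 minimum positive-cluster area; the study's
#'   cutoff for microglial clusters/enlarged cells is 180.
#' @return `quant_config` list.
#' @export
quant_config <- function(um_per_pixel = 0.65,
                         tissue_rule = list(lo = c(0, 0, 0),
                                            hi = c(244, 244, 250)),
                         tissue_close_radius_um = 3,
                         tissue_open_radius_um = 3,
                         min_component_um2 = 5000,
                         erode_margin_um = 10,
                         cell_rule = list(lo = c(60, 20, 0),
                                          hi = c(190, 140, 110)),
                         open_radius_um = 2,
                         reconstruct_radius_um = 1.5,
                         ws_smooth_sigma_px = 1,
                         ws_tolerance_px = 1,
                         dilate_radius_um = 1,
                         min_cell_area_um2 = 120,
                         max_cell_area_um2 = 1600,
                         brown_rule = list(blue_ratio_max = 0.25,
                                           intensity_max = 220),
                         brown_smooth_radius_um = 1.3,
                         min_cluster_area_um2 = 180) {
  cfg <- as.list(environment())
  if (cfg$um_per_pixel <= 0) stopf("um_per_pixel must be > 0")
  radii <- c(cfg$tissue_close_radius_um, cfg$tissue_open_radius_um,
             cfg$erode_margin_um, cfg$open_radius_um,
             cfg$reconstruct_radius_um, cfg$dilate_radius_um,
             cfg$brown_smooth_radius_um)
  if (any(radii < 0)) stopf("all radii must be >= 0")
  if (cfg$min_cell_area_um2 >= cfg$max_cell_area_um2)
    stopf("min_cell_area_um2 must be < max_cell_area_um2")
  if (cfg$min_cluster_area_um2 < 0)
    stopf("min_cluster_area_um2 must be >= 0")
  structure(cfg, class = "quant_config")
}

check_rgb <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stopf("expected an RGB image as a rows x cols x 3 array")
  invisible(rgb)
}

# per-channel interval rule -> logical matrix
apply_rgb_rule <- function(rgb, rule) {
  ok <- rgb[, , 1] >= rule$lo[1] & rgb[, , 1] <= rule$hi[1] &
    rgb[, , 2] >= rule$lo[2] & rgb[, , 2] <= rule$hi[2] &
    rgb[, , 3] >= rule$lo[3] & rgb[, , 3] <= rule$hi[3]
  ok
}

binary_morph <- function(mask, op, radius_px) {
  if (radius_px <= 0) return(mask)
  kern <- disc_kernel(radius_px)
  f <- switch(op, open = EBImage::opening, close = EBImage::closing,
              erode = EBImage::erode, dilate = EBImage::dilate)
  EBImage::imageData(f(EBImage::Image(mask * 1), kern)) > 0.5
}

#' Tissue mask from RGB color detection and morphology
#'
#' Pixels satisfying the tissue color rule, regularized by morphological
#' closing (fill pinholes) then opening (remove speckle), keeping
#' connected components of at least `min_component_um2`. An image with no
#' tissue colors yields an empty mask (area 0) with a warning, not an
#' error.
#'
#' @param rgb `rows x cols x 3` array in `[0, 255]`.
#' @param config a [quant_config()].
#' @return `tissue_mask` list: `mask` (logical matrix), `area_um2`,
#'   `um_per_pixel`.
#' @export
compute_tissue_mask <- function(rgb, config) {
  check_rgb(rgb)
  stopifnot(inherits(config, "quant_config"))
  px <- config$um_per_pixel
  mask <- apply_rgb_rule(rgb, config$tissue_rule)
  mask <- binary_morph(mask, "close", config$tissue_close_radius_um / px)
  mask <- binary_morph(mask, "open", config$tissue_open_radius_um / px)
  if (any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas * px^2 >= config$min_component_um2)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) warnf("tissue mask is empty")
  structure(list(mask = mask, area_um2 = sum(mask) * px^2,
                 um_per_pixel = px), class = "tissue_mask")
}

#' Erode a tissue mask by a physical margin
#'
#' Binary erosion with a disc of radius `margin_um`; the result is always
#' a subset of the input (edge pixels are removed to avoid staining edge
#' effects).
#'
#' @param tissue a `tissue_mask`.
#' @param margin_um erosion depth in micrometres (0 = identity).
#' @return eroded `tissue_mask`.
#' @export
erode_tissue_mask <- function(tissue, margin_um) {
  stopifnot(inherits(tissue, "tissue_mask"))
  if (margin_um < 0) stopf("margin_um must be >= 0")
  px <- tissue$um_per_pixel
  mask <- binary_morph(tissue$mask, "erode", margin_um / px)
  structure(list(mask = mask, area_um2 = sum(mask) * px^2,
                 um_per_pixel = px), class = "tissue_mask")
}

#' Detect motor-neuron cell bodies
#'
#' The three-stage automated procedure: (a) global per-channel color
#' thresholds for stained somata restricted to the tissue mask, followed
#' by morphological opening; (b) close-open with (binary morphological)
#' reconstruction, regularizing blob outlines while preserving marker
#' geometry; (c) watershed on the smoothed distance-transform landscape
#' -- its regional maxima are the markers, equivalent to regional minima
#' of the inverted landscape -- splitting touching somata, followed by
#' dilation and inclusive size filtering in square micrometres.
#'
#' @param rgb RGB array in `[0, 255]`.
#' @param tissue a `tissue_mask` from [compute_tissue_mask()].
#' @param config a [quant_config()].
#' @return `cell_detection` list: `label_mask` (integer matrix), `count`,
#'   `centroids` (`(row, col)` matrix), `areas_um2`.
#' @export
detect_motor_neurons <- function(rgb, tissue, config) {
  check_rgb(rgb)
  stopifnot(inherits(tissue, "tissue_mask"),
            inherits(config, "quant_config"))
  px <- config$um_per_pixel

  # (a) global color thresholds, restricted to tissue, then opening
  cand <- apply_rgb_rule(rgb, config$cell_rule) & tissue$mask
  cand <- binary_morph(cand, "open", config$open_radius_um / px)

  # (b) close-open with reconstruction: close, then open, then
  # reconstruct the closed mask from the opened marker
  r_px <- config$reconstruct_radius_um / px
  closed <- binary_morph(cand, "close", r_px)
  marker <- binary_morph(closed, "open", r_px)
  cand <- binary_reconstruct(marker, closed)

  empty <- list(label_mask = matrix(0L, nrow(tissue$mask),
                                    ncol(tissue$mask)),
                count = 0L,
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                areas_um2 = numeric(0))
  class(empty) <- "cell_detection"
  if (!any(cand)) return(empty)

  # (c) watershed on the smoothed distance transform; basins of the
  # inverted landscape split abutting somata
  dm <- EBImage::distmap(EBImage::Image(cand * 1))
  if (config$ws_smooth_sigma_px > 0) {
    dm <- EBImage::gblur(dm, sigma = config$ws_smooth_sigma_px)
    dm <- EBImage::imageData(dm)
    dm[!cand] <- 0
    dm <- EBImage::Image(dm)
  }
  ws <- EBImage::watershed(dm, tolerance = config$ws_tolerance_px, ext = 1)
  ws <- EBImage::imageData(ws)

  # dilation: grow each label into the dilated support without merging
  d_px <- config$dilate_radius_um / px
  if (d_px > 0) {
    grown_support <- binary_morph(cand, "dilate", d_px) & tissue$mask
    ws <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(matrix(0, nrow(ws), ncol(ws))),
      seeds = EBImage::Image(ws),
      mask = EBImage::Image(grown_support * 1)))
  }

  # inclusive size filter in um^2, then relabel sequentially
  st <- label_stats(ws)
  areas_um2 <- st$areas_px * px^2
  keep <- areas_um2 >= config$min_cell_area_um2 &
    areas_um2 <= config$max_cell_area_um2
  if (!any(keep)) return(empty)
  old <- st$labels[keep]
  relab <- match(ws, old, nomatch = 0L)
  label_mask <- matrix(as.integer(relab), nrow(ws), ncol(ws))
  structure(list(label_mask = label_mask,
                 count = length(old),
                 centroids = st$centroids[keep, , drop = FALSE],
                 areas_um2 = unname(areas_um2[keep])),
            class = "cell_detection")
}

#' Brown (DAB-positive) pixel detection
#'
#' A pixel is positive when it lies inside the tissue mask and is classed
#' brown: normalized blue `B/(R+G+B)` below `blue_ratio_max` and mean
#' channel intensity below `intensity_max` (excluding white background);
#' a zero channel sum is never brown. Neighboring binary pixels are then
#' filtered and merged by morphological opening-closing.
#'
#' @inheritParams detect_motor_neurons
#' @return logical matrix of positive pixels.
#' @export
detect_brown_positive <- function(rgb, tissue, config) {
  check_rgb(rgb)
  stopifnot(inherits(tissue, "tissue_mask"),
            inherits(config, "quant_config"))
  s <- rgb[, , 1] + rgb[, , 2] + rgb[, , 3]
  ratio <- ifelse(s > 0, rgb[, , 3] / s, 1)   # zero sum -> never brown
  pos <- tissue$mask &
    ratio < config$brown_rule$blue_ratio_max &
    (s / 3) < config$brown_rule$intensity_max
  r_px <- config$brown_smooth_radius_um / config$um_per_pixel
  pos <- binary_morph(pos, "open", r_px)
  pos <- binary_morph(pos, "close", r_px)
  pos
}

#' Remove positive clusters below a minimum area
#'
#' Connected components (8-connectivity) with area below the cutoff are
#' removed entirely; components at or above it are kept intact. Cutoff 0
#' is the identity.
#'
#' @param positive logical matrix of positive pixels.
#' @param min_cluster_area_um2 cutoff in square micrometres.
#' @param um_per_pixel physical scale.
#' @return filtered logical matrix.
#' @export
filter_by_min_area <- function(positive, min_cluster_area_um2,
                               um_per_pixel) {
  if (min_cluster_area_um2 < 0) stopf("cutoff must be >= 0")
  if (min_cluster_area_um2 == 0 || !any(positive)) return(positive)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(positive * 1)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas * um_per_pixel^2 >= min_cluster_area_um2)
  matrix(lab %in% keep, nrow(positive), ncol(positive))
}

#' Percent tissue area stained
#'
#' `percent_area = 100 * |positive n tissue| / |tissue|`, areas in square
#' micrometres.
#'
#' @param positive logical matrix of positive pixels.
#' @param tissue a `tissue_mask` with nonzero area.
#' @return `stain_quant` list: `positive_mask`, `positive_area_um2`,
#'   `tissue_area_um2`, `percent_area`.
#' @export
percent_area_stained <- function(positive, tissue) {
  stopifnot(inherits(tissue, "tissue_mask"))
  if (tissue$area_um2 <= 0)
    stopf("tissue area is 0; percent area undefined")
  inter <- positive & tissue$mask
  px2 <- tissue$um_per_pixel^2
  structure(list(positive_mask = inter,
                 positive_area_um2 = sum(inter) * px2,
                 tissue_area_um2 = tissue$area_um2,
                 percent_area = 100 * sum(inter) * px2 / tissue$area_um2),
            class = "stain_quant")
}

#' Calibrate automated against manual counts
#'
#' Ordinary least squares of `automated ~ manual`, with the coefficient
#' of determination and the mean fractional underestimate
#' `mean((manual - automated) / manual)`.
#'
#' @param manual,automated paired counts (>= 3 pairs, manual > 0).
#' @return `count_calibration` list: `slope`, `intercept`, `r_squared`,
#'   `mean_bias_fraction`, `n`.
#' @export
calibrate_automated_counts <- function(manual, automated) {
  if (length(manual) != length(automated))
    stopf("manual and automated must have equal length")
  if (length(manual) < 3) stopf("at least 3 pairs required")
  if (any(manual <= 0)) stopf("manual counts must be > 0")
  if (stats::var(manual) == 0)
    stopf("degenerate fit: all manual counts identical")
  fit <- lm(automated ~ manual)
  sst <- sum((automated - mean(automated))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 mean_bias_fraction = mean((manual - automated) / manual),
                 n = length(manual)),
            class = "count_calibration")
}

#' Quantify one section image end to end
#'
#' Convenience wrapper: tissue mask, then one of three analyses.
#' `"neurons"` runs motor-neuron detection; `"area"` measures the brown
#' positive-pixel percent area inside the eroded tissue mask; and
#' `"clusters"` does the same but keeps only positive clusters of at
#' least `min_cluster_area_um2` (the enlarged-cell / cluster endpoint;
#' the plain percent-area endpoint applies no size cutoff).
#'
#' @param rgb RGB array in `[0, 255]`.
#' @param config a [quant_config()].
#' @param mode `"neurons"`, `"area"` or `"clusters"`.
#' @return the `cell_detection` or `stain_quant` result, with the tissue
#'   mask attached as attribute `tissue`.
#' @export
quantify_section <- function(rgb, config,
                             mode = c("neurons", "area", "clusters")) {
  mode <- match.arg(mode)
  tissue <- compute_tissue_mask(rgb, config)
  out <- if (mode == "neurons") {
    detect_motor_neurons(rgb, tissue, config)
  } else {
    eroded <- erode_tissue_mask(tissue, config$erode_margin_um)
    pos <- detect_brown_positive(rgb, eroded, config)
    if (mode == "clusters")
      pos <- filter_by_min_area(pos, config$min_cluster_area_um2,
                                config$um_per_pixel)
    percent_area_stained(pos, eroded)
  }
  attr(out, "tissue") <- tissue
  out
}
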