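# Ground-truthed synthetic DAB section generator: elliptical brown cell
# bodies and diffuse brown staining on a bluish tissue background, with
# per-pixel ground truth (cell labels, tissue mask, diffuse mask) so the
# image-quantification operations are testable without real slides.
#
# Convention throughout: images are [row, col(, channel)] arrays, origin
# top-left; RGB values in [0, 255].

#' Synthetic section scene configuration
#'
#' @param canvas_px `(rows, cols)` canvas size in pixels.
#' @param um_per_pixel physical scale (micrometres per pixel).
#' @param tissue_shape `"ellipse"` (single centered ellipse) or
#'   `"butterfly"` (two overlapping lateral lobes, a spinal-cord-like
#'   bilateral section).
#' @param n_cells number of cell bodies to place (touching-pair members
#'   count toward this total).
#' @param cell_diameter_um `(min, max)` equivalent-diameter range for the
#'   elliptical somata.
#' @param n_touching_pairs number of deliberately abutting cell pairs
#'   (the watershed stress case; pairs share a 1-3 px boundary).
#' @param diffuse_fraction target fraction of tissue area covered by
#'   diffuse positive stain, in `[0, 1]`.
#' @param stain_color,tissue_color,background_color RGB triples in
#'   `[0, 255]`: DAB brown, bluish counterstained tissue, slide
#'   background.
#' @param noise_sd additive Gaussian noise SD (8-bit intensity units).
#' @param blur_sigma_um Gaussian smoothing scale in micrometres.
#' @param seed integer; identical `(config)` reproduce bit-identical
#'   scenes and renders.
#' @return `scene_config` list.
#' @export
scene_config <- function(canvas_px = c(1024, 1024),
                         um_per_pixel = 0.65,
                         tissue_shape = c("butterfly", "ellipse"),
                         n_cells = 30,
                         cell_diameter_um = c(15, 40),
                         n_touching_pairs = 0,
                         diffuse_fraction = 0,
                         stain_color = c(130, 80, 40),
                         tissue_color = c(190, 190, 210),
                         background_color = c(255, 255, 255),
                         noise_sd = 0,
                         blur_sigma_um = 0,
                         seed = 1) {
  tissue_shape <- match.arg(tissue_shape)
  cfg <- as.list(environment())
  if (length(cfg$canvas_px) != 2 || any(cfg$canvas_px < 64))
    stopf("canvas_px must be (rows, cols), each >= 64")
  if (cfg$um_per_pixel <= 0) stopf("um_per_pixel must be > 0")
  if (cfg$n_cells < 0) stopf("n_cells must be >= 0")
  if (2 * cfg$n_touching_pairs > cfg$n_cells)
    stopf("every touching pair counts 2 toward n_cells")
  if (cfg$diffuse_fraction < 0 || cfg$diffuse_fraction > 1)
    stopf("diffuse_fraction must lie in [0, 1]")
  d <- cfg$cell_diameter_um
  if (length(d) != 2 || d[1] <= 0 || d[1] > d[2])
    stopf("cell_diameter_um must be (min, max) with 0 < min <= max")
  for (nm in c("stain_color", "tissue_color", "background_color"))
    if (any(cfg[[nm]] < 0 | cfg[[nm]] > 255) || length(cfg[[nm]]) != 3)
      stopf("%s must be an RGB triple in [0, 255]", nm)
  if (cfg$noise_sd < 0 || cfg$blur_sigma_um < 0)
    stopf("noise_sd and blur_sigma_um must be >= 0")
  structure(cfg, class = "scene_config")
}

# parametric tissue region for a config
tissue_region <- function(cfg) {
  nr <- cfg$canvas_px[1]; nc <- cfg$canvas_px[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside_ellipse <- function(cy, cx, a_r, a_c) {
    ((rr - cy) / a_r)^2 + ((cc - cx) / a_c)^2 <= 1
  }
  if (cfg$tissue_shape == "ellipse") {
    inside_ellipse(nr / 2, nc / 2, 0.42 * nr, 0.42 * nc)
  } else {
    # two overlapping lateral lobes (bilateral "butterfly")
    inside_ellipse(nr / 2, 0.32 * nc, 0.38 * nr, 0.24 * nc) |
      inside_ellipse(nr / 2, 0.68 * nc, 0.38 * nr, 0.24 * nc) |
      inside_ellipse(nr / 2, nc / 2, 0.12 * nr, 0.30 * nc)
  }
}

# rasterize a rotated ellipse; returns logical matrix of given dim
raster_ellipse <- function(dims, cy, cx, a, b, theta) {
  # bounding box to keep cost local
  r <- ceiling(max(a, b)) + 2L
  r0 <- max(1L, floor(cy) - r); r1 <- min(dims[1], ceiling(cy) + r)
  c0 <- max(1L, floor(cx) - r); c1 <- min(dims[2], ceiling(cx) + r)
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  x <- cc - cx; y <- rr - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  list(rows = r0:r1, cols = c0:c1, mask = sel)
}

# paint a raster patch into a logical canvas
paint <- function(canvas, patch, value = TRUE) {
  sub <- canvas[patch$rows, patch$cols]
  sub[patch$mask] <- value
  canvas[patch$rows, patch$cols] <- sub
  canvas
}

# does patch overlap TRUE pixels of canvas?
overlaps <- function(canvas, patch) {
  any(canvas[patch$rows, patch$cols] & patch$mask)
}

# is patch fully inside mask?
inside_mask <- function(mask, patch) {
  all(mask[patch$rows, patch$cols][patch$mask])
}

# 8-neighbour adjacency between a patch and existing TRUE pixels
adjacent_to <- function(canvas, patch) {
  d <- EBImage::dilate(EBImage::Image(patch_to_full(canvas, patch) * 1),
                       matrix(1, 3, 3)) > 0.5
  any(d & canvas)
}

patch_to_full <- function(canvas, patch) {
  full <- matrix(FALSE, nrow(canvas), ncol(canvas))
  full[patch$rows, patch$cols] <- patch$mask
  full
}

# sample ellipse semi-axes (px) matching an equivalent diameter draw
sample_axes <- function(cfg) {
  d_um <- runif(1, cfg$cell_diameter_um[1], cfg$cell_diameter_um[2])
  d_px <- d_um / cfg$um_per_pixel
  ratio <- runif(1, 0.75, 1)      # mild eccentricity keeps distance maps clean
  # equivalent diameter d: pi*a*b = pi*(d/2)^2 with b = ratio*a
  a <- (d_px / 2) / sqrt(ratio)
  list(a = a, b = ratio * a, theta = runif(1, 0, pi))
}

#' Build the ground-truth scene for a configuration
#'
#' Places `n_cells` elliptical cell bodies inside the tissue region
#' without overlap (except the requested abutting pairs), then paints
#' diffuse-positive blobs until the realized tissue fraction is within
#' 0.01 of `diffuse_fraction` (a shortfall is flagged, not hidden).
#' Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @return `ground_truth` list: `cell_label_mask` (integer matrix, 0 =
#'   non-cell), `cell_count`, `cell_centroids` (`(row, col)` matrix),
#'   `cell_areas_px`, `touching_pairs` (2-column label matrix),
#'   `tissue_mask_true`, `diffuse_mask_true`,
#'   `diffuse_area_fraction_true`, `stained_area_fraction_true`
#'   (cells and diffuse combined), `diffuse_shortfall` flag.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, build_scene_impl(config))
}

build_scene_impl <- function(cfg) {
  dims <- cfg$canvas_px
  tissue <- tissue_region(cfg)
  tissue_px <- sum(tissue)
  if (tissue_px == 0) stopf("tissue region is empty")
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(tissue * 1)))

  label <- matrix(0L, dims[1], dims[2])
  occupied <- matrix(FALSE, dims[1], dims[2])  # cells + 5 px clearance
  cellmask <- matrix(FALSE, dims[1], dims[2])
  next_label <- 0L
  centroids <- NULL
  pairs <- NULL
  max_attempts <- 400L

  place_one <- function(must_touch = NULL) {
    # must_touch: an existing patch to abut (for touching pairs)
    for (attempt in seq_len(max_attempts)) {
      ax <- sample_axes(cfg)
      amax <- max(ax$a, ax$b)
      if (is.null(must_touch)) {
        ok <- which(dt > amax + 1, arr.ind = TRUE)
        if (nrow(ok) == 0) next
        ctr <- ok[sample.int(nrow(ok), 1), ]
        cy <- ctr[1]; cx <- ctr[2]
        p <- raster_ellipse(dims, cy, cx, ax$a, ax$b, ax$theta)
        if (is.null(p) || !any(p$mask)) next
        if (!inside_mask(tissue, p)) next
        if (overlaps(occupied, p)) next
        return(p)
      } else {
        # walk outward along a random direction from the partner centre
        th <- runif(1, 0, 2 * pi)
        pc <- must_touch$centre
        partner_full <- patch_to_full(cellmask, must_touch)
        sep0 <- must_touch$amax + amax
        for (d_off in seq(sep0 + 3, sep0 * 0.5, by = -0.5)) {
          cy <- pc[1] + d_off * sin(th); cx <- pc[2] + d_off * cos(th)
          p <- raster_ellipse(dims, cy, cx, ax$a, ax$b, ax$theta)
          if (is.null(p) || !any(p$mask)) next
          if (!inside_mask(tissue, p)) break
          full <- patch_to_full(cellmask, p)
          if (any(full & partner_full)) break   # stepped too far: overlap
          others <- occupied & !must_touch$clearance
          if (any(full & others)) break
          dil <- EBImage::dilate(EBImage::Image(full * 1),
                                 matrix(1, 3, 3)) > 0.5
          if (any(dil & partner_full)) return(p)  # abutting, no overlap
        }
      }
    }
    NULL
  }

  commit <- function(p) {
    next_label <<- next_label + 1L
    sub <- label[p$rows, p$cols]
    sub[p$mask] <- next_label
    label[p$rows, p$cols] <<- sub
    cellmask <<- paint(cellmask, p)
    full <- patch_to_full(cellmask, p)
    clearance <- EBImage::dilate(EBImage::Image(full * 1),
                                 disc_kernel(5)) > 0.5
    occupied <<- occupied | clearance
    next_label
  }

  n_single <- cfg$n_cells - 2L * cfg$n_touching_pairs
  for (k in seq_len(cfg$n_touching_pairs)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      ax <- sample_axes(cfg)
      amax <- max(ax$a, ax$b)
      ok <- which(dt > 2 * amax + 4, arr.ind = TRUE)  # room for a partner
      if (nrow(ok) == 0) next
      ctr <- ok[sample.int(nrow(ok), 1), ]
      p1 <- raster_ellipse(dims, ctr[1], ctr[2], ax$a, ax$b, ax$theta)
      if (is.null(p1) || !any(p1$mask)) next
      if (!inside_mask(tissue, p1) || overlaps(occupied, p1)) next
      full1 <- patch_to_full(cellmask, p1)
      clearance1 <- EBImage::dilate(EBImage::Image(full1 * 1),
                                    disc_kernel(5)) > 0.5
      p1$centre <- c(ctr[1], ctr[2]); p1$amax <- amax
      p1$clearance <- clearance1
      p2 <- place_one(must_touch = p1)
      if (is.null(p2)) next
      l1 <- commit(p1); l2 <- commit(p2)
      pairs <- rbind(pairs, c(l1, l2))
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("placement failure: could not place touching pair %d", k)
  }
  for (k in seq_len(n_single)) {
    p <- place_one()
    if (is.null(p))
      stopf("placement failure: could not place cell %d of %d",
            k + 2L * cfg$n_touching_pairs, cfg$n_cells)
    commit(p)
  }

  # diffuse staining: random soft blobs inside tissue, off the cells,
  # until the realized fraction reaches the target within 0.01
  diffuse <- matrix(FALSE, dims[1], dims[2])
  shortfall <- FALSE
  if (cfg$diffuse_fraction > 0) {
    target <- cfg$diffuse_fraction
    avail <- tissue & !cellmask
    # centres drawn from a dilated tissue region so blobs clipped at the
    # boundary do not leave the tissue interior denser than its margin
    pool <- which(binary_morph(tissue, "dilate", 20), arr.ind = TRUE)
    it <- 0L
    repeat {
      realized <- sum(diffuse) / tissue_px
      if (realized >= target - 0.01) break
      it <- it + 1L
      if (it > 5000L) { shortfall <- TRUE; break }
      # patch size: a compromise between realism (multi-cell glial
      # patches, tens of micrometres) and spatial homogeneity -- each
      # patch is ~0.1-0.2% of tissue, so the stained fraction in any
      # interior window tracks the whole-tissue fraction closely
      rad <- runif(1, 8, 12)
      ctr <- pool[sample.int(nrow(pool), 1), ]
      ecc <- runif(1, 0.6, 1)
      p <- raster_ellipse(dims, ctr[1], ctr[2], rad, rad * ecc,
                          runif(1, 0, pi))
      if (is.null(p) || !any(p$mask)) next
      sub <- diffuse[p$rows, p$cols]
      sub[p$mask & avail[p$rows, p$cols]] <- TRUE
      diffuse[p$rows, p$cols] <- sub
    }
  }
  realized <- sum(diffuse & tissue) / tissue_px

  st <- label_stats(label)
  structure(list(
    cell_label_mask = label,
    cell_count = next_label,
    cell_centroids = st$centroids,
    cell_areas_px = st$areas_px,
    touching_pairs = if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs,
    tissue_mask_true = tissue,
    diffuse_mask_true = diffuse,
    diffuse_area_fraction_true = realized,
    stained_area_fraction_true = sum((diffuse | cellmask) & tissue) /
      tissue_px,
    diffuse_shortfall = shortfall
  ), class = "ground_truth")
}

#' Render a scene to an RGB section image
#'
#' Cells and diffuse regions take `stain_color`, remaining tissue
#' `tissue_color`, the exterior `background_color`; Gaussian blur and
#' additive noise are then applied and the result rounded and clipped to
#' 8-bit. Noise is drawn under `config$seed + 1`, so the render is
#' deterministic given `(truth, config)`.
#'
#' @param truth a [build_scene()] result produced from the same config.
#' @param config the [scene_config()].
#' @return `rendered_section` list: `rgb` (`rows x cols x 3` integer
#'   array in `[0, 255]`), `um_per_pixel`, `truth`, `seed`.
#' @export
render_section <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "scene_config"))
  if (!identical(dim(truth$cell_label_mask), as.integer(config$canvas_px)) &&
      !identical(dim(truth$cell_label_mask), config$canvas_px))
    stopf("truth dimensions do not match config canvas")
  dims <- dim(truth$tissue_mask_true)
  stained <- truth$cell_label_mask > 0 | truth$diffuse_mask_true
  img <- array(0, dim = c(dims, 3))
  for (ch in 1:3) {
    plane <- matrix(config$background_color[ch], dims[1], dims[2])
    plane[truth$tissue_mask_true] <- config$tissue_color[ch]
    plane[stained] <- config$stain_color[ch]
    img[, , ch] <- plane
  }
  if (config$blur_sigma_um > 0) {
    sigma_px <- config$blur_sigma_um / config$um_per_pixel
    for (ch in 1:3)
      img[, , ch] <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(img[, , ch]), sigma = sigma_px))
  }
  if (config$noise_sd > 0) {
    img <- img + withr::with_seed(config$seed + 1L,
                                  array(rnorm(length(img), 0,
                                              config$noise_sd),
                                        dim = dim(img)))
  }
  img <- round(pmin(pmax(img, 0), 255))
  structure(list(rgb = img, um_per_pixel = config$um_per_pixel,
                 truth = truth, seed = config$seed),
            class = "rendered_section")
}

#' Write a rendered section and its ground truth to disk
#'
#' The RGB image goes to 8-bit PNG, the label mask to 16-bit single
#' channel TIFF, and a JSON sidecar records the summary ground truth.
#'
#' @param section a [render_section()] result.
#' @param path_png,path_labels,path_json output paths.
#' @return invisibly, the three paths.
#' @export
write_section <- function(section, path_png, path_labels, path_json) {
  stopifnot(inherits(section, "rendered_section"))
  png::writePNG(section$rgb / 255, path_png)
  if (max(section$truth$cell_label_mask) > 65535)
    stopf("more than 65535 labels cannot be stored in 16-bit TIFF")
  tiff::writeTIFF(section$truth$cell_label_mask / 65535, path_labels,
                  bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(
    seed = section$seed,
    cell_count = section$truth$cell_count,
    diffuse_area_fraction_true = section$truth$diffuse_area_fraction_true,
    stained_area_fraction_true = section$truth$stained_area_fraction_true,
    um_per_pixel = section$um_per_pixel
  ), path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(png = path_png, labels = path_labels, json = path_json))
}

#' Read a section image written by [write_section()]
#'
#' @param path_png path to the 8-bit PNG.
#' @return integer `rows x cols x 3` array in `[0, 255]`.
#' @export
read_section_image <- function(path_png) {
  img <- png::readPNG(path_png)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Generate a fixture set of synthetic sections
#'
#' Writes one PNG + 16-bit label TIFF + JSON sidecar per config, plus a
#' CSV manifest (`file`, `seed`, `cell_count`, `diffuse_fraction`,
#' `um_per_pixel`). Re-running with the same manifest reproduces
#' byte-identical files.
#'
#' @param out_dir writable directory (created if absent).
#' @param configs list of [scene_config()]s.
#' @param prefix file-name prefix.
#' @return invisibly, the manifest data.frame.
#' @export
generate_fixture_set <- function(out_dir, configs, prefix = "section") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    stopifnot(inherits(cfg, "scene_config"))
    truth <- build_scene(cfg)
    sec <- render_section(truth, cfg)
    base <- sprintf("%s_%02d", prefix, i)
    write_section(sec,
                  file.path(out_dir, paste0(base, ".png")),
                  file.path(out_dir, paste0(base, "_labels.tiff")),
                  file.path(out_dir, paste0(base, "_truth.json")))
    data.frame(file = paste0(base, ".png"), seed = cfg$seed,
               cell_count = truth$cell_count,
               diffuse_fraction = truth$diffuse_area_fraction_true,
               um_per_pixel = cfg$um_per_pixel)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
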