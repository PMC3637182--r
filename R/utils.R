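#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rweibull rexp coef logLik
#'   lm pchisq t.test sd median quantile complete.cases setNames
#' @importFrom utils write.csv read.csv
NULL

# stop() with sprintf formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# micrometres -> pixels for a given physical scale
um_to_px <- function(um, um_per_pixel) {
  stopifnot(um_per_pixel > 0)
  um / um_per_pixel
}

# odd-sized disc structuring element; radius in pixels (0 -> 1x1 identity)
disc_kernel <- function(radius_px) {
  r <- max(0L, as.integer(round(radius_px)))
  if (r == 0L) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# binary morphological reconstruction by dilation: grow `marker` inside `mask`
# until stable. Both logical matrices; 8-connectivity via 3x3 kernel.
binary_reconstruct <- function(marker, mask) {
  stopifnot(identical(dim(marker), dim(mask)))
  marker <- marker & mask
  kern <- matrix(1, 3, 3)
  repeat {
    grown <- EBImage::dilate(EBImage::Image(marker * 1), kern) > 0.5
    grown <- grown & mask
    if (identical(grown, marker)) break
    marker <- grown
  }
  marker
}

# centroids (row, col) and pixel areas of a positive-integer label matrix
label_stats <- function(label_mask) {
  labs <- sort(unique(as.vector(label_mask)))
  labs <- labs[labs > 0]
  if (length(labs) == 0) {
    return(list(labels = integer(0),
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                areas_px = integer(0)))
  }
  idx <- which(label_mask > 0, arr.ind = TRUE)
  vals <- label_mask[label_mask > 0]
  f <- factor(vals, levels = labs)           # numeric-sorted levels
  rs <- as.numeric(tapply(idx[, 1], f, mean))
  cs <- as.numeric(tapply(idx[, 2], f, mean))
  ar <- tabulate(as.integer(f), nbins = length(labs))
  list(labels = as.integer(labs),
       centroids = cbind(row = rs, col = cs),
       areas_px = as.integer(ar))
}
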