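#' Binary segmentation mask
#'
#' @param pixels matrix of 0/1 values, same shape as the source image.
#' @param px_size_um pixel size in micrometres.
#' @param role one of `"root_with_hairs"`, `"root_body"`, `"hairs_only"`, or
#'   `NA` for intermediate masks.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, px_size_um, role = NA_character_) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (min(pixels) < 0 || max(pixels) > 1 || any(pixels != as.integer(pixels)))
    stop("mask values must be strictly 0/1")
  if (!is.na(role) && !role %in% c("root_with_hairs", "root_body", "hairs_only"))
    stop("unknown mask role: ", role)
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 px_size_um = as.numeric(px_size_um), role = role),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, role = %s, %d fg px\n",
              nrow(x$pixels), ncol(x$pixels), x$px_size_um, x$role,
              sum(x$pixels)))
  invisible(x)
}

#' Segmentation configuration
#'
#' Bundles the local-threshold and morphological-smoothing parameters for
#' [build_masks]. Defaults follow the published workflow: Bernsen radius 5 px
#' with contrast threshold 15 (8-bit scale) for the root+hairs mask,
#' Phansalkar radius 100 px with the method's published constants
#' (k = 0.25, r = 0.5, p = 2, q = 10) for the root body, smoothing by
#' 5 dilate/erode for the hairs mask and 10 dilate/erode closing followed by
#' a 12-iteration opening for the body.
#'
#' @param bernsen_radius,phansalkar_radius local neighbourhood radii (px,
#'   >= 1).
#' @param bernsen_contrast Bernsen local-contrast threshold (intensity units
#'   on the image's bit-depth scale).
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q dimensionless
#'   Phansalkar constants (r is the normalisation of the local standard
#'   deviation).
#' @param smooth_iters_hairs dilate/erode iterations for the root+hairs mask.
#' @param smooth_iters_body_close dilate/erode (closing) iterations for the
#'   root-body mask.
#' @param smooth_iters_body_open erode/dilate (opening) iterations that strip
#'   the hairs off the root-body mask.
#' @param fill_hole_max_px only fill interior holes of at most this many
#'   pixels (`Inf` fills every interior hole). A finite cap keeps dense
#'   inter-hair channels, enclosed by bent hairs crossing their neighbours,
#'   from being flooded as "holes".
#' @param dark_objects TRUE when structures are darker than the background
#'   (brightfield); FALSE for fluorescence-like polarity.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(bernsen_radius = 5, bernsen_contrast = 15,
                                phansalkar_radius = 100, phansalkar_k = 0.25,
                                phansalkar_r = 0.5, phansalkar_p = 2,
                                phansalkar_q = 10,
                                smooth_iters_hairs = 5,
                                smooth_iters_body_close = 10,
                                smooth_iters_body_open = 12,
                                fill_hole_max_px = Inf,
                                dark_objects = TRUE) {
  if (bernsen_radius < 1 || phansalkar_radius < 1) stop("radii must be >= 1")
  if (smooth_iters_hairs < 0 || smooth_iters_body_close < 0 ||
      smooth_iters_body_open < 0) stop("iteration counts must be >= 0")
  structure(list(bernsen_radius = bernsen_radius,
                 bernsen_contrast = bernsen_contrast,
                 phansalkar_radius = phansalkar_radius,
                 phansalkar_k = phansalkar_k, phansalkar_r = phansalkar_r,
                 phansalkar_p = phansalkar_p, phansalkar_q = phansalkar_q,
                 smooth_iters_hairs = smooth_iters_hairs,
                 smooth_iters_body_close = smooth_iters_body_close,
                 smooth_iters_body_open = smooth_iters_body_open,
                 fill_hole_max_px = fill_hole_max_px,
                 dark_objects = isTRUE(dark_objects)),
            class = "segmentation_config")
}

#' Derive a segmentation configuration from physical scales
#'
#' The pixel-denominated segmentation settings (threshold radii, smoothing
#' iteration counts) are tied to the acquisition resolution: a closing that
#' nicely smooths a root outline at 0.65 um/px will bridge the gaps between
#' neighbouring hairs at 2.5 um/px. This constructor derives them from the
#' physical scene scales instead: the Bernsen radius spans about one hair
#' diameter, the Phansalkar radius about one root width (so its window always
#' sees background next to the root), the root+hairs smoothing stays well
#' below the inter-hair gap, and the body opening exceeds the hair diameter
#' (so it strips hairs but not the root body).
#'
#' @param px_size_um pixel size of the images to segment.
#' @param hair_width_um typical hair diameter.
#' @param root_width_um typical root body width.
#' @param ... further arguments passed to [segmentation_config].
#' @return A [segmentation_config].
#' @export
segmentation_config_for <- function(px_size_um, hair_width_um = 12,
                                    root_width_um = 120, ...) {
  hair_px <- hair_width_um / px_size_um
  segmentation_config(
    bernsen_radius = max(2, round(hair_px)),
    phansalkar_radius = max(10, round(root_width_um / px_size_um)),
    smooth_iters_hairs = max(1, round(hair_px / 4)),
    # closing must stay well below the inter-hair gap or hairs fuse into a
    # slab the opening cannot remove; opening must exceed the hair diameter
    # plus the ~2 px widening the threshold adds on each side
    smooth_iters_body_close = 1,
    smooth_iters_body_open = floor(hair_px / 2) + 4,
    fill_hole_max_px = round((3 * hair_px)^2),
    ...)
}

.disc <- function(radius) EBImage::makeBrush(2 * as.integer(radius) + 1, "disc")
.box3 <- function() EBImage::makeBrush(3, "box")

# binary dilation/erosion with a (2n+1) box structuring element, identical
# to n iterated 3x3 box operations but O(n_pixels); windows shrink at the
# image border (out-of-bounds pixels are ignored, as in the ImageJ ops)
.box_dilate <- function(m, n)
  matrix(as.integer(.box_sum_cpp(m * 1.0, as.integer(n)) > 0.5), nrow(m))
.box_erode <- function(m, n) {
  cnt <- .box_sum_cpp(matrix(1.0, nrow(m), ncol(m)), as.integer(n))
  matrix(as.integer(.box_sum_cpp(m * 1.0, as.integer(n)) > cnt - 0.5), nrow(m))
}

# local mean and sd over a disc of radius r (dx^2 + dy^2 <= r^2);
# borders handled by edge replication
.disc_stats <- function(x, r) {
  n1 <- nrow(x); n2 <- ncol(x)
  xp <- x[c(rep(1, r), seq_len(n1), rep(n1, r)),
          c(rep(1, r), seq_len(n2), rep(n2, r))]
  area <- sum(2 * floor(sqrt(pmax(r^2 - (-r:r)^2, 0))) + 1)
  keep1 <- r + seq_len(n1); keep2 <- r + seq_len(n2)
  s2 <- .disc_sum2_cpp(xp, as.integer(r))
  mu <- s2[[1]][keep1, keep2] / area
  m2 <- s2[[2]][keep1, keep2] / area
  list(mean = mu, sd = sqrt(pmax(m2 - mu^2, 0)))
}

# fill interior holes: 4-connected background components not touching the
# image border, optionally only those of at most max_px pixels
.fill_holes <- function(m, max_px = Inf) {
  lab <- EBImage::bwlabel(1L - m)
  nlab <- max(lab)
  if (nlab == 0) return(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  fill <- setdiff(which(sizes <= max_px), border)
  if (length(fill) > 0) m[lab %in% fill] <- 1L
  m
}

#' Local adaptive thresholding (Bernsen / Phansalkar)
#'
#' Bernsen: with local minimum m and maximum M in a disk of the configured
#' radius, the local contrast is c = M - m and the midgrey is (m + M)/2. When
#' c >= the contrast threshold, a pixel is foreground iff its intensity is on
#' the object side of the midgrey; in low-contrast neighbourhoods (c below
#' the threshold) the whole neighbourhood is classified by comparing the
#' midgrey against half the dynamic range.
#'
#' Phansalkar: on intensities normalised to \[0, 1\], the local threshold is
#' t = mean * (1 + p * exp(-q * mean) + k * (sd/r - 1)) with the mean and
#' standard deviation taken over the disk; a pixel is foreground iff it is on
#' the object side of t.
#'
#' `dark_objects = TRUE` flips the object side of the comparison while the
#' local statistics are computed on the original intensities (the behaviour
#' of the ImageJ Auto Local Threshold implementations): for Bernsen,
#' foreground becomes intensity <= midgrey (low-contrast neighbourhoods:
#' midgrey <= half range); for Phansalkar, foreground becomes intensity <= t.
#' For Bernsen this is exactly equivalent to inverting the image and
#' thresholding bright objects; Phansalkar's threshold formula is not
#' symmetric under intensity inversion, so there the flip is the method's
#' dark-object semantics rather than an exact mirror.
#'
#' @param img an [intensity_image].
#' @param method `"bernsen"` or `"phansalkar"`.
#' @param cfg a [segmentation_config].
#' @return A [binary_mask] (role `NA`).
#' @export
local_threshold <- function(img, method = c("bernsen", "phansalkar"),
                            cfg = segmentation_config()) {
  stopifnot(inherits(img, "intensity_image"))
  method <- match.arg(method)
  maxval <- 2^img$bit_depth - 1
  r <- if (method == "bernsen") cfg$bernsen_radius else cfg$phansalkar_radius
  if (r >= min(dim(img$pixels)) / 2)
    stop("threshold radius ", r, " too large for image of size ",
         paste(dim(img$pixels), collapse = "x"))
  x <- img$pixels / maxval                      # work in [0, 1]
  dark <- cfg$dark_objects

  if (method == "bernsen") {
    mn <- .disc_minmax_cpp(x, as.integer(r), FALSE)
    mx <- .disc_minmax_cpp(x, as.integer(r), TRUE)
    mid <- (mn + mx) / 2
    contrast <- (mx - mn) * maxval              # back on intensity scale
    fg <- if (dark)
      ifelse(contrast >= cfg$bernsen_contrast, x <= mid, mid <= 0.5)
    else
      ifelse(contrast >= cfg$bernsen_contrast, x >= mid, mid >= 0.5)
  } else {
    st <- .disc_stats(x, as.integer(r))
    t <- st$mean * (1 + cfg$phansalkar_p * exp(-cfg$phansalkar_q * st$mean) +
                      cfg$phansalkar_k * (st$sd / cfg$phansalkar_r - 1))
    fg <- if (dark) x <= t else x > t
  }
  binary_mask(matrix(as.integer(fg), nrow(fg)), img$px_size_um)
}

#' Morphological smoothing of a binary mask
#'
#' Applies `n_dilate` dilations then `n_erode` erosions with a fixed 3x3
#' square structuring element, optionally followed by hole filling (interior
#' background components not connected to the image border become
#' foreground).
#'
#' @param mask a [binary_mask].
#' @param n_dilate,n_erode iteration counts (>= 0).
#' @param fill fill interior holes after the dilate/erode sequence (holes
#'   are 4-connected background components not touching the image border).
#' @param fill_max_px only fill holes of at most this many pixels.
#' @return A [binary_mask] with the same calibration and role.
#' @export
smooth_mask <- function(mask, n_dilate = 0, n_erode = 0, fill = FALSE,
                        fill_max_px = Inf) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$pixels
  # n iterations of a 3x3 box dilation/erosion equal one pass with a
  # (2n+1) box structuring element
  if (n_dilate > 0) m <- .box_dilate(m, n_dilate)
  if (n_erode > 0) m <- .box_erode(m, n_erode)
  if (fill) m <- .fill_holes(m, fill_max_px)
  binary_mask(matrix(as.integer(m > 0), nrow(m)), mask$px_size_um, mask$role)
}

# retain only the largest 4-connected foreground component
.keep_largest <- function(m) {
  lab <- EBImage::bwlabel(m)
  if (max(lab) <= 1) return(m)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(m))
}

#' Segment root, root body, and hairs from a root-tip image
#'
#' Produces the three co-registered masks of the workflow:
#' \describe{
#'   \item{root_with_hairs}{Bernsen local threshold, smoothed by
#'     `smooth_iters_hairs` dilate/erode iterations plus hole filling.}
#'   \item{root_body}{Phansalkar local threshold, closed by
#'     `smooth_iters_body_close` dilate/erode iterations with hole filling,
#'     then opened by `smooth_iters_body_open` erode/dilate iterations (this
#'     strips structures thinner than the opening, i.e. the hairs), then
#'     restricted to the root+hairs mask.}
#'   \item{hairs_only}{set difference root_with_hairs AND NOT root_body.}
#' }
#' Both the root+hairs and root-body masks are reduced to their largest
#' connected component, which stands in for the interactive particle/ROI
#' cleanup of the original workflow. By construction
#' `hairs_only & root_body == 0` and `hairs_only <= root_with_hairs`.
#'
#' @param img an [intensity_image].
#' @param cfg a [segmentation_config].
#' @param keep_largest retain only the largest connected component of the
#'   root+hairs and root-body masks (default TRUE).
#' @return A list with elements `root_with_hairs`, `root_body`, `hairs_only`
#'   (all [binary_mask]).
#' @export
build_masks <- function(img, cfg = segmentation_config(), keep_largest = TRUE) {
  stopifnot(inherits(img, "intensity_image"))
  rw <- smooth_mask(local_threshold(img, "bernsen", cfg),
                    n_dilate = cfg$smooth_iters_hairs,
                    n_erode = cfg$smooth_iters_hairs, fill = TRUE,
                    fill_max_px = cfg$fill_hole_max_px)
  if (keep_largest) rw$pixels <- .keep_largest(rw$pixels)

  body <- smooth_mask(local_threshold(img, "phansalkar", cfg),
                      n_dilate = cfg$smooth_iters_body_close,
                      n_erode = cfg$smooth_iters_body_close, fill = TRUE,
                      fill_max_px = cfg$fill_hole_max_px)
  nop <- cfg$smooth_iters_body_open
  body <- smooth_mask(body, n_dilate = 0, n_erode = nop, fill = FALSE)
  body <- smooth_mask(body, n_dilate = nop, n_erode = 0, fill = FALSE)
  body$pixels <- body$pixels * rw$pixels        # clear background outside root
  if (keep_largest) body$pixels <- .keep_largest(body$pixels)
  if (sum(body$pixels) == 0)
    stop("no root detected: root-body mask is empty")

  hairs <- binary_mask(rw$pixels * (1L - body$pixels), img$px_size_um,
                       "hairs_only")
  rw$role <- "root_with_hairs"
  body$role <- "root_body"
  list(root_with_hairs = rw, root_body = body, hairs_only = hairs)
}
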