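#' Intensity image with spatial calibration
#'
#' Container for a single-channel grayscale image as used throughout the
#' pipeline. Pixels are stored as a numeric matrix indexed `[row, col]`
#' (row = y, col = x, origin top-left), with integer intensities in
#' `[0, 2^bit_depth - 1]` and a pixel size in micrometres.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bit_depth 8 or 16.
#' @param px_size_um pixel size in micrometres per pixel (> 0).
#' @return An object of class `intensity_image` with fields `pixels`,
#'   `bit_depth` and `px_size_um`.
#' @export
intensity_image <- function(pixels, bit_depth = 8L, px_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 32 || ncol(pixels) < 32)
    stop("image must be at least 32x32 pixels")
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  if (missing(px_size_um) || is.null(px_size_um) || is.na(px_size_um))
    stop("missing calibration: px_size_um must be supplied")
  if (!is.finite(px_size_um) || px_size_um <= 0)
    stop("px_size_um must be finite and positive")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         px_size_um = as.numeric(px_size_um)),
    class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %d-bit, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$px_size_um))
  invisible(x)
}

#' Read a root-tip image from a TIFF file
#'
#' Reads a single- or multi-page grayscale TIFF. Multi-page stacks are
#' combined according to `plane_policy`: `"sum"` performs a per-pixel sum
#' projection followed by a linear min-max rescale to the 8-bit range
#' (constant images map to 0); `"single:<i>"` selects page `i` unchanged.
#'
#' Calibration is taken from `px_size_um` when supplied, otherwise from the
#' TIFF resolution tags (inch or cm units); if neither is available an error
#' names the missing field.
#'
#' @param path path to a TIFF file.
#' @param plane_policy `"sum"` or `"single:<index>"`.
#' @param px_size_um optional pixel size in micrometres per pixel; overrides
#'   any TIFF resolution tag.
#' @return An [intensity_image].
#' @export
load_image <- function(path, plane_policy = "sum", px_size_um = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (length(pages) == 0) stop("zero-size image: ", path)
  if (length(dim(pages[[1]])) > 2) stop("only single-channel images are supported")
  if (any(vapply(pages, function(p) length(p) == 0, logical(1))))
    stop("zero-size image: ", path)

  if (is.null(px_size_um)) px_size_um <- .tiff_px_size(pages[[1]])
  if (is.null(px_size_um))
    stop("missing calibration: supply px_size_um (no usable TIFF resolution tag)")

  bits <- attr(pages[[1]], "bits.per.sample")
  bit_depth <- if (!is.null(bits) && bits > 8) 16L else
    if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L

  if (identical(plane_policy, "sum")) {
    if (length(pages) == 1) {
      px <- pages[[1]]
    } else {
      s <- Reduce(`+`, lapply(pages, function(p) matrix(as.numeric(p), nrow(p))))
      rng <- range(s)
      px <- if (rng[2] > rng[1])
        round((s - rng[1]) / (rng[2] - rng[1]) * 255) else s * 0
      bit_depth <- 8L
    }
  } else if (grepl("^single:[0-9]+$", plane_policy)) {
    i <- as.integer(sub("^single:", "", plane_policy))
    if (i < 1 || i > length(pages))
      stop("plane_policy index ", i, " out of range (", length(pages), " pages)")
    px <- pages[[i]]
  } else stop("plane_policy must be 'sum' or 'single:<index>'")

  px <- matrix(as.numeric(px), nrow(px))
  intensity_image(px, bit_depth = bit_depth, px_size_um = px_size_um)
}

# pixel size (um) from TIFF resolution tags, or NULL
.tiff_px_size <- function(page) {
  res <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(res) || !is.numeric(res) || res <= 0) return(NULL)
  if (is.null(unit)) return(NULL)
  um_per_unit <- switch(as.character(unit), inch = 25400, cm = 10000, NULL)
  if (is.null(um_per_unit)) return(NULL)
  um_per_unit / res
}

#' Root-hair length profile
#'
#' The unit of exchange between the imaging and fitting halves of the
#' pipeline: a table of windowed RH length measurements with their distance
#' from the root tip, the root side they were measured on, and 0/1 annotation
#' flags.
#'
#' @param points data.frame with columns `distance_um`, `length_um`, `side`
#'   (`"left"`/`"right"`) and optionally `flag_<label>` 0/1 columns; rows must
#'   be ordered by distance within each side.
#' @param w_um measuring-window width in micrometres (> 0).
#' @param interval_k max-filter interval (number of consecutive windows,
#'   >= 1).
#' @param scan_range_um numeric length-2, scan start and end (micrometres).
#' @return An object of class `rh_profile`.
#' @export
rh_profile <- function(points, w_um, interval_k = 1L,
                       scan_range_um = c(0, Inf)) {
  stopifnot(is.data.frame(points))
  need <- c("distance_um", "length_um", "side")
  if (!all(need %in% names(points)))
    stop("points must have columns: ", paste(need, collapse = ", "))
  if (!all(points$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (any(points$distance_um < 0) || any(points$length_um < 0))
    stop("distances and lengths must be non-negative")
  for (s in unique(points$side)) {
    d <- points$distance_um[points$side == s]
    if (is.unsorted(d)) stop("points must be ordered by distance within side ", s)
  }
  if (!is.numeric(w_um) || w_um <= 0) stop("w_um must be > 0")
  if (interval_k < 1) stop("interval_k must be >= 1")
  fl <- setdiff(names(points), need)
  if (length(fl) > 0) {
    bad <- fl[!vapply(fl, function(f) all(points[[f]] %in% c(0, 1)), logical(1))]
    if (length(bad) > 0) stop("flag columns must be 0/1: ", paste(bad, collapse = ", "))
  }
  structure(list(points = points, w_um = as.numeric(w_um),
                 interval_k = as.integer(interval_k),
                 scan_range_um = as.numeric(scan_range_um)),
            class = "rh_profile")
}

#' @export
print.rh_profile <- function(x, ...) {
  cat(sprintf("<rh_profile> %d points (%d left / %d right), w = %.3g um, interval k = %d\n",
              nrow(x$points), sum(x$points$side == "left"),
              sum(x$points$side == "right"), x$w_um, x$interval_k))
  invisible(x)
}

#' Write / read an RH length profile as CSV
#'
#' The CSV carries the profile settings in `# key=value` header comments and
#' one row per measurement with columns `distance_um`, `length_um`, `side`
#' and one 0/1 column per annotation label (0 = no annotation, 1 = annotation
#' present). `read_profile(write_profile(p))` is a field-for-field identity
#' (numeric values are written with full precision).
#'
#' @param profile an [rh_profile]; must be non-empty.
#' @param path output (input) CSV path.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns an
#'   [rh_profile].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "rh_profile"))
  if (nrow(profile$points) == 0) stop("profile is empty")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rhsizer profile v1",
               sprintf("# w_um=%.15g", profile$w_um),
               sprintf("# interval_k=%d", profile$interval_k),
               sprintf("# scan_start_um=%.15g", profile$scan_range_um[1]),
               sprintf("# scan_end_um=%.15g", profile$scan_range_um[2])), con)
  utils::write.table(format(profile$points, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  kv <- list()
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)=([-0-9.eE+Inf]+)", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (length(body) < 2) stop("malformed profile CSV (no data rows): ", path)
  nf <- length(strsplit(body[1], ",", fixed = TRUE)[[1]])
  cnt <- vapply(strsplit(body, ",", fixed = TRUE), length, integer(1))
  bad <- which(cnt != nf)
  if (length(bad) > 0)
    stop(sprintf("malformed profile CSV at line %d of '%s': expected %d fields, got %d",
                 setdiff(seq_along(lines), hdr)[bad[1]], path, nf, cnt[bad[1]]))
  pts <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  for (req in c("w_um", "interval_k", "scan_start_um", "scan_end_um"))
    if (is.null(kv[[req]])) stop("malformed profile CSV: missing header '", req, "'")
  rh_profile(pts, w_um = kv$w_um, interval_k = kv$interval_k,
             scan_range_um = c(kv$scan_start_um, kv$scan_end_um))
}

#' Polygonal annotation region
#'
#' A labelled polygon, drawn over the original image, marking a zone to be
#' flagged in the profile (for example an artefact such as a bubble, or a
#' root side with systematically shorter hairs).
#'
#' @param vertices numeric matrix (n x 2) of (x, y) pixel coordinates,
#'   n >= 3; the polygon must have non-zero area.
#' @param label free-text category name.
#' @return An object of class `annotation_region`.
#' @export
annotation_region <- function(vertices, label) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("annotation polygon needs >= 3 (x, y) vertices")
  x <- vertices[, 1]; y <- vertices[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area == 0) stop("annotation polygon has zero area")
  if (!is.character(label) || length(label) != 1 || nchar(label) == 0)
    stop("label must be a non-empty string")
  structure(list(vertices = vertices, label = label), class = "annotation_region")
}

#' Read annotation regions from sidecar JSON
#'
#' The sidecar file is a JSON array of objects
#' `{"label": "...", "vertices": [[x, y], ...]}` in pixel coordinates of the
#' original (unstraightened) image.
#'
#' @param path JSON file path.
#' @return A list of [annotation_region] objects.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, as.numeric))
    annotation_region(v, r$label)
  })
}

#' Write fitted and derived parameters as JSON
#'
#' @param x a named list (e.g. fit results from [two_step_fit] plus
#'   [derive_parameters] output).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path) {
  jsonlite::write_json(.unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_deep) else unclass(x)
}
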