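#' Sliding-window RH length scan of a straightened mask
#'
#' Slides a rectangular measuring window of width `w_um` along the
#' straightened hairs-only mask, stepping by exactly its own width
#' (non-overlapping windows). For each window and each root side (rows above
#' vs below the RML row), the thresholded area A is the foreground pixel
#' count times the pixel area, and the RH length estimate is L = A / w. The
#' distance d of each measurement is the arc length of the window centre
#' from the root tip.
#'
#' @param sm a [straightened_mask].
#' @param w_um window width in micrometres (must convert to >= 1 px; the
#'   realised width is the nearest whole number of pixels).
#' @param range_um numeric length-2 scan range (start, end) in micrometres
#'   from the tip; clipped to the straightened extent.
#' @param px_size_um pixel size; defaults to the mask's calibration.
#' @return data.frame with columns `distance_um`, `length_um`, `side`,
#'   ordered by distance within side.
#' @export
scan_windows <- function(sm, w_um, range_um = c(0, Inf),
                         px_size_um = sm$px_size_um) {
  stopifnot(inherits(sm, "straightened_mask"))
  if (range_um[2] < range_um[1]) stop("scan range end before start")
  px <- px_size_um
  w_px <- round(w_um / px)
  if (w_px < 1) stop("window width ", w_um, " um is below one pixel")
  nc <- ncol(sm$pixels)
  c_start <- max(1L, floor(range_um[1] / px) + 1L)
  c_end <- min(nc, if (is.finite(range_um[2])) floor(range_um[2] / px) else nc)
  if (c_end - c_start + 1 < w_px)
    return(data.frame(distance_um = numeric(0), length_um = numeric(0),
                      side = character(0), stringsAsFactors = FALSE))
  starts <- seq(c_start, c_end - w_px + 1L, by = w_px)

  ctr <- sm$center_row
  top <- sm$pixels[seq_len(ctr - 1), , drop = FALSE]        # left side
  bot <- sm$pixels[seq(ctr + 1, nrow(sm$pixels)), , drop = FALSE]
  colL <- colSums(top); colR <- colSums(bot)
  block_sum <- function(colcounts) {
    vapply(starts, function(c0) sum(colcounts[c0:(c0 + w_px - 1)]), numeric(1))
  }
  d <- ((starts - 1) + w_px / 2) * px
  L <- function(counts) counts / w_px * px     # (count * px^2) / (w_px * px)
  out <- rbind(
    data.frame(distance_um = d, length_um = L(block_sum(colL)), side = "left",
               stringsAsFactors = FALSE),
    data.frame(distance_um = d, length_um = L(block_sum(colR)), side = "right",
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Interval max filter on a raw window scan
#'
#' Partitions the consecutive windows of each side into blocks of `k` (the
#' last block may be shorter) and keeps, per block, the maximal length
#' estimate together with the distance of its argmax window (ties broken
#' toward the smaller distance). This makes the profile robust to bald spots
#' and non-orthogonal hairs: within each interval, the best-positioned hair
#' dominates.
#'
#' @param raw data.frame from [scan_windows] (columns `distance_um`,
#'   `length_um`, `side`).
#' @param k block size (>= 1); `k = 1` is the identity.
#' @return data.frame with the same columns, one row per block and side.
#' @export
max_filter <- function(raw, k) {
  if (k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  res <- lapply(split(raw, raw$side), function(df) {
    df <- df[order(df$distance_um), , drop = FALSE]
    blk <- (seq_len(nrow(df)) - 1L) %/% k
    picks <- vapply(split(seq_len(nrow(df)), blk), function(ix) {
      ix[which.max(df$length_um[ix])]   # first max = smaller distance
    }, integer(1))
    df[picks, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Project annotation regions onto the root median line
#'
#' For every vertex of every polygon, finds the nearest point on the RML
#' (perpendicular projection onto each polyline segment, clamped to the
#' segment ends) and converts it to arc length from the tip; a region's
#' interval is the min-max span of its vertices' arc lengths.
#'
#' @param regions list of [annotation_region] objects.
#' @param rml a [medial_line].
#' @return data.frame with columns `label`, `d_min_um`, `d_max_um`.
#' @export
project_annotations <- function(regions, rml) {
  stopifnot(inherits(rml, "medial_line"))
  if (length(regions) == 0)
    return(data.frame(label = character(0), d_min_um = numeric(0),
                      d_max_um = numeric(0), stringsAsFactors = FALSE))
  V <- rml$vertices
  arc <- rml$arc_length_um
  p1 <- V[-nrow(V), , drop = FALSE]
  dp <- diff(V)
  len2 <- rowSums(dp^2)
  project_vertex <- function(v) {
    t <- pmin(1, pmax(0, ((v[1] - p1[, 1]) * dp[, 1] +
                            (v[2] - p1[, 2]) * dp[, 2]) / len2))
    qx <- p1[, 1] + t * dp[, 1]; qy <- p1[, 2] + t * dp[, 2]
    d2 <- (v[1] - qx)^2 + (v[2] - qy)^2
    i <- which.min(d2)
    arc[i] + t[i] * (arc[i + 1] - arc[i])
  }
  rows <- lapply(regions, function(r) {
    stopifnot(inherits(r, "annotation_region"))
    a <- apply(r$vertices, 1, project_vertex)
    data.frame(label = r$label, d_min_um = min(a), d_max_um = max(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag profile points lying inside annotation intervals
#'
#' Adds one 0/1 column `flag_<label>` per annotation label: a point's flag is
#' 1 iff its distance lies inside any interval of that label (intervals are
#' closed). No points are removed; exclusion happens at fit time.
#'
#' @param points data.frame of profile points (from [max_filter] or
#'   [scan_windows]).
#' @param intervals data.frame from [project_annotations].
#' @return `points` with the flag columns appended.
#' @export
flag_profile <- function(points, intervals) {
  if (nrow(intervals) == 0) return(points)
  for (lab in unique(intervals$label)) {
    iv <- intervals[intervals$label == lab, , drop = FALSE]
    hit <- rep(FALSE, nrow(points))
    for (j in seq_len(nrow(iv)))
      hit <- hit | (points$distance_um >= iv$d_min_um[j] &
                      points$distance_um <= iv$d_max_um[j])
    points[[paste0("flag_", lab)]] <- as.integer(hit)
  }
  points
}

#' Measure an RH length profile from a straightened mask
#'
#' Convenience wrapper: [scan_windows], [max_filter], annotation projection
#' and flagging, assembled into an [rh_profile].
#'
#' @param sm a [straightened_mask].
#' @param w_um window width (micrometres; default 8, about half a hair
#'   diameter).
#' @param interval_k max-filter interval (default 10 windows).
#' @param range_um scan range in micrometres from the tip.
#' @param regions optional list of [annotation_region].
#' @param rml the [medial_line] used to straighten (required when `regions`
#'   are given).
#' @return An [rh_profile].
#' @export
measure_profile <- function(sm, w_um = 8, interval_k = 10,
                            range_um = c(0, 10000), regions = list(),
                            rml = NULL) {
  raw <- scan_windows(sm, w_um, range_um)
  pts <- max_filter(raw, interval_k)
  if (length(regions) > 0) {
    if (is.null(rml)) stop("annotation projection requires the rml")
    pts <- flag_profile(pts, project_annotations(regions, rml))
  }
  pts <- pts[order(pts$side, pts$distance_um), , drop = FALSE]
  rownames(pts) <- NULL
  rh_profile(pts, w_um = w_um, interval_k = interval_k,
             scan_range_um = range_um)
}
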