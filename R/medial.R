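#' Root median line (RML)
#'
#' Ordered polyline along the root axis. The first vertex is the root tip;
#' `arc_length_um` is the cumulative arc length from the tip (strictly
#' increasing, 0 at the tip).
#'
#' @param vertices numeric matrix (n x 2) of (x, y) pixel coordinates, n >= 2.
#' @param px_size_um pixel size in micrometres.
#' @return An object of class `medial_line` with fields `vertices`,
#'   `arc_length_um`, `px_size_um`.
#' @export
medial_line <- function(vertices, px_size_um) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  if (nrow(vertices) < 2 || ncol(vertices) != 2)
    stop("medial line needs >= 2 (x, y) vertices")
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (any(seg <= 0)) stop("medial line has duplicated consecutive vertices")
  structure(list(vertices = vertices,
                 arc_length_um = c(0, cumsum(seg)) * px_size_um,
                 px_size_um = as.numeric(px_size_um)),
            class = "medial_line")
}

#' @export
print.medial_line <- function(x, ...) {
  cat(sprintf("<medial_line> %d vertices, arc length %.1f um (tip at x=%g, y=%g)\n",
              nrow(x$vertices), max(x$arc_length_um),
              x$vertices[1, 1], x$vertices[1, 2]))
  invisible(x)
}

#' Skeletonize a binary mask to unit width (Zhang-Suen thinning)
#'
#' Iterative two-subpass thinning producing an 8-connected skeleton of
#' approximately one-pixel width. Used internally by [extract_rml]; exported
#' for QC.
#'
#' @param mask a [binary_mask] or 0/1 matrix.
#' @return A 0/1 integer matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  stopifnot(all(m %in% c(0L, 1L)))
  full_dim <- dim(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(0L, full_dim[1], full_dim[2]))
  r0 <- range(idx[, 1]); c0 <- range(idx[, 2])
  sub <- matrix(0L, diff(r0) + 3, diff(c0) + 3)   # 1-px zero pad
  sub[cbind(idx[, 1] - r0[1] + 2, idx[, 2] - c0[1] + 2)] <- 1L
  sub <- .zs_thin_cpp(sub)
  out <- matrix(0L, full_dim[1], full_dim[2])
  ii <- which(sub == 1L, arr.ind = TRUE)
  out[cbind(ii[, 1] + r0[1] - 2, ii[, 2] + c0[1] - 2)] <- 1L
  out
}

# skeleton pixel graph: vertices = foreground pixels, edges between
# 8-neighbours weighted 1 (orthogonal) / sqrt(2) (diagonal)
.skeleton_graph <- function(skel) {
  pix <- which(skel == 1L)
  if (length(pix) == 0) stop("empty skeleton")
  nr <- nrow(skel)
  id <- integer(length(skel)); id[pix] <- seq_along(pix)
  rr <- (pix - 1) %% nr + 1; cc <- (pix - 1) %/% nr + 1
  edges <- NULL; w <- NULL
  for (d in list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skel)
    nb <- integer(length(pix))
    nb[ok] <- id[(c2[ok] - 1) * nr + r2[ok]]
    has <- which(nb > 0)
    if (length(has) > 0) {
      edges <- c(edges, rbind(seq_along(pix)[has], nb[has]))
      w <- c(w, rep(d[3], length(has)))
    }
  }
  g <- igraph::make_empty_graph(n = length(pix), directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$weight <- w
  list(g = g, x = cc, y = rr)
}

#' Extract the root median line from the root-body mask
#'
#' Skeletonizes the root-body mask, finds the pair of skeleton endpoints with
#' the greatest geodesic distance along the skeleton (steps weighted 1
#' orthogonal, sqrt(2) diagonal), and returns that longest path as a
#' simplified polyline with the root tip as its first vertex.
#'
#' The tip end is chosen by `tip_rule`: `"auto"` picks the endpoint whose
#' surrounding window contains the least hairs-only area (the tip region is
#' bald); `"end:left"` / `"end:right"` / `"end:top"` / `"end:bottom"` pick
#' the endpoint nearest the named image border.
#'
#' @param root_body a [binary_mask] with exactly one connected foreground
#'   component of at least 100 px.
#' @param simplify_stride keep every `simplify_stride`-th skeleton pixel plus
#'   both endpoints (default 200, clamped so at least 4 vertices survive).
#' @param tip_rule `"auto"` or `"end:<left|right|top|bottom>"`.
#' @param hairs_only optional [binary_mask] of hairs, required for
#'   `tip_rule = "auto"`.
#' @param tip_window_px half-size of the square window used by the auto tip
#'   rule.
#' @return A [medial_line].
#' @export
extract_rml <- function(root_body, simplify_stride = 200, tip_rule = "auto",
                        hairs_only = NULL, tip_window_px = 150) {
  stopifnot(inherits(root_body, "binary_mask"))
  if (sum(root_body$pixels) == 0) stop("root-body mask is empty")
  if (sum(root_body$pixels) < 100)
    stop("root-body component has fewer than 100 px")

  skel <- skeletonize_mask(root_body)
  sg <- .skeleton_graph(skel)
  # connectivity check (8-connected): thinning preserves component count
  ncomp <- igraph::count_components(sg$g)
  if (ncomp > 1) stop("root-body mask has ", ncomp,
                      " connected components; expected exactly one")
  deg <- igraph::degree(sg$g)
  ends <- which(deg == 1)
  if (length(ends) < 2) stop("skeleton has fewer than 2 endpoints")

  D <- igraph::distances(sg$g, v = ends, to = ends)
  D[!is.finite(D)] <- -1
  best <- which(D == max(D), arr.ind = TRUE)[1, ]
  vp <- igraph::shortest_paths(sg$g, from = ends[best[1]],
                               to = ends[best[2]])$vpath[[1]]
  path <- cbind(x = sg$x[as.integer(vp)], y = sg$y[as.integer(vp)])

  n <- nrow(path)
  stride <- max(1, min(as.integer(simplify_stride), floor((n - 1) / 3)))
  keep <- unique(c(seq(1, n, by = stride), n))
  poly <- path[keep, , drop = FALSE]

  tip_first <- .tip_is_first(poly, tip_rule, hairs_only, tip_window_px,
                             dim(root_body$pixels))
  if (!tip_first) poly <- poly[nrow(poly):1, , drop = FALSE]
  medial_line(poly, root_body$px_size_um)
}

.tip_is_first <- function(poly, tip_rule, hairs_only, win, img_dim) {
  a <- poly[1, ]; b <- poly[nrow(poly), ]
  if (identical(tip_rule, "auto")) {
    if (is.null(hairs_only))
      stop("tip_rule='auto' requires the hairs_only mask")
    h <- if (inherits(hairs_only, "binary_mask")) hairs_only$pixels else hairs_only
    count_near <- function(p) {
      rs <- max(1, round(p[2]) - win):min(nrow(h), round(p[2]) + win)
      cs <- max(1, round(p[1]) - win):min(ncol(h), round(p[1]) + win)
      sum(h[rs, cs])
    }
    return(count_near(a) <= count_near(b))
  }
  side <- sub("^end:", "", tip_rule)
  score <- switch(side,
                  left   = c(a[1], b[1]),
                  right  = c(img_dim[2] - a[1], img_dim[2] - b[1]),
                  top    = c(a[2], b[2]),
                  bottom = c(img_dim[1] - a[2], img_dim[1] - b[2]),
                  stop("tip_rule must be 'auto' or 'end:left|right|top|bottom'"))
  score[1] <= score[2]
}

#' Straightened mask
#'
#' Binary grid whose column index maps to arc length from the root tip
#' (1 px per column) and whose row index maps to the signed normal offset
#' from the RML: the centre row lies on the RML, rows above it (smaller row
#' index) are the "left" side of the tip-to-end direction.
#'
#' @param pixels 0/1 matrix, (2*band_halfwidth_px + 1) rows.
#' @param band_halfwidth_px half of the sampled normal extent (px).
#' @param px_size_um pixel size in micrometres.
#' @return An object of class `straightened_mask` with an additional
#'   `center_row` field.
#' @export
straightened_mask <- function(pixels, band_halfwidth_px, px_size_um) {
  stopifnot(is.matrix(pixels), all(pixels %in% c(0L, 1L)))
  if (nrow(pixels) != 2 * band_halfwidth_px + 1)
    stop("pixels must have 2*band_halfwidth_px + 1 rows")
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels)),
                 band_halfwidth_px = as.integer(band_halfwidth_px),
                 px_size_um = as.numeric(px_size_um),
                 center_row = as.integer(band_halfwidth_px) + 1L),
            class = "straightened_mask")
}

#' Straighten the hairs-only mask along the root median line
#'
#' Resamples the mask in a band around the RML: for each 1-px step of arc
#' length from the tip, the mask is sampled along the local normal at offsets
#' up to `band_halfwidth_px` on both sides using nearest-neighbour lookup,
#' and the result is re-binarized. Normals are perpendicular to the
#' central-difference tangent of the polyline; positive offsets (upper rows)
#' are to the left of the tip-to-end direction (image y-axis pointing down).
#'
#' @param hairs_only a [binary_mask] (any role).
#' @param rml a [medial_line] with the tip first.
#' @param band_halfwidth_px sampled normal half-extent; must exceed the
#'   longest hair plus half the root width (a warning is issued if foreground
#'   touches the band edge).
#' @return A [straightened_mask].
#' @export
straighten <- function(hairs_only, rml, band_halfwidth_px) {
  stopifnot(inherits(hairs_only, "binary_mask"), inherits(rml, "medial_line"))
  px <- rml$px_size_um
  arc_px <- rml$arc_length_um / px
  total <- arc_px[length(arc_px)]
  if (total < 2) stop("RML shorter than 2 px")
  b <- as.integer(band_halfwidth_px)

  s <- seq(0, floor(total))
  xs <- stats::approx(arc_px, rml$vertices[, 1], xout = s)$y
  ys <- stats::approx(arc_px, rml$vertices[, 2], xout = s)$y
  n <- length(s)
  tx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[1:(n - 2)]) / 2, xs[n] - xs[n - 1])
  ty <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[1:(n - 2)]) / 2, ys[n] - ys[n - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  tx <- tx / nrm; ty <- ty / nrm
  nx <- ty; ny <- -tx              # left of travel with y pointing down

  off <- seq(b, -b)                # row 1 = +b (left side on top)
  X <- matrix(xs, 2 * b + 1, n, byrow = TRUE) + off %o% nx
  Y <- matrix(ys, 2 * b + 1, n, byrow = TRUE) + off %o% ny
  ri <- round(Y); ci <- round(X)
  m <- hairs_only$pixels
  ok <- ri >= 1 & ri <= nrow(m) & ci >= 1 & ci <= ncol(m)
  out <- matrix(0L, 2 * b + 1, n)
  out[ok] <- m[(ci[ok] - 1) * nrow(m) + ri[ok]]
  if (sum(out[c(1, nrow(out)), ]) > 0)
    warning("foreground touches the band edge; increase band_halfwidth_px")
  straightened_mask(out, b, px)
}
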