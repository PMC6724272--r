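# Fixtures and independent oracles shared across tests. Everything is built
# in code; no binary fixtures on disk.

# small constant-free intensity image from a matrix (recycled if needed)
make_image <- function(values, nr = 40, nc = 40, px = 1, bit_depth = 8L) {
  intensity_image(matrix(values, nr, nc), bit_depth = bit_depth,
                  px_size_um = px)
}

# straightened mask wrapper around a plain 0/1 matrix (odd row count)
make_straightened <- function(m, px = 1) {
  b <- (nrow(m) - 1) / 2
  straightened_mask(m, band_halfwidth_px = b, px_size_um = px)
}

# profile sampled from the sigmoid, optionally with Gaussian noise
make_sigmoid_profile <- function(L_noise = 10, L_max = 600, d50 = 2500,
                                 delta = 500, n = 100, d_max = 6000,
                                 noise_sd = 0, w_um = 8, interval_k = 1) {
  d <- seq(0, d_max, length.out = n)
  L <- rh_sigmoid(d, L_noise, L_max, d50, delta)
  if (noise_sd > 0) L <- pmax(0, L + rnorm(n, 0, noise_sd))
  pts <- rbind(
    data.frame(distance_um = d, length_um = L, side = "left",
               stringsAsFactors = FALSE),
    data.frame(distance_um = d, length_um = L, side = "right",
               stringsAsFactors = FALSE))
  rh_profile(pts, w_um = w_um, interval_k = interval_k,
             scan_range_um = c(0, d_max))
}

# independent per-pixel disc statistics (dx^2 + dy^2 <= r^2), brute force
brute_disc_stats <- function(m, r, stat = c("min", "max", "mean", "sd")) {
  stat <- match.arg(stat)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dx^2 + dy^2 > r^2) next
      ii <- i + dy; jj <- j + dx
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- switch(stat, min = min(vals), max = max(vals),
                        mean = mean(vals),
                        sd = sqrt(mean(vals^2) - mean(vals)^2))
  }
  out
}

# independent geodesic oracle on a skeleton: Dijkstra over the pixel graph
# (8-neighbours, weight 1 orthogonal / sqrt(2) diagonal), maximum distance
# over all endpoint pairs
brute_longest_geodesic <- function(skel) {
  nr <- nrow(skel)
  pix <- which(skel == 1L)
  id <- integer(length(skel)); id[pix] <- seq_along(pix)
  rr <- (pix - 1) %% nr + 1; cc <- (pix - 1) %/% nr + 1
  nbrs <- vector("list", length(pix))
  wts <- vector("list", length(pix))
  for (k in seq_along(pix)) {
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      i2 <- rr[k] + dy; j2 <- cc[k] + dx
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > ncol(skel)) next
      n2 <- id[(j2 - 1) * nr + i2]
      if (n2 > 0) {
        nbrs[[k]] <- c(nbrs[[k]], n2)
        wts[[k]] <- c(wts[[k]], if (dy != 0 && dx != 0) sqrt(2) else 1)
      }
    }
  }
  deg <- lengths(nbrs)
  ends <- which(deg == 1)
  if (length(ends) < 2) return(NA_real_)
  dijkstra <- function(src) {
    dist <- rep(Inf, length(pix)); dist[src] <- 0
    done <- rep(FALSE, length(pix))
    repeat {
      u <- which(!done & is.finite(dist))
      if (length(u) == 0) break
      u <- u[which.min(dist[u])]
      done[u] <- TRUE
      for (q in seq_along(nbrs[[u]])) {
        v <- nbrs[[u]][q]
        alt <- dist[u] + wts[[u]][q]
        if (alt < dist[v]) dist[v] <- alt
      }
    }
    dist
  }
  best <- 0
  for (e in ends) {
    dd <- dijkstra(e)
    best <- max(best, max(dd[ends][is.finite(dd[ends])]))
  }
  best
}

# random tree-shaped 1-px skeleton drawn as straight segments
random_tree_mask <- function(nr = 80, nc = 80, n_branches = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  draw_seg <- function(m, x0, y0, x1, y1) {
    ns <- max(2, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
    u <- seq(0, 1, length.out = ns)
    xs <- round(x0 + u * (x1 - x0)); ys <- round(y0 + u * (y1 - y0))
    ok <- xs >= 2 & xs <= nc - 1 & ys >= 2 & ys <= nr - 1
    m[cbind(ys[ok], xs[ok])] <- 1L
    m
  }
  x0 <- sample(20:(nc - 20), 1); y0 <- sample(20:(nr - 20), 1)
  pts <- matrix(c(x0, y0), 1, 2)
  for (b in seq_len(n_branches)) {
    src <- pts[sample(nrow(pts), 1), ]
    ang <- runif(1, 0, 2 * pi); len <- runif(1, 25, 40)
    x1 <- src[1] + len * cos(ang); y1 <- src[2] + len * sin(ang)
    m <- draw_seg(m, src[1], src[2], x1, y1)
    pts <- rbind(pts, c(x1, y1))
  }
  # border clipping can strand a branch: keep the trunk's 8-connected
  # component only
  keep <- matrix(FALSE, nr, nc)
  queue <- list(c(y0, x0))
  keep[y0, x0] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dy in -1:1) for (dx in -1:1) {
      i <- p[1] + dy; j <- p[2] + dx
      if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
          m[i, j] == 1L && !keep[i, j]) {
        keep[i, j] <- TRUE
        queue[[length(queue) + 1]] <- c(i, j)
      }
    }
  }
  matrix(as.integer(m == 1L & keep), nr)
}

# compact synthetic scene for fast segmentation/pipeline tests
small_synth_spec <- function(seed = 1, ...) {
  args <- list(L_max = 200, d50 = 800, delta = 200, root_length_um = 2000,
               root_width_um = 90, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_spec, args)
}

# segmentation settings matched to the generator's resolution
synth_seg_cfg <- function(px = 1.5) segmentation_config_for(px)

# independent 3x3 box dilation (iterated), for recall checks
.box_dilate_for_test <- function(m, n) {
  for (i in seq_len(n)) m <- EBImage::dilate(m, EBImage::makeBrush(3, "box"))
  matrix(as.integer(m > 0), nrow(m))
}

# temporary TIFF helper: writes pages (list of 0..255 matrices), returns path
write_tmp_tiff <- function(pages) {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                  bits.per.sample = 8)
  path
}
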