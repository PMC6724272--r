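#' Specification for a synthetic root-tip image
#'
#' Describes a brightfield-like root-tip scene with known ground truth: a
#' dark curved root body on a bright background, with perpendicular dark
#' hairs whose true lengths follow the sigmoid [rh_sigmoid] of distance from
#' the tip. Hairs may be skipped (bald spots), kinked mid-length (bent
#' hairs), and are rendered with multiplicative lognormal length jitter;
#' Gaussian blur and additive intensity noise are applied last.
#'
#' @param L_max,d50,delta truth sigmoid parameters (micrometres); the lower
#'   asymptote of the truth is 0.
#' @param root_width_um root body width.
#' @param root_curvature_radius_um radius of the circular bend of the root
#'   axis; `Inf` gives a straight root.
#' @param root_length_um total root length from the tip.
#' @param hair_spacing_um spacing of hair insertion sites along the root.
#' @param hair_width_um hair diameter.
#' @param bald_prob probability that a hair site is skipped.
#' @param bent_frac fraction of hairs drawn with a mid-length kink.
#' @param length_jitter_sd lognormal sd of the multiplicative length jitter.
#' @param noise_sd additive Gaussian intensity noise sd (8-bit scale).
#' @param blur_sigma_px Gaussian blur sigma in pixels.
#' @param bg_level,fg_level background / structure intensity (8-bit scale).
#' @param px_size_um pixel size of the rendered image.
#' @param img_width_px,img_height_px canvas size; `NULL` sizes the canvas to
#'   fit the geometry. An explicit size too small for the geometry is an
#'   error before rendering.
#' @param margin_um free margin around the scene.
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(L_max = 600, d50 = 2500, delta = 500,
                       root_width_um = 120,
                       root_curvature_radius_um = 50000,
                       root_length_um = 6200,
                       hair_spacing_um = 25, hair_width_um = 12,
                       bald_prob = 0.2, bent_frac = 0.2,
                       length_jitter_sd = 0.1,
                       noise_sd = 2, blur_sigma_px = 1,
                       bg_level = 200, fg_level = 60,
                       px_size_um = 1.5,
                       img_width_px = NULL, img_height_px = NULL,
                       margin_um = 100, seed = 1) {
  stopifnot(L_max > 0, d50 > 0, delta > 0, root_width_um > 0,
            root_curvature_radius_um > 0, root_length_um > 0,
            hair_spacing_um > 0, hair_width_um > 0, px_size_um > 0,
            bald_prob >= 0, bald_prob <= 1, bent_frac >= 0, bent_frac <= 1)
  structure(as.list(environment()), class = "synth_spec")
}

.rotate2 <- function(v, phi) {
  c(cos(phi) * v[1] - sin(phi) * v[2], sin(phi) * v[1] + cos(phi) * v[2])
}

# stamp points (x_px, y_px continuous) into a 0/1 matrix
.stamp <- function(m, x, y) {
  ri <- round(y); ci <- round(x)
  ok <- ri >= 1 & ri <= nrow(m) & ci >= 1 & ci <= ncol(m)
  m[cbind(ri[ok], ci[ok])] <- 1L
  m
}

# separable Gaussian blur via shift-and-add (kernel radius 3*sigma)
.sepblur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  pass <- function(a, along_rows) {
    out <- a * k[r + 1]
    for (o in seq_len(r)) {
      if (along_rows) {
        out[, (1 + o):nc] <- out[, (1 + o):nc] + k[r + 1 + o] * a[, 1:(nc - o)]
        out[, 1:(nc - o)] <- out[, 1:(nc - o)] + k[r + 1 - o] * a[, (1 + o):nc]
        # replicate edges so totals stay normalised
        out[, 1:o] <- out[, 1:o] + k[r + 1 + o] * a[, 1]
        out[, (nc - o + 1):nc] <- out[, (nc - o + 1):nc] + k[r + 1 - o] * a[, nc]
      } else {
        out[(1 + o):nr, ] <- out[(1 + o):nr, ] + k[r + 1 + o] * a[1:(nr - o), ]
        out[1:(nr - o), ] <- out[1:(nr - o), ] + k[r + 1 - o] * a[(1 + o):nr, ]
        out[1:o, ] <- out[1:o, ] + matrix(k[r + 1 + o] * a[1, ], o, nc, byrow = TRUE)
        out[(nr - o + 1):nr, ] <- out[(nr - o + 1):nr, ] +
          matrix(k[r + 1 - o] * a[nr, ], o, nc, byrow = TRUE)
      }
    }
    out
  }
  pass(pass(m, TRUE), FALSE)
}

#' Generate a synthetic root-tip image with ground truth
#'
#' Renders the scene described by a [synth_spec] and returns the intensity
#' image alongside the ground truth: the per-hair table of (distance from
#' tip, side, true length), the true root median line, and the noise-free
#' binary masks of the root body and the hairs.
#'
#' @param spec a [synth_spec].
#' @return A list with elements `image` ([intensity_image]), `truth`
#'   (data.frame `d_um`, `side`, `length_um` of rendered hairs), `rml`
#'   ([medial_line], tip first), and `masks` (list of 0/1 matrices
#'   `root_body`, `hairs`).
#' @export
generate_root_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  px <- spec$px_size_um

  # centerline in um, tip at arc 0, heading +x, bending toward +y (down)
  t <- seq(0, spec$root_length_um, by = px / 2)
  R <- spec$root_curvature_radius_um
  if (is.infinite(R)) {
    cx <- t; cy <- rep(0, length(t))
    theta <- rep(0, length(t))
  } else {
    theta <- t / R
    cx <- R * sin(theta); cy <- R * (1 - cos(theta))
  }
  # left normal with image y pointing down: (sin(theta), -cos(theta))
  nlx <- sin(theta); nly <- -cos(theta)

  allow <- 1.5 * spec$L_max + spec$root_width_um / 2 + spec$margin_um
  x0 <- spec$margin_um + spec$root_width_um / 2
  y0 <- allow - min(cy)
  cx <- cx + x0; cy <- cy + y0

  width_um <- max(cx) + spec$margin_um + spec$root_width_um / 2
  height_um <- max(cy) + allow
  nc <- if (is.null(spec$img_width_px)) ceiling(width_um / px) else spec$img_width_px
  nr <- if (is.null(spec$img_height_px)) ceiling(height_um / px) else spec$img_height_px
  if (nc * px < width_um || nr * px < height_um)
    stop("geometry overflow: image of ", nc, "x", nr,
         " px cannot contain the root and its hairs")

  body_pts <- matrix(0L, nr, nc)
  body_pts <- .stamp(body_pts, cx / px, cy / px)
  rb <- max(1L, round(spec$root_width_um / 2 / px))
  body <- matrix(as.integer(EBImage::dilate(body_pts, .disc(rb)) > 0), nr, nc)

  hb <- max(1L, round(spec$hair_width_um / 2 / px))
  sdlog <- spec$length_jitter_sd
  sites <- seq(spec$hair_spacing_um, spec$root_length_um - spec$hair_spacing_um,
               by = spec$hair_spacing_um)
  hx <- list(); hy <- list()
  td <- numeric(0); tside <- character(0); tlen <- numeric(0)
  for (d in sites) {
    i <- which.min(abs(t - d))
    for (side in c("left", "right")) {
      sgn <- if (side == "left") 1 else -1
      if (stats::runif(1) < spec$bald_prob) next
      jit <- if (sdlog > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
      len <- rh_sigmoid(d, 0, spec$L_max, spec$d50, spec$delta) * jit
      bent <- stats::runif(1) < spec$bent_frac
      phi <- sample(c(-1, 1), 1) * stats::runif(1, 20, 35) * pi / 180
      if (len < spec$hair_width_um) next     # too short to render: bald site
      n <- sgn * c(nlx[i], nly[i])
      base <- c(cx[i], cy[i]) + n * (spec$root_width_um / 2)
      draw_len <- len - hb * px              # cap of the dilated stroke
      if (bent) {
        mid <- base + n * (draw_len / 2)
        n2 <- .rotate2(n, phi)
        segs <- rbind(c(base, mid), c(mid, mid + n2 * (draw_len / 2)))
      } else {
        segs <- rbind(c(base, base + n * draw_len))
      }
      for (k in seq_len(nrow(segs))) {
        a <- segs[k, 1:2]; bpt <- segs[k, 3:4]
        ns <- max(2, ceiling(sqrt(sum((bpt - a)^2)) / (px / 2)))
        u <- seq(0, 1, length.out = ns)
        hx[[length(hx) + 1]] <- (a[1] + u * (bpt[1] - a[1])) / px
        hy[[length(hy) + 1]] <- (a[2] + u * (bpt[2] - a[2])) / px
      }
      td <- c(td, d); tside <- c(tside, side); tlen <- c(tlen, len)
    }
  }
  hair_pts <- matrix(0L, nr, nc)
  if (length(hx) > 0)
    hair_pts <- .stamp(hair_pts, unlist(hx), unlist(hy))
  hairs <- matrix(as.integer(EBImage::dilate(hair_pts, .disc(hb)) > 0), nr, nc)
  truth <- data.frame(d_um = td, side = tside, length_um = tlen,
                      stringsAsFactors = FALSE)

  img <- matrix(spec$bg_level, nr, nc)
  img[body == 1L | hairs == 1L] <- spec$fg_level
  if (spec$blur_sigma_px > 0)
    img <- .sepblur(img, spec$blur_sigma_px)
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  img <- round(pmin(pmax(img, 0), 255))

  stride <- max(1, floor(length(t) / 400))
  keep <- unique(c(seq(1, length(t), by = stride), length(t)))
  rml <- medial_line(cbind(cx[keep], cy[keep]) / px, px)

  list(image = intensity_image(img, 8L, px),
       truth = truth,
       rml = rml,
       masks = list(root_body = body, hairs = hairs))
}
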