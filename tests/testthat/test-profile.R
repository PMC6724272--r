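test_that("a solid block filling one window gives L = block height", {
  m <- matrix(0L, 21, 40)          # band halfwidth 10, center row 11
  m[1:10, 9:16] <- 1L              # 8 px wide, 10 px tall, on the left side
  sm <- make_straightened(m, px = 2)
  raw <- scan_windows(sm, w_um = 16, range_um = c(0, 80))  # w = 8 px
  left <- raw[raw$side == "left", ]
  expect_equal(left$length_um[2], 10 * 2)     # window 2 covers cols 9:16
  expect_equal(left$length_um[-2], rep(0, nrow(left) - 1))
  expect_true(all(raw$length_um[raw$side == "right"] == 0))
})

test_that("window measurements equal a per-window pixel-count oracle", {
  set.seed(51)
  for (rep in 1:5) {
    m <- matrix(as.integer(runif(31 * 97) < 0.3), 31, 97)
    px <- runif(1, 0.5, 3)
    sm <- make_straightened(m, px = px)
    w_um <- runif(1, 2, 6) * px
    raw <- scan_windows(sm, w_um = w_um, range_um = c(0, 97 * px))
    w_px <- round(w_um / px)
    starts <- seq(1, 97 - w_px + 1, by = w_px)
    for (side in c("left", "right")) {
      rows <- if (side == "left") 1:15 else 17:31
      got <- raw[raw$side == side, ]
      expect_equal(nrow(got), length(starts))
      for (k in seq_along(starts)) {
        count <- sum(m[rows, starts[k]:(starts[k] + w_px - 1)])
        expect_equal(got$length_um[k], (count * px^2) / (w_px * px))
        expect_equal(got$distance_um[k], (starts[k] - 1 + w_px / 2) * px)
      }
    }
  }
})

test_that("window count per side is floor(range / w) up to the range end", {
  m <- matrix(0L, 11, 100)
  sm <- make_straightened(m, px = 1)
  for (w in c(3, 7, 10)) {
    raw <- scan_windows(sm, w_um = w, range_um = c(0, 100))
    expect_lte(abs(sum(raw$side == "left") - floor(100 / w)), 1)
  }
  expect_error(scan_windows(sm, 5, range_um = c(50, 10)), "before start")
})

test_that("L is invariant under vertical translation of hairs in the band", {
  m1 <- matrix(0L, 41, 24); m1[3:12, 5:12] <- 1L
  m2 <- matrix(0L, 41, 24); m2[9:18, 5:12] <- 1L
  r1 <- scan_windows(make_straightened(m1), w_um = 8, range_um = c(0, 24))
  r2 <- scan_windows(make_straightened(m2), w_um = 8, range_um = c(0, 24))
  expect_equal(r1$length_um, r2$length_um)
})

test_that("max filter takes block maxima with argmax distances", {
  raw <- data.frame(distance_um = c(4, 12, 20, 28),
                    length_um = c(3, 7, 2, 9),
                    side = "left", stringsAsFactors = FALSE)
  out <- max_filter(raw, 2)
  expect_equal(out$length_um, c(7, 9))
  expect_equal(out$distance_um, c(12, 28))
  expect_identical(max_filter(raw, 1)[, 1:2], raw[, 1:2])
  # ties break toward the smaller distance
  tie <- data.frame(distance_um = c(1, 2), length_um = c(5, 5),
                    side = "left", stringsAsFactors = FALSE)
  expect_equal(max_filter(tie, 2)$distance_um, 1)
})

test_that("max filter equals brute-force block maxima and nests exactly", {
  set.seed(52)
  raw <- data.frame(distance_um = seq(2, 400, by = 2),
                    length_um = runif(200, 0, 100),
                    side = rep(c("left", "right"), each = 100),
                    stringsAsFactors = FALSE)
  for (k in c(1, 4, 7)) {
    got <- max_filter(raw, k)
    for (side in c("left", "right")) {
      v <- raw$length_um[raw$side == side]
      want <- vapply(split(v, (seq_along(v) - 1) %/% k), max, numeric(1))
      expect_equal(got$length_um[got$side == side], unname(want))
    }
  }
  # nesting: the k = m*k1 maxima equal maxima over m consecutive k1 blocks
  f2 <- max_filter(raw, 2); f10 <- max_filter(raw, 10)
  for (side in c("left", "right")) {
    v2 <- f2$length_um[f2$side == side]
    v10 <- f10$length_um[f10$side == side]
    regrouped <- vapply(split(v2, (seq_along(v2) - 1) %/% 5), max, numeric(1))
    expect_equal(v10, unname(regrouped))
  }
})

test_that("annotation projection onto a straight RML matches its orthogonal shadow", {
  rml <- medial_line(cbind(c(0, 400), c(50, 50)), px_size_um = 1)
  rect <- annotation_region(cbind(c(100, 200, 200, 100), c(30, 30, 70, 70)),
                            "artefact")
  iv <- project_annotations(list(rect), rml)
  expect_equal(iv$d_min_um, 100, tolerance = 1)
  expect_equal(iv$d_max_um, 200, tolerance = 1)
  # polygon entirely on one side projects to the same shadow
  oneside <- annotation_region(cbind(c(120, 180, 150), c(10, 10, 25)), "dust")
  iv2 <- project_annotations(list(oneside), rml)
  expect_equal(iv2$d_min_um, 120, tolerance = 1)
  expect_equal(iv2$d_max_um, 180, tolerance = 1)
})

test_that("annotation projection agrees with a dense-sampling nearest-point oracle", {
  set.seed(53)
  vx <- c(10, 60, 120, 200); vy <- c(10, 40, 35, 90)
  rml <- medial_line(cbind(vx, vy), px_size_um = 1.5)
  poly <- annotation_region(cbind(runif(5, 20, 180), runif(5, 5, 95)), "x")
  iv <- project_annotations(list(poly), rml)
  # oracle: sample the polyline at 0.01-px steps, nearest sample per vertex
  tt <- seq(0, 1, length.out = 200001)
  arc <- rml$arc_length_um
  sx <- approx(arc, vx, xout = tt * max(arc))$y
  sy <- approx(arc, vy, xout = tt * max(arc))$y
  proj <- apply(poly$vertices, 1, function(v) {
    tt[which.min((v[1] - sx)^2 + (v[2] - sy)^2)] * max(arc)
  })
  expect_equal(iv$d_min_um, min(proj), tolerance = 0.1)
  expect_equal(iv$d_max_um, max(proj), tolerance = 0.1)
})

test_that("flags mark points inside closed intervals and leave others at 0", {
  pts <- data.frame(distance_um = c(50, 100, 150, 200, 250),
                    length_um = 1:5, side = "left",
                    stringsAsFactors = FALSE)
  iv <- data.frame(label = "artefact", d_min_um = 100, d_max_um = 200,
                   stringsAsFactors = FALSE)
  out <- flag_profile(pts, iv)
  expect_equal(out$flag_artefact, c(0L, 1L, 1L, 1L, 0L))  # closed endpoints
  expect_identical(flag_profile(pts, iv[0, ]), pts)        # no intervals
})
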