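test_that("the landmark transform sends fovea to origin and disc onto +x at 9.5% of the diameter", {
  g <- grid_spec()
  D <- 2 * g$total_radius
  withr::with_seed(7, {
    for (i in 1:300) {
      fov <- stats::runif(2, 0, 3000)
      disc <- fov + stats::rnorm(2, 0, 200)
      if (all(disc == fov)) next
      tr <- compute_transform(landmarks(fov, disc), g)
      f <- grid_from_image(fov[1], fov[2], tr)
      d <- grid_from_image(disc[1], disc[2], tr)
      expect_lt(abs(f$x) + abs(f$y), 1e-9 * D)
      expect_lt(abs(d$y), 1e-9 * D)
      expect_lt(abs(d$x - 0.095 * D), 1e-9 * D)
    }
  })
})

test_that("worked transform examples hold", {
  g <- grid_spec()
  tr <- compute_transform(landmarks(c(100, 100), c(150, 100)), g)
  expect_equal(tr$scale, 3.23 / 50)
  expect_equal(grid_from_image(150, 100, tr)$x, 0.095 * 34)
  # disc straight below the fovea (pixel y is down): pure rotation
  tr2 <- compute_transform(landmarks(c(0, 0), c(0, 40)), g)
  d2 <- grid_from_image(0, 40, tr2)
  expect_lt(abs(d2$y), 1e-9)
  expect_equal(d2$x, 3.23)
  expect_error(landmarks(c(5, 5), c(5, 5)),
               class = "gridfa_degenerate_landmarks")
})

test_that("inverse transform is exact and angles are preserved", {
  g <- grid_spec()
  withr::with_seed(11, {
    tr <- compute_transform(landmarks(c(512, 480), c(700, 300)), g)
    x <- stats::runif(200, -2000, 2000)
    y <- stats::runif(200, -2000, 2000)
    gpt <- grid_from_image(x, y, tr)
    back <- image_from_grid(gpt$x, gpt$y, tr)
    expect_lt(max(abs(back$x - x), abs(back$y - y)), 1e-9)
    # similarity: angles of random triples preserved (up to y-flip sign)
    ang <- function(ax, ay, bx, by, cx, cy) {
      u <- c(ax - bx, ay - by); v <- c(cx - bx, cy - by)
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
    for (i in 1:50) {
      idx <- sample(200, 3)
      a1 <- ang(x[idx[1]], y[idx[1]], x[idx[2]], y[idx[2]], x[idx[3]], y[idx[3]])
      a2 <- ang(gpt$x[idx[1]], gpt$y[idx[1]], gpt$x[idx[2]], gpt$y[idx[2]],
                gpt$x[idx[3]], gpt$y[idx[3]])
      expect_lt(abs(a1 - a2), 1e-9)
    }
  })
})

test_that("millimetre calibration follows the fixed fovea-disc distance", {
  g <- grid_spec()
  lm <- landmarks(c(0, 0), c(100, 0))
  cal <- mm_calibration(lm, physical_calibration(), g)
  expect_equal(cal$mm_per_px, 4.76 / 100)
  expect_equal(cal$grid_diameter_mm, 4.76 / 0.095)
  expect_equal(cal$cell_area_mm2, pi * (4.76 / 0.095 / 2)^2 / 289)
  # doubling the anatomical distance quadruples cell area
  cal2 <- mm_calibration(lm, physical_calibration(2 * 4.76), g)
  expect_equal(cal2$cell_area_mm2, 4 * cal$cell_area_mm2)
  expect_error(physical_calibration(-1), class = "gridfa_invalid_argument")
})

test_that("display warp honours identity, translation, and rotation contracts", {
  g <- grid_spec()
  withr::with_seed(3, img <- matrix(stats::runif(60 * 60), 60, 60))
  id_tr <- structure(list(dx = 0, dy = 0, theta = 0, scale = 1, d_px = NA),
                     class = "gridfa_transform")
  out <- warp_image(img, id_tr, center = c(0, 0), method = "nearest")
  expect_identical(out, img)
  # integer translation, nearest mode: shifted copy
  sh_tr <- structure(list(dx = -10, dy = -5, theta = 0, scale = 1, d_px = NA),
                     class = "gridfa_transform")
  out2 <- warp_image(img, sh_tr, center = c(0, 0), method = "nearest")
  expect_identical(out2[1:55, 1:50], img[6:60, 11:60])
  # 90-degree rotation of a cross pattern swaps the arms; oracle is a plain
  # array transpose+reverse, independent of the warp implementation
  cross <- matrix(0, 61, 61)
  cross[31, ] <- 1            # horizontal arm
  cross[11:20, 31] <- 0.5     # upper vertical arm segment
  rot_tr <- compute_transform(landmarks(c(31, 31), c(31, 71)), g)
  rot_tr$scale <- 1           # keep resolution; rotation is the point
  out3 <- warp_image(cross, rot_tr, out_shape = c(61, 61), out_scale = 1,
                     center = c(31, 31), method = "nearest")
  oracle <- t(cross)[61:1, ]  # quarter-turn by transpose + row reversal
  expect_equal(out3[2:60, 2:60], oracle[2:60, 2:60])
  expect_error(warp_image(matrix(numeric(0), 0, 0), id_tr),
               class = "gridfa_invalid_argument")
})

test_that("per-cell mean intensities are invariant to the image's placement", {
  g <- grid_spec()
  n <- 600L
  scene <- function(fov, disc) {
    tr <- compute_transform(landmarks(fov, disc), g)
    px <- rep(seq_len(n), each = n); py <- rep(seq_len(n), times = n)
    gc_ <- grid_from_image(px, py, tr)
    # a smooth scene fixed in grid coordinates, rendered at this placement
    list(img = matrix(0.5 + 0.4 * sin(gc_$x / 3) * cos(gc_$y / 4), n, n),
         tr = tr)
  }
  means <- function(z) {
    lab <- grid_label_raster(g, z$tr, c(n, n))
    tapply(z$img[lab > 0], lab[lab > 0], mean)
  }
  a <- means(scene(c(300, 300), c(340, 300)))
  b <- means(scene(c(280, 310), c(310, 290)))   # shifted, rotated, rescaled
  common <- intersect(names(a), names(b))
  expect_identical(length(common), 289L)
  expect_lt(max(abs(a[common] - b[common]) / abs(a[common])), 0.01)
})

test_that("matched cell patches share the gain and clip at white", {
  g <- grid_spec()
  n <- 200L
  withr::with_seed(5, img <- matrix(stats::runif(n * n, 0, 0.5), n, n))
  tr <- centered_transform(g, c(n, n))
  pr <- extract_cell_pair(img, img, 0, 0, tr, tr, g, gain = 1)
  expect_false(pr$empty)
  expect_identical(pr$assessment, pr$control)  # same image, same cell
  pr2 <- extract_cell_pair(img, img, 0, 0, tr, tr, g, gain = 4)
  inside <- !is.na(pr$assessment)
  expect_equal(pr2$assessment[inside], pmin(4 * pr$assessment[inside], 1))
  # cell outside the control image field: flagged empty, no error
  tr_small <- compute_transform(landmarks(c(9, 9), c(10, 9)), g)
  pr3 <- extract_cell_pair(img, matrix(0, 3, 3), 0, 0, tr, tr_small, g)
  expect_true(pr3$empty)
  expect_error(extract_cell_pair(img, img, 0, 0, tr, tr, g, gain = 0),
               class = "gridfa_invalid_argument")
})
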