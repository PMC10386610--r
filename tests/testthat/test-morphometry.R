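test_that("moment ellipse fit recovers axes and orientation", {
  m <- pumpkinpheno:::ellipse_mask(300, 400, 200, 150, 100, 40, 0)
  e <- fit_ellipse(m)
  expect_lt(abs(e$major_px / 200 - 1), 0.02)
  expect_lt(abs(e$minor_px / 80 - 1), 0.02)
  expect_lt(abs(e$theta_deg), 1)
  expect_equal(c(e$cx, e$cy), c(200, 150), tolerance = 0.01)

  disk <- pumpkinpheno:::ellipse_mask(140, 140, 70, 70, 50, 50, 0)
  ed <- fit_ellipse(disk)
  expect_lt(abs(ed$major_px / ed$minor_px - 1), 0.01)

  rot <- pumpkinpheno:::ellipse_mask(400, 400, 200, 200, 100, 40, 35)
  er <- fit_ellipse(rot)
  expect_lt(abs(er$theta_deg - 35), 1)
})

test_that("degenerate masks are rejected by the ellipse fit", {
  expect_error(fit_ellipse(tiny_mask(c(1, 2, 3))), "fewer than 5")
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(fit_ellipse(line), "collinear")
})

test_that("axis alignment preserves area and undoes rotation", {
  m <- pumpkinpheno:::ellipse_mask(400, 400, 200, 200, 100, 40, 35)
  e <- fit_ellipse(m)
  aligned <- align_to_axes(m, e)
  expect_lt(abs(sum(aligned) / sum(m) - 1), 0.01)   # area within 1 percent

  # identity rotation keeps the mask (up to canvas padding)
  m0 <- pumpkinpheno:::ellipse_mask(300, 400, 200, 150, 100, 40, 0)
  a0 <- align_to_axes(m0, fit_ellipse(m0))
  expect_equal(sum(a0), sum(m0))

  # rotating a rotated rectangle back restores its bounding box
  rect <- rect_mask(300, 300, 101:160, 51:250)   # 200 x 60
  er <- list(cx = 149.5, cy = 129.5, theta_deg = 25)
  rot <- align_to_axes(rect, list(cx = 149.5, cy = 129.5, theta_deg = -25))
  back <- align_to_axes(rot, fit_ellipse(rot))
  bb <- which(back, arr.ind = TRUE)
  w <- diff(range(bb[, 2])) + 1
  h <- diff(range(bb[, 1])) + 1
  expect_lt(abs(w - 200), 2 * 2)
  expect_lt(abs(h - 60), 2 * 2)
})

test_that("width equals the perpendicular extent and matches brute force", {
  expect_equal(measure_width_px(rect_mask(200, 300, 61:140, 51:250)), 80)
  expect_equal(measure_width_px(tiny_mask(10)), 1)
  ell <- pumpkinpheno:::ellipse_mask(300, 400, 200, 150, 100, 40, 0)
  expect_lt(abs(measure_width_px(ell) - 80), 2)
  expect_error(measure_width_px(matrix(FALSE, 5, 5)), "no foreground")

  set.seed(42)
  for (i in 1:12) {
    m <- matrix(runif(64 * 64) < 0.15, 64, 64)
    if (!any(m)) next
    expect_equal(measure_width_px(m), brute_force_width(m))
  }
})

test_that("skeletons of canonical shapes behave like the medial axis", {
  line <- matrix(FALSE, 20, 120); line[10, 11:110] <- TRUE
  sk <- skeletonize_mask(line)
  expect_equal(nrow(sk$path), 100)
  expect_equal(measure_length_px(sk), 100)

  disk <- pumpkinpheno:::ellipse_mask(140, 140, 70, 70, 50, 50, 0)
  skd <- skeletonize_mask(disk)
  expect_lte(nrow(skd$path), 5)

  # tube around a known polyline: path stays within radius of the
  # generating centerline
  t <- seq(0, 1, length.out = 129)
  poly <- cbind(50 + 400 * t, 100 + 30 * sin(pi * t))
  tube <- pumpkinpheno:::polyline_tube_mask(200, 500, poly, 12)
  skt <- skeletonize_mask(tube)
  d_to_poly <- vapply(seq_len(nrow(skt$path)), function(i) {
    min(sqrt((poly[, 1] - skt$path[i, 1])^2 + (poly[, 2] - skt$path[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d_to_poly), 12)

  arc <- sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
  len <- measure_length_px(skt)
  expect_gte(len, arc - 2 * 12 - 10)
  expect_lte(len, arc + 10)

  single <- tiny_mask(30)
  expect_equal(nrow(skeletonize_mask(single)$path), 1)
})

test_that("skeleton pixels always lie inside the source mask", {
  for (seed in c(2, 6)) {
    b <- generate_scene(random_scene_spec(seed))
    for (mask in list(b$fruit_mask, b$vine_mask)) {
      sk <- skeletonize_mask(mask)
      inside <- mask[cbind(sk$path[, 2] + 1L, sk$path[, 1] + 1L)]
      expect_true(all(inside))
    }
  }
})

test_that("length models give the closed-form values on diagonals", {
  n <- 100
  diag_mask <- matrix(FALSE, n + 2, n + 2)
  diag_mask[cbind(1:n + 1L, 1:n + 1L)] <- TRUE
  sk <- skeletonize_mask(diag_mask)
  expect_equal(measure_length_px(sk, "pixel_count"), 100)
  expect_equal(measure_length_px(sk, "euclidean"), 99 * sqrt(2))
  expect_equal(measure_length_px(sk, scope = "total_pixels"), 100)
})

test_that("tube width is twice the median medial radius", {
  poly <- cbind(seq(30, 430, length.out = 5), rep(60.3, 5))
  tube <- pumpkinpheno:::polyline_tube_mask(120, 460, poly, 12)
  expect_lt(abs(tube_width_px(skeletonize_mask(tube)) - 24), 2)

  thin <- matrix(FALSE, 10, 60); thin[5, 6:55] <- TRUE
  expect_lte(tube_width_px(skeletonize_mask(thin)), 2)
})

test_that("peel color classification follows HSV range membership", {
  or_img <- uniform_image(10, 10, grDevices::col2rgb(
    grDevices::hsv(25 / 360, 0.9, 0.9)) / 255)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(as.character(classify_fpc(or_img, mask)), "OR")

  g_img <- uniform_image(10, 10, grDevices::col2rgb(
    grDevices::hsv(110 / 360, 0.6, 0.4)) / 255)
  expect_equal(as.character(classify_fpc(g_img, mask)), "G")

  lg_img <- uniform_image(10, 10, grDevices::col2rgb(
    grDevices::hsv(110 / 360, 0.15, 0.85)) / 255)
  expect_equal(as.character(classify_fpc(lg_img, mask)), "LG")

  # 70/30 two-tone majority
  two <- g_img
  for (ch in 1:3) two[1:3, , ch] <- or_img[1:3, , ch]
  res <- classify_fpc(two, mask)
  expect_equal(as.character(res), "G")
  counts <- attr(res, "counts")
  expect_equal(unname(counts[["green"]]), 70)
  expect_equal(unname(counts[["orange"]]), 30)

  # nothing in range -> classed error with the counts attached
  blue <- uniform_image(10, 10, c(0.1, 0.1, 0.9))
  err <- tryCatch(classify_fpc(blue, mask), fpc_unclassified = function(e) e)
  expect_s3_class(err, "fpc_unclassified")
  expect_true(all(err$counts == 0))
})

test_that("component measurement combines skeleton length and widths", {
  # fruit ellipse 320 x 180 px at 0.1 mm/px
  img <- uniform_image(500, 700, c(0.8, 0.8, 0.8))
  fruit <- pumpkinpheno:::ellipse_mask(500, 700, 350, 250, 160, 90, 20)
  col <- grDevices::col2rgb(grDevices::hsv(110 / 360, 0.6, 0.45)) / 255
  for (ch in 1:3) { p <- img[, , ch]; p[fruit] <- col[ch]; img[, , ch] <- p }
  res <- measure_component(img, fruit, px_scale(0.1), role = "fruit")
  expect_lt(abs(res$width_mm / 18 - 1), 0.03)
  expect_equal(res$fpc, "G")
  L <- 2 * (160^2 - 90^2) / 160
  expect_gte(res$details$length_px, L - 2 * 90^2 / 160 - 10)
  expect_lte(res$details$length_px, L + 10)

  # vine tube L = 400 px, r = 12 at 0.05 mm/px
  t <- seq(0, 1, length.out = 129)
  poly <- cbind(50 + 395 * t, 100 + 25 * sin(pi * t))
  vine <- pumpkinpheno:::polyline_tube_mask(200, 500, poly, 12)
  vres <- measure_component(img[1:200, 1:500, , drop = FALSE], vine,
                            px_scale(0.05), role = "vine")
  expect_lt(abs(vres$width_mm / 1.2 - 1), 0.1)

  expect_error(measure_component(img, matrix(FALSE, 500, 700), px_scale(0.1),
                                 role = "fruit"), "degenerate")
})

test_that("sample records scale linearly and tolerate missing components", {
  b <- generate_scene(random_scene_spec(8))
  r1 <- measure_sample(b$image, b$fruit_mask, b$vine_mask, px_scale(0.1), "a")
  r2 <- measure_sample(b$image, b$fruit_mask, b$vine_mask, px_scale(0.2), "a")
  for (f in c("FL_mm", "FW_mm", "VL_mm", "VW_mm"))
    expect_equal(r2[[f]], 2 * r1[[f]], tolerance = 1e-12)

  fruit_only <- measure_sample(b$image, b$fruit_mask, NULL, px_scale(0.1), "f")
  expect_true(is.na(fruit_only$VL_mm) && is.na(fruit_only$VW_mm))
  expect_false(is.na(fruit_only$FL_mm))
})

test_that("right-angle rotation of the scene leaves measurements unchanged", {
  b <- generate_scene(random_scene_spec(6))
  sc <- px_scale(b$truth$mm_per_px)
  r1 <- measure_sample(b$image, b$fruit_mask, b$vine_mask, sc, "a")
  r2 <- measure_sample(rot90_image(b$image), rot90_mask(b$fruit_mask),
                       rot90_mask(b$vine_mask), sc, "a")
  for (f in c("FL_mm", "FW_mm", "VL_mm", "VW_mm"))
    expect_lt(abs(r2[[f]] / r1[[f]] - 1), 0.02)
  expect_equal(r1$FPC, r2$FPC)
})

test_that("dilating a fruit mask never decreases its measured width", {
  for (th in c(0, 20, 40)) {
    m <- pumpkinpheno:::ellipse_mask(300, 400, 200, 150, 90, 50, th)
    md <- EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0
    w1 <- measure_width_px(align_to_axes(m, fit_ellipse(m)))
    w2 <- measure_width_px(align_to_axes(md, fit_ellipse(md)))
    expect_gte(w2, w1)
  }
})
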