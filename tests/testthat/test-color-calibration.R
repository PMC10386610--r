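test_that("chip means are exact on constant and painted checkers", {
  grid <- regular_chip_grid(10, 10, 20, 5)
  img <- uniform_image(200, 300, c(0.5, 0.5, 0.5))
  means <- extract_chip_means(img, grid)
  expect_equal(dim(means), c(24L, 3L))
  expect_true(all(means == 0.5))

  # painted checker recovered exactly (margin keeps averaging inside chips)
  bundle <- generate_scene(scene_spec(
    seed = 1, checker = list(x0 = 15, y0 = 15, chip_px = 28, gap_px = 4)))
  rec <- extract_chip_means(bundle$image, bundle$chip_grid)
  expect_equal(rec, checker_reference_colors(), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("chip means under additive noise respect the standard-error bound", {
  colors <- 0.1 + 0.8 * checker_reference_colors()
  idx <- expand.grid(col = 0:5, row = 0:3)
  for (seed in 2:4) {
    set.seed(seed)
    img <- array(0, c(200, 300, 3))
    for (k in 1:24) {
      rows <- idx$row[k] * 50 + 1:50
      cols <- idx$col[k] * 50 + 1:50
      for (ch in 1:3) img[rows, cols, ch] <- colors[k, ch]
    }
    img <- img + array(rnorm(length(img), 0, 0.01), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    means <- extract_chip_means(img, regular_chip_grid(0, 0, 50, 0,
                                                       sample_margin = 0))
    expect_lt(max(abs(means - colors)), 3 * 0.01 / sqrt(2500))
  }
})

test_that("chip extraction rejects out-of-bounds and degenerate grids", {
  grid <- regular_chip_grid(290, 10, 20, 5)    # runs past a 300-px width
  expect_error(extract_chip_means(uniform_image(200, 300, rep(0.5, 3)), grid),
               "bounds")
  tight <- regular_chip_grid(10, 10, 1, 5, sample_margin = 0.49)
  expect_error(extract_chip_means(uniform_image(200, 300, rep(0.5, 3)), tight),
               "empty")
  expect_error(chip_grid(matrix(c(0, 0, 10, 10), 24, 4, byrow = TRUE)),
               "overlap")
})

test_that("correction fit recovers identity, scalars and generating matrices", {
  ref <- checker_reference_colors()
  cm <- fit_correction_matrix(ref, ref)
  expect_lt(max(abs(cm$M - diag(3))), 1e-10)
  expect_true(all(cm$offset == 0))

  half <- fit_correction_matrix(0.5 * ref, ref, model = "linear")
  expect_equal(half$M, 2 * diag(3), tolerance = 1e-10)

  # oracle: source = A ref  =>  fitted M = A^-1 (direct inversion)
  A <- matrix(c(0.9, 0.1, 0, 0.05, 0.85, 0.1, 0, 0.1, 0.95), 3, byrow = TRUE)
  cmA <- fit_correction_matrix(ref %*% t(A), ref)
  expect_lt(max(abs(cmA$M - solve(A))), 1e-8)

  # affine model recovers matrix plus offset exactly
  b <- c(0.03, -0.02, 0.05)
  srcA <- ref %*% t(A) + rep(b, each = 24)
  cmAf <- fit_correction_matrix(srcA, ref, model = "affine")
  fitted <- srcA %*% t(cmAf$M) + rep(cmAf$offset, each = 24)
  expect_lt(max(abs(fitted - ref)), 1e-8)
})

test_that("rank-deficient chip sets are rejected with the condition number", {
  gray <- matrix(rep(seq(0.1, 0.9, length.out = 24), 3), 24, 3)
  expect_error(fit_correction_matrix(gray, checker_reference_colors()),
               "condition number")
})

test_that("applying a correction clips and reports out-of-gamut samples", {
  img <- uniform_image(4, 5, c(0.6, 0.6, 0.6))
  out <- apply_correction(img, 2 * diag(3))
  expect_true(all(out == 1))
  expect_equal(attr(out, "n_clipped"), 4L * 5L * 3L)
  same <- apply_correction(img, diag(3))
  expect_equal(as.numeric(same), as.numeric(img))
  expect_equal(attr(same, "n_clipped"), 0L)
})

test_that("cast-then-correct round trip restores chip means", {
  ref <- checker_reference_colors()
  bundle <- generate_scene(scene_spec(
    seed = 2, checker = list(x0 = 15, y0 = 15, chip_px = 28, gap_px = 4)))
  cast <- random_color_cast(11)
  cast_img <- apply_color_cast(bundle$image, cast)
  expect_equal(attr(cast_img, "n_clipped"), 0L)
  cm <- fit_correction_matrix(extract_chip_means(cast_img, bundle$chip_grid),
                              ref)
  means <- extract_chip_means(apply_correction(cast_img, cm),
                              bundle$chip_grid)
  expect_lt(sqrt(mean((means - ref)^2)), 1e-6)

  # refitting on the corrected image is the identity (idempotence)
  cm2 <- fit_correction_matrix(means, ref)
  expect_lt(max(abs(cm2$M - diag(3))), 1e-6)
})

test_that("fitting never increases chip-space error relative to identity", {
  for (seed in 1:5) {
    set.seed(seed)
    src <- matrix(runif(72, 0.05, 0.95), 24, 3)
    ref <- matrix(runif(72, 0.05, 0.95), 24, 3)
    cm <- fit_correction_matrix(src, ref)
    fitted <- src %*% t(cm$M)
    expect_lte(sum((fitted - ref)^2), sum((src - ref)^2) + 1e-12)
  }
})

test_that("chip-order permutation leaves the fitted matrix unchanged", {
  set.seed(3)
  src <- matrix(runif(72, 0.05, 0.95), 24, 3)
  ref <- matrix(runif(72, 0.05, 0.95), 24, 3)
  perm <- sample(24)
  cm1 <- fit_correction_matrix(src, ref)
  cm2 <- fit_correction_matrix(src[perm, ], ref[perm, ])
  expect_equal(cm1$M, cm2$M, tolerance = 1e-10)
})

test_that("linearity report flags deviating chips and handles degeneracy", {
  ref <- checker_reference_colors()
  same <- linearity_report(ref, ref)
  for (ch in c("r", "g", "b")) {
    expect_equal(same[[ch]]$r_squared, 1, tolerance = 1e-12)
    expect_length(same[[ch]]$flagged, 0)
  }

  src <- ref
  src[7, 1] <- src[7, 1] + 0.3       # red-channel outlier on chip 7
  rep7 <- linearity_report(src, ref)
  expect_true(7L %in% rep7$r$flagged)

  # exact affine relation: perfect fit, nothing flagged
  aff <- linearity_report(0.8 * ref + 0.05, ref)
  for (ch in c("r", "g", "b")) {
    expect_equal(aff[[ch]]$r_squared, 1, tolerance = 1e-10)
    expect_length(aff[[ch]]$flagged, 0)
  }

  flat <- ref; flat[, 2] <- 0.5
  repf <- linearity_report(flat, ref)
  expect_true(repf$g$undefined)
  expect_true(is.na(repf$g$slope))
})

test_that("chip grids and correction matrices round-trip through JSON", {
  grid <- regular_chip_grid(15, 15, 28, 4, sample_margin = 0.25)
  gp <- withr::local_tempfile(fileext = ".json")
  write_chip_grid(grid, gp)
  grid2 <- read_chip_grid(gp)
  expect_equal(grid2$boxes, grid$boxes, ignore_attr = TRUE)
  expect_equal(grid2$sample_margin, 0.25)

  cm <- fit_correction_matrix(0.5 * checker_reference_colors(),
                              checker_reference_colors())
  mp <- withr::local_tempfile(fileext = ".json")
  write_correction_matrix(cm, mp)
  cm2 <- read_correction_matrix(mp)
  expect_equal(cm2$M, cm$M, tolerance = 1e-12)
  expect_equal(cm2$model, "linear")
})
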