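# Seeded generator of pumpkin-like test scenes with exact ground truth.
#
# A scene holds, on one canvas: a 4 x 6 color checker, a ruler bar of
# known physical length, an elliptical fruit and a curved tube-like vine.
# Shapes are rendered with hard edges (no anti-aliasing) from the same
# geometry that produces the ground-truth masks, so masks are exact pixel
# sets and every measured quantity has a closed-form or finely integrated
# reference value.

#' Reference colors for the synthetic 24-chip checker
#'
#' Eighteen saturated hues spread over the color circle plus a six-step
#' neutral gray ramp (a generic checker layout; real charts have
#' proprietary values and any 24 x 3 reference matrix can be substituted).
#'
#' @return Numeric `24 x 3` RGB matrix in `[0, 1]`.
#' @export
checker_reference_colors <- function() {
  hues <- seq(0, 340, by = 20)
  chrom <- hsv_rows_to_rgb(cbind(hues, 0.8, 0.8))
  grays <- cbind(seq(0.05, 0.95, length.out = 6),
                 seq(0.05, 0.95, length.out = 6),
                 seq(0.05, 0.95, length.out = 6))
  rbind(chrom, grays)
}

#' Construct an explicit scene specification
#'
#' All geometry is in pixels with 0-based coordinates; `mm_per_px` is the
#' true scale the scene encodes. Any of `fruit`, `vine`, `ruler`,
#' `checker` may be `NULL` to omit that element.
#'
#' @param seed integer seed controlling the scene's stochastic parts
#'   (noise); the geometry itself is deterministic in the spec.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param mm_per_px true millimetres per pixel (> 0).
#' @param fruit list `cx, cy, a, b, theta_deg, color` (HSV triple, hue in
#'   degrees) and `fpc` (truth category `"G"`, `"OR"` or `"LG"`).
#' @param vine list `p0, p1, p2` (quadratic Bezier control points, each
#'   `c(x, y)`), `radius` (>= 2 px) and `color` (HSV).
#' @param ruler list `x0, y0` (top end of the centerline), `angle_deg`
#'   (from vertical, clockwise toward +x), `length_px`, `bar_width_px`.
#' @param checker list `x0, y0, chip_px, gap_px` and optional `colors`
#'   (24 x 3 RGB, defaults to [checker_reference_colors()]).
#' @param cast optional 3 x 3 matrix simulating a lighting color cast,
#'   applied to the rendered image.
#' @param noise_sigma standard deviation of additive zero-mean Gaussian
#'   RGB noise (0 = noiseless).
#' @param bg background RGB triple.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, canvas = c(600L, 800L), mm_per_px = 0.1,
                       fruit = NULL, vine = NULL, ruler = NULL,
                       checker = NULL, cast = NULL, noise_sigma = 0,
                       bg = c(0.82, 0.82, 0.80)) {
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("mm_per_px must be positive", call. = FALSE)
  if (!is.null(vine) && vine$radius < 2)
    stop("vine radius must be at least 2 px", call. = FALSE)
  if (!is.null(checker) && is.null(checker$colors))
    checker$colors <- checker_reference_colors()
  structure(list(seed = as.integer(seed), canvas = as.integer(canvas),
                 mm_per_px = mm_per_px, fruit = fruit, vine = vine,
                 ruler = ruler, checker = checker, cast = cast,
                 noise_sigma = noise_sigma, bg = bg),
            class = "scene_spec")
}

# Study-condition distributions for randomized scenes. Layout bands keep
# the four elements disjoint for every draw: checker strip top-left,
# vine band above the fruit, fruit in the lower center, ruler at the
# right edge.
FRUIT_COLOR_RANGES <- list(
  G = list(h = c(95, 130), s = c(0.45, 0.70), v = c(0.35, 0.60)),
  OR = list(h = c(15, 35), s = c(0.60, 0.90), v = c(0.50, 0.78)),
  LG = list(h = c(95, 130), s = c(0.30, 0.50), v = c(0.70, 0.85)))
VINE_COLOR_RANGE <- list(h = c(65, 85), s = c(0.45, 0.60), v = c(0.30, 0.45))

#' Draw a randomized scene specification
#'
#' Samples fruit geometry and color (within the chosen peel-color
#' category), vine curvature and thickness, ruler length and scale from
#' fixed study-condition ranges, with a layout that keeps all elements
#' disjoint. Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param fpc peel-color category to draw (`"G"`, `"OR"`, `"LG"`) or
#'   `NULL` to pick one at random.
#' @param noise_sigma,cast passed through to [scene_spec()].
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(seed, fpc = NULL, noise_sigma = 0, cast = NULL) {
  with_seed(seed, {
    mm_per_px <- stats::runif(1, 0.05, 0.2)
    if (is.null(fpc)) fpc <- sample(c("G", "OR", "LG"), 1)
    cr <- FRUIT_COLOR_RANGES[[fpc]]
    fruit <- list(
      cx = stats::runif(1, 300, 520), cy = stats::runif(1, 400, 440),
      a = stats::runif(1, 100, 140), b = stats::runif(1, 60, 85),
      theta_deg = stats::runif(1, -25, 25),
      color = c(stats::runif(1, cr$h[1], cr$h[2]),
                stats::runif(1, cr$s[1], cr$s[2]),
                stats::runif(1, cr$v[1], cr$v[2])),
      fpc = fpc)
    p0 <- c(stats::runif(1, 250, 330), stats::runif(1, 195, 215))
    span <- stats::runif(1, 220, 300)
    p2 <- c(p0[1] + span, stats::runif(1, 195, 225))
    mid <- (p0 + p2) / 2
    p1 <- c(mid[1], mid[2] + stats::runif(1, -50, -20))
    vr <- VINE_COLOR_RANGE
    vine <- list(p0 = p0, p1 = p1, p2 = p2,
                 radius = stats::runif(1, 8, 12),
                 color = c(stats::runif(1, vr$h[1], vr$h[2]),
                           stats::runif(1, vr$s[1], vr$s[2]),
                           stats::runif(1, vr$v[1], vr$v[2])))
    ruler <- list(x0 = stats::runif(1, 725, 755), y0 = stats::runif(1, 50, 70),
                  angle_deg = stats::runif(1, -3, 3),
                  length_px = stats::runif(1, 400, 500), bar_width_px = 7)
    checker <- list(x0 = 15, y0 = 15, chip_px = 28, gap_px = 4,
                    colors = checker_reference_colors())
    scene_spec(seed = seed, canvas = c(600L, 800L), mm_per_px = mm_per_px,
               fruit = fruit, vine = vine, ruler = ruler, checker = checker,
               cast = cast, noise_sigma = noise_sigma)
  })
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a scene bundle from a specification
#'
#' Renders the image (hard edges, no anti-aliasing), the exact fruit and
#' vine masks, the chip grid, and the ground-truth record computed from
#' the spec geometry: fruit width `2b`, fruit length from the closed-form
#' ellipse medial axis `2(a^2 - b^2)/a`, vine length as the finely
#' integrated Bezier arc length, vine width `2 r`, all scaled by
#' `mm_per_px`. Deterministic for a fixed spec.
#'
#' @param spec a [scene_spec()].
#' @return List of class `scene_bundle` with `image`, `fruit_mask`,
#'   `vine_mask`, `chip_grid`, `truth` and `spec`. Errors with class
#'   `layout_error` when rendered elements overlap or leave the canvas.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$canvas[1]; W <- spec$canvas[2]
  img <- array(rep(spec$bg, each = H * W), c(H, W, 3))
  masks <- list()
  truth <- list(mm_per_px = spec$mm_per_px)

  if (!is.null(spec$checker)) {
    ck <- spec$checker
    grid <- regular_chip_grid(ck$x0, ck$y0, ck$chip_px, ck$gap_px)
    b <- grid$boxes
    if (any(b[, 1] < 0 | b[, 2] < 0 | b[, 3] > W | b[, 4] > H))
      layout_error("checker leaves the canvas")
    ck_mask <- matrix(FALSE, H, W)
    for (k in seq_len(24)) {
      rows <- (b[k, 2] + 1L):b[k, 4]
      cols <- (b[k, 1] + 1L):b[k, 3]
      for (ch in 1:3) img[rows, cols, ch] <- ck$colors[k, ch]
      ck_mask[rows, cols] <- TRUE
    }
    # reserve the full checker card footprint including gaps
    ck_mask[(ck$y0 + 1L):min(H, max(b[, 4])), (ck$x0 + 1L):min(W, max(b[, 3]))] <- TRUE
    masks$checker <- ck_mask
    truth$checker_colors <- ck$colors
  } else grid <- NULL

  if (!is.null(spec$ruler)) {
    rl <- spec$ruler
    ang <- rl$angle_deg * pi / 180
    p0 <- c(rl$x0, rl$y0)
    p1 <- p0 + rl$length_px * c(sin(ang), cos(ang))
    rl_mask <- segment_band_mask(H, W, p0, p1, rl$bar_width_px / 2)
    if (any(p0 < 0) || any(p1 < 0) || p0[1] >= W || p1[1] >= W ||
        p0[2] >= H || p1[2] >= H)
      layout_error("ruler leaves the canvas")
    for (ch in 1:3) {
      chm <- img[, , ch]; chm[rl_mask] <- 0.15; img[, , ch] <- chm
    }
    masks$ruler <- rl_mask
    truth$ruler <- list(x1 = p0[1], y1 = p0[2], x2 = p1[1], y2 = p1[2],
                        length_px = rl$length_px,
                        length_mm = rl$length_px * spec$mm_per_px)
  }

  if (!is.null(spec$vine)) {
    vn <- spec$vine
    poly <- bezier_polyline(vn$p0, vn$p1, vn$p2, n = 129)
    vine_mask <- polyline_tube_mask(H, W, poly, vn$radius)
    if (!any(vine_mask)) layout_error("vine renders empty")
    if (min(poly[, 1]) - vn$radius < 0 || max(poly[, 1]) + vn$radius >= W ||
        min(poly[, 2]) - vn$radius < 0 || max(poly[, 2]) + vn$radius >= H)
      layout_error("vine leaves the canvas")
    rgbv <- hsv_rows_to_rgb(matrix(vn$color, 1))
    for (ch in 1:3) {
      chm <- img[, , ch]; chm[vine_mask] <- rgbv[ch]; img[, , ch] <- chm
    }
    masks$vine <- vine_mask
    arc <- bezier_arc_length(vn$p0, vn$p1, vn$p2)
    truth$VL_mm <- arc * spec$mm_per_px
    truth$VW_mm <- 2 * vn$radius * spec$mm_per_px
    truth$vine_arc_px <- arc
    truth$vine_radius_px <- vn$radius
  }

  if (!is.null(spec$fruit)) {
    fr <- spec$fruit
    fruit_mask <- ellipse_mask(H, W, fr$cx, fr$cy, fr$a, fr$b, fr$theta_deg)
    if (!any(fruit_mask)) layout_error("fruit renders empty")
    ext_x <- fr$a * abs(cos(fr$theta_deg * pi / 180)) +
      fr$b * abs(sin(fr$theta_deg * pi / 180))
    ext_y <- fr$a * abs(sin(fr$theta_deg * pi / 180)) +
      fr$b * abs(cos(fr$theta_deg * pi / 180))
    if (fr$cx - ext_x < 0 || fr$cx + ext_x >= W ||
        fr$cy - ext_y < 0 || fr$cy + ext_y >= H)
      layout_error("fruit leaves the canvas")
    rgbf <- hsv_rows_to_rgb(matrix(fr$color, 1))
    for (ch in 1:3) {
      chm <- img[, , ch]; chm[fruit_mask] <- rgbf[ch]; img[, , ch] <- chm
    }
    masks$fruit <- fruit_mask
    truth$FW_mm <- 2 * fr$b * spec$mm_per_px
    truth$FL_mm <- 2 * (fr$a^2 - fr$b^2) / fr$a * spec$mm_per_px
    truth$fruit_medial_px <- 2 * (fr$a^2 - fr$b^2) / fr$a
    truth$fruit_a_px <- fr$a
    truth$fruit_b_px <- fr$b
    truth$FPC <- fr$fpc
  }

  nm <- names(masks)
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq(i + 1, length(nm))) {
        if (any(masks[[i]] & masks[[j]]))
          layout_error(sprintf("scene elements overlap: %s and %s",
                               nm[i], nm[j]))
      }
    }
  }

  if (!is.null(spec$cast)) img <- apply_color_cast(img, spec$cast)
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      clip01(img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                         dim(img)))
    })
  }
  truth$cast <- spec$cast

  structure(list(image = img,
                 fruit_mask = masks$fruit,
                 vine_mask = masks$vine,
                 chip_grid = grid,
                 truth = truth,
                 spec = spec),
            class = "scene_bundle")
}

layout_error <- function(msg) {
  stop(structure(class = c("layout_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# solid ellipse pixel set (pixel centers inside the ellipse)
ellipse_mask <- function(H, W, cx, cy, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  x <- rep(0:(W - 1), each = H) - cx
  y <- rep(0:(H - 1), times = W) - cy
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  matrix((u / a)^2 + (v / b)^2 <= 1, H, W)
}

# pixels within half_w of the segment p0-p1 (flat caps handled by the
# along-segment clamp, so the band is a stadium shape)
segment_band_mask <- function(H, W, p0, p1, half_w) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len
  x <- rep(0:(W - 1), each = H) - p0[1]
  y <- rep(0:(H - 1), times = W) - p0[2]
  along <- x * u[1] + y * u[2]
  along_c <- pmin(pmax(along, 0), len)
  dx <- x - along_c * u[1]
  dy <- y - along_c * u[2]
  matrix(dx^2 + dy^2 <= half_w^2, H, W)
}

bezier_polyline <- function(p0, p1, p2, n = 129) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

bezier_arc_length <- function(p0, p1, p2, n = 4097) {
  poly <- bezier_polyline(p0, p1, p2, n)
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

# pixels within `radius` of the polyline (union of segment stadiums),
# computed on the polyline bounding box for speed
polyline_tube_mask <- function(H, W, poly, radius) {
  x0 <- max(0L, floor(min(poly[, 1]) - radius - 1))
  x1 <- min(W - 1L, ceiling(max(poly[, 1]) + radius + 1))
  y0 <- max(0L, floor(min(poly[, 2]) - radius - 1))
  y1 <- min(H - 1L, ceiling(max(poly[, 2]) + radius + 1))
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  gx <- rep(x0:x1, each = ny)
  gy <- rep(y0:y1, times = nx)
  d2 <- rep(Inf, nx * ny)
  for (s in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[s, ]; p1 <- poly[s + 1L, ]
    d <- p1 - p0
    l2 <- sum(d^2)
    if (l2 == 0) next
    t <- ((gx - p0[1]) * d[1] + (gy - p0[2]) * d[2]) / l2
    t <- pmin(pmax(t, 0), 1)
    dd <- (gx - (p0[1] + t * d[1]))^2 + (gy - (p0[2] + t * d[2]))^2
    d2 <- pmin(d2, dd)
  }
  mask <- matrix(FALSE, H, W)
  sel <- d2 <= radius^2
  mask[cbind(gy[sel] + 1L, gx[sel] + 1L)] <- TRUE
  mask
}

#' Apply a color cast to an image
#'
#' Per-pixel multiplication by a 3 x 3 matrix followed by clipping to
#' `[0, 1]` — the same contract as [apply_correction()] with a zero
#' offset. Simulates a lighting-induced color shift. The number of
#' clipped samples is attached as attribute `n_clipped`.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param cast finite 3 x 3 matrix.
#' @return Cast image.
#' @export
apply_color_cast <- function(image, cast) {
  stopifnot(is.matrix(cast), all(dim(cast) == c(3L, 3L)))
  apply_correction(image, list(M = cast, offset = c(0, 0, 0)))
}

#' Draw a random invertible color cast
#'
#' A channel-mixing matrix: identity plus nonnegative uniform
#' perturbations up to `strength`, with rows normalized to sum to one.
#' Row-stochastic nonnegative mixing maps every in-gamut pixel to a
#' convex combination of its channels, so the cast never clips, is
#' diagonally dominant (hence invertible), and preserves neutral grays —
#' a simple model of a lighting-induced color shift.
#'
#' @param seed integer seed.
#' @param strength maximum off-diagonal mixing weight before
#'   normalization. Default 0.12.
#' @return A 3 x 3 matrix.
#' @export
random_color_cast <- function(seed, strength = 0.12) {
  with_seed(seed, {
    cast <- diag(1 + stats::runif(3, 0, strength)) +
      matrix(stats::runif(9, 0, strength), 3) * (1 - diag(3))
    cast / rowSums(cast)
  })
}

#' Embedded ground-truth/prediction worked example
#'
#' Ten pumpkin samples with manually measured (GT) and pipeline-predicted
#' values of the four quantitative properties plus peel color, along with
#' the originally reported per-sample metric rows (`printed`) for
#' cross-checking. Some printed cells are not arithmetically consistent
#' with the MAE/MAPE definitions; the `printed` element reproduces them
#' verbatim so tests can document the discrepancy.
#'
#' @return List with data frames `gt` and `pred` (columns `sample_id, FL,
#'   FW, VL, VW, FPC`) and `printed` (per-sample `accuracy_pct, mae,
#'   mape_pct` as originally reported).
#' @export
table2_fixture <- function() {
  ids <- paste0("S", 1:10)
  gt <- data.frame(
    sample_id = ids,
    FL = c(6.8, 27.8, 14.1, 8.4, 9.5, 22.6, 25.9, 6.2, 6.9, 6.3),
    FW = c(10.2, 9.6, 12.2, 12.9, 12.1, 9.2, 8.1, 8.6, 11.1, 9.7),
    VL = c(12.2, 10.3, 16.2, 12.8, 10.7, 10, 8.9, 14.8, 10.6, 6.5),
    VW = c(1.4, 0.9, 1.2, 1.64, 1.8, 0.67, 1, 1.1, 1.4, 1.6),
    FPC = c("G", "OR", "LG", "G", "G", "LG", "LG", "G", "G", "G"),
    stringsAsFactors = FALSE)
  pred <- data.frame(
    sample_id = ids,
    FL = c(6.8, 28.1, 14.1, 8.3, 9.2, 23, 26.1, 6.5, 7, 6.8),
    FW = c(9.9, 9.1, 12.3, 13.1, 12, 9.1, 8, 8.9, 11.5, 9.5),
    VL = c(12, 10.1, 15.9, 12.6, 10.9, 9.8, 8.4, 14.2, 10, 6.3),
    VW = c(1.4, 0.85, 1.3, 1.63, 1.8, 0.68, 1, 1.2, 1.3, 1.6),
    FPC = c("G", "OR", "LG", "G", "G", "LG", "LG", "G", "G", "G"),
    stringsAsFactors = FALSE)
  printed <- data.frame(
    sample_id = ids,
    accuracy_pct = c(99.7, 98.6, 100, 82.9, 100, 93.7, 96.1, 97.4, 99, 96.1),
    mae = c(0.12, 0.26, 0.12, 0.15, 0.15, 0.2, 0.2, 0.32, 0.3, 0.22),
    mape_pct = c(1.14, 4.4, 2.75, 2.6, 1.46, 1.58, 1.9, 1.9, 4.46, 3.2),
    stringsAsFactors = FALSE)
  list(gt = gt, pred = pred, printed = printed)
}

#' Default HSV threshold boxes for baseline scene segmentation
#'
#' Boxes covering the generator's fruit and vine color draws with a small
#' pad for noise tolerance; intended only for synthetic scenes with
#' controlled colors.
#'
#' @return Named list of per-component HSV box lists.
#' @export
default_component_ranges <- function() {
  list(
    fruit = list(
      list(h = c(90, 136), s = c(0.24, 0.78), v = c(0.28, 0.92)),  # G / LG
      list(h = c(9, 41), s = c(0.52, 0.98), v = c(0.42, 0.86))),   # OR
    vine = list(
      list(h = c(59, 91), s = c(0.38, 0.68), v = c(0.24, 0.52))))
}

#' Baseline HSV segmentation of a synthetic scene
#'
#' Stands in for an external instance-segmentation model on synthetic
#' scenes: thresholds each component's HSV color boxes and keeps the
#' largest connected component.
#'
#' @param image numeric `H x W x 3` array.
#' @param ranges per-component HSV box lists, see
#'   [default_component_ranges()].
#' @return List `fruit_mask, vine_mask` (logical matrices). Errors with
#'   class `missing_component` naming the component when no pixel matches.
#' @export
baseline_segment <- function(image, ranges = default_component_ranges()) {
  validate_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  hsv <- rgb_rows_to_hsv(matrix(image, ncol = 3L))
  out <- lapply(names(ranges), function(comp) {
    member <- rep(FALSE, H * W)
    for (b in ranges[[comp]]) member <- member | hsv_in_box(hsv, b)
    if (!any(member)) {
      stop(structure(class = c("missing_component", "error", "condition"),
                     list(message = paste0("no pixels match component '",
                                           comp, "'"),
                          call = NULL, component = comp)))
    }
    m <- matrix(member, H, W)
    # heal single-pixel dropout from sensor noise before selecting the
    # component (standard closing step for threshold segmentation)
    m <- EBImage::closing(m, EBImage::makeBrush(3, "box")) > 0
    largest_component(m)
  })
  names(out) <- paste0(names(ranges), "_mask")
  out
}

#' Write a scene bundle to a directory
#'
#' Writes `image.png`, `fruit_mask.png`, `vine_mask.png`, `truth.json`,
#' `chip_grid.json`, `scene_config.json` (the per-sample inputs a
#' measurement run needs: ruler length and reference chip colors) and
#' `coco.json` (COCO-style instance export, uncompressed RLE).
#'
#' @param bundle a [generate_scene()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(bundle$image, file.path(dir, "image.png"))
  if (!is.null(bundle$fruit_mask))
    write_mask(bundle$fruit_mask, file.path(dir, "fruit_mask.png"))
  if (!is.null(bundle$vine_mask))
    write_mask(bundle$vine_mask, file.path(dir, "vine_mask.png"))
  if (!is.null(bundle$chip_grid))
    write_chip_grid(bundle$chip_grid, file.path(dir, "chip_grid.json"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- list(ruler_length_mm = bundle$truth$ruler$length_mm,
              reference_colors = bundle$spec$checker$colors)
  jsonlite::write_json(cfg, file.path(dir, "scene_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_coco_instances(list(fruit = bundle$fruit_mask,
                            vine = bundle$vine_mask),
                       file.path(dir, "coco.json"))
  invisible(dir)
}
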