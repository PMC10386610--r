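# Ruler detection and pixel-to-millimetre calibration.
#
# The ruler placed in the frame is recovered by the classical chain
# grayscale -> Gaussian blur -> Canny edges -> Hough line transform; the
# selected segment's pixel length against the ruler's known physical
# length gives the mm-per-pixel scale used to convert all downstream
# pixel measurements to real units.

#' Parameters of the ruler-detection chain
#'
#' @param blur_sigma standard deviation (pixels) of the Gaussian blur
#'   applied to the grayscale image before edge detection. Default 2.
#' @param canny_low,canny_high hysteresis thresholds on the 8-bit gradient
#'   magnitude scale (0-255). Defaults 50 and 150.
#' @param hough_threshold minimum accumulator votes for a Hough line.
#'   Default 50.
#' @param min_line_frac minimum accepted segment length as a fraction of
#'   `max(H, W)`. Default 0.3.
#' @param max_gap_px segments broken by gaps of at most this many pixels
#'   along the line are merged. Default 10.
#' @return An object of class `ruler_params`.
#' @export
ruler_params <- function(blur_sigma = 2, canny_low = 50, canny_high = 150,
                         hough_threshold = 50, min_line_frac = 0.3,
                         max_gap_px = 10) {
  if (canny_low >= canny_high)
    stop("canny_low must be below canny_high", call. = FALSE)
  if (min_line_frac <= 0 || min_line_frac > 1)
    stop("min_line_frac must lie in (0, 1]", call. = FALSE)
  structure(list(blur_sigma = blur_sigma, canny_low = canny_low,
                 canny_high = canny_high, hough_threshold = hough_threshold,
                 min_line_frac = min_line_frac, max_gap_px = max_gap_px),
            class = "ruler_params")
}

#' Canny edge detection
#'
#' Sobel gradients on the (optionally pre-blurred) grayscale image,
#' non-maximum suppression along the quantized gradient direction, then
#' two-threshold hysteresis: weak edge pixels survive only when
#' 8-connected to a strong pixel. Thresholds are expressed on the 8-bit
#' gradient magnitude scale.
#'
#' @param gray numeric `H x W` matrix in `[0, 1]`.
#' @param low,high hysteresis thresholds (0-255 scale).
#' @return Logical `H x W` edge matrix.
#' @export
canny_edges <- function(gray, low = 50, high = 150) {
  stopifnot(is.matrix(gray))
  sob_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(gray, sob_x, boundary = "replicate")   # d/dx (columns)
  gy <- EBImage::filter2(gray, t(sob_x), boundary = "replicate") # d/dy (rows)
  mag <- sqrt(gx^2 + gy^2) * 255
  # quantize gradient direction to 0/45/90/135 degrees
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  H <- nrow(gray); W <- ncol(gray)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mag
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  nb <- function(dy, dx) pad[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx]
  # gradient along x (sector 0) -> compare left/right neighbours, etc.
  keep <- (sector == 0L & ctr >= nb(0L, -1L) & ctr >= nb(0L, 1L)) |
          (sector == 45L & ctr >= nb(-1L, 1L) & ctr >= nb(1L, -1L)) |
          (sector == 90L & ctr >= nb(-1L, 0L) & ctr >= nb(1L, 0L)) |
          (sector == 135L & ctr >= nb(-1L, -1L) & ctr >= nb(1L, 1L))
  nms <- mag * keep
  strong <- nms >= high
  weak <- nms >= low & !strong
  edges <- hysteresis_grow(strong, weak)
  # gradient orientation (normal direction of the local edge), mod pi;
  # used by the Hough stage for orientation-selective support
  attr(edges, "grad_theta") <- atan2(gy, gx) %% pi
  edges
}

# 8-connected hysteresis: grow the strong set into adjacent weak pixels.
hysteresis_grow <- function(strong, weak) {
  H <- nrow(strong); W <- ncol(strong)
  result <- strong
  frontier <- strong
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  while (any(frontier)) {
    grown <- matrix(FALSE, H, W)
    for (k in seq_len(nrow(shifts))) {
      dy <- shifts$dy[k]; dx <- shifts$dx[k]
      src_r <- max(1, 1 - dy):min(H, H - dy)
      src_c <- max(1, 1 - dx):min(W, W - dx)
      grown[src_r + dy, src_c + dx] <-
        grown[src_r + dy, src_c + dx] | frontier[src_r, src_c]
    }
    frontier <- grown & weak & !result
    result <- result | frontier
  }
  result
}

#' Extract line segments with a Hough transform
#'
#' Standard `(rho, theta)` accumulator voting over edge pixels followed by
#' peak picking with neighbourhood suppression; for each peak line the
#' supporting edge pixels are projected onto the line direction, split at
#' gaps larger than `max_gap_px`, and runs at least `min_len` long are
#' returned as endpoint segments — the probabilistic-Hough style output.
#'
#' @param edges logical edge matrix from [canny_edges()].
#' @param threshold minimum accumulator votes for a candidate line.
#' @param min_len minimum segment length in pixels.
#' @param max_gap_px gap tolerance along the line in pixels.
#' @param theta_step accumulator angular resolution in degrees.
#' @return Data frame with 0-based endpoint columns `x1, y1, x2, y2`,
#'   `length` (pixels) and `theta_deg` (line normal angle), one row per
#'   segment, sorted by decreasing length.
#' @export
hough_segments <- function(edges, threshold = 50, min_len = 50,
                           max_gap_px = 10, theta_step = 1) {
  stopifnot(is.matrix(edges))
  idx <- which(edges)
  if (length(idx) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0),
                      theta_deg = numeric(0)))
  H <- nrow(edges)
  y <- (idx - 1L) %% H          # 0-based row
  x <- (idx - 1L) %/% H         # 0-based column
  grad <- attr(edges, "grad_theta")
  gtheta <- if (is.null(grad)) NULL else grad[idx]
  # angular distance mod pi between pixel gradients and a line normal;
  # the tolerance admits blur-rotated gradients near segment ends while
  # still rejecting pixels that wrap around end caps (rotated >= 45 deg)
  ang_ok <- function(theta, tol = pi / 6) {
    if (is.null(gtheta)) return(rep(TRUE, length(x)))
    dd <- abs(gtheta - theta %% pi)
    pmin(dd, pi - dd) <= tol
  }
  thetas <- seq(0, 180 - theta_step, by = theta_step) * pi / 180
  n_t <- length(thetas)
  diag_len <- ceiling(sqrt(H^2 + ncol(edges)^2))
  rho_off <- diag_len + 1L
  n_rho <- 2L * diag_len + 3L
  acc <- matrix(0L, n_rho, n_t)
  rho_all <- outer(x, cos(thetas)) + outer(y, sin(thetas))  # n_px x n_t
  rho_idx <- round(rho_all) + rho_off + 1L
  for (t in seq_len(n_t)) {
    tab <- tabulate(rho_idx[, t], nbins = n_rho)
    acc[, t] <- tab
  }
  # peak picking with greedy suppression of a (rho, theta) neighbourhood
  cand <- which(acc >= threshold)
  if (length(cand) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0),
                      theta_deg = numeric(0)))
  ord <- cand[order(acc[cand], decreasing = TRUE)]
  suppressed <- rep(FALSE, length(ord))
  pr <- (ord - 1L) %% n_rho + 1L
  pt <- (ord - 1L) %/% n_rho + 1L
  segs <- list()
  for (i in seq_along(ord)) {
    if (suppressed[i]) next
    ri <- pr[i]; ti <- pt[i]
    # suppress neighbours (theta wraps at 180 with rho sign flip ignored;
    # plain window is adequate at 1-degree resolution)
    suppressed <- suppressed | (abs(pr - ri) <= 2L &
                                pmin(abs(pt - ti), n_t - abs(pt - ti)) <= 2L)
    theta <- thetas[ti]
    rho <- ri - rho_off - 1L
    # refine the accumulator line by total least squares on a wide support
    # band, then keep pixels close to the refined line; this recovers
    # lines falling between accumulator cells
    d <- x * cos(theta) + y * sin(theta) - rho
    support <- abs(d) <= 3 & ang_ok(theta)
    if (sum(support) >= 2L) {
      xs0 <- x[support]; ys0 <- y[support]
      mx <- mean(xs0); my <- mean(ys0)
      cv <- cbind(xs0 - mx, ys0 - my)
      eg <- eigen(crossprod(cv) / length(xs0), symmetric = TRUE)
      nrm <- eg$vectors[, 2]                   # normal = minor axis
      theta <- atan2(nrm[2], nrm[1])
      if (theta < 0) { theta <- theta + pi; nrm <- -nrm }
      rho <- mx * cos(theta) + my * sin(theta)
      d <- x * cos(theta) + y * sin(theta) - rho
    }
    on_line <- abs(d) <= 1.5 & ang_ok(theta)
    if (sum(on_line) < 2L) next
    tx <- -sin(theta); ty <- cos(theta)        # unit direction along the line
    tpos <- x[on_line] * tx + y[on_line] * ty
    o <- order(tpos)
    xs <- x[on_line][o]; ys <- y[on_line][o]; tp <- tpos[o]
    brk <- c(0L, which(diff(tp) > max_gap_px), length(tp))
    for (s in seq_len(length(brk) - 1L)) {
      a <- brk[s] + 1L; b <- brk[s + 1L]
      len <- sqrt((xs[b] - xs[a])^2 + (ys[b] - ys[a])^2)
      if (len >= min_len) {
        segs[[length(segs) + 1L]] <-
          c(xs[a], ys[a], xs[b], ys[b], len, theta * 180 / pi)
      }
    }
  }
  if (length(segs) == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0),
                      theta_deg = numeric(0)))
  m <- do.call(rbind, segs)
  df <- data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4],
                   length = m[, 5], theta_deg = m[, 6])
  df[order(df$length, decreasing = TRUE), , drop = FALSE]
}

#' Detect the ruler in an image
#'
#' Runs the full chain: luminance grayscale, Gaussian blur, Canny edge
#' detection, Hough segment extraction; then selects the longest segment
#' at least `min_line_frac * max(H, W)` pixels long. Length ties are
#' broken by the smaller angular deviation from vertical, then by the
#' smaller `x1`.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param params a [ruler_params()] object.
#' @return A `line_segment`: list with 0-based `x1, y1, x2, y2` and
#'   `length` (pixels). Errors with class `ruler_not_found` (carrying the
#'   candidate count in `n_candidates`) when no segment qualifies.
#' @export
detect_ruler <- function(image, params = ruler_params()) {
  validate_image(image)
  stopifnot(inherits(params, "ruler_params"))
  gray <- to_gray(image)
  blurred <- gaussian_blur(gray, params$blur_sigma)
  edges <- canny_edges(blurred, params$canny_low, params$canny_high)
  min_len <- params$min_line_frac * max(dim(gray))
  segs <- hough_segments(edges, threshold = params$hough_threshold,
                         min_len = min_len, max_gap_px = params$max_gap_px)
  if (nrow(segs) == 0L) {
    cond <- structure(
      class = c("ruler_not_found", "error", "condition"),
      list(message = sprintf(
             "no line segment of at least %.0f px found (0 qualifying candidates)",
             min_len),
           call = sys.call(-1), n_candidates = 0L))
    stop(cond)
  }
  # tie-break: most vertical (segment direction closest to the y axis), then x1
  dx <- segs$x2 - segs$x1; dy <- segs$y2 - segs$y1
  vert_dev <- abs(atan2(abs(dx), abs(dy))) * 180 / pi   # 0 when vertical
  ord <- order(-segs$length, vert_dev, segs$x1)
  best <- segs[ord[1L], ]
  structure(list(x1 = best$x1, y1 = best$y1, x2 = best$x2, y2 = best$y2,
                 length = best$length, n_candidates = nrow(segs)),
            class = "line_segment")
}

#' Pixel length of a line segment
#'
#' @param line a `line_segment` or list with `x1, y1, x2, y2`.
#' @return Euclidean distance between the endpoints, in pixels.
#' @export
segment_length <- function(line) {
  sqrt((line$x2 - line$x1)^2 + (line$y2 - line$y1)^2)
}

#' Convert a detected ruler line to a pixel scale
#'
#' @param line a `line_segment` (detected ruler).
#' @param ruler_length_mm physical length in millimetres of the ruler span
#'   corresponding to the detected segment.
#' @return A `pixel_scale` object with element `mm_per_px`.
#' @export
compute_scale <- function(line, ruler_length_mm) {
  len <- segment_length(line)
  if (!is.finite(len) || len <= 0)
    stop("degenerate ruler line: zero pixel length", call. = FALSE)
  if (!is.finite(ruler_length_mm) || ruler_length_mm <= 0)
    stop("ruler_length_mm must be a positive number", call. = FALSE)
  structure(list(mm_per_px = ruler_length_mm / len), class = "pixel_scale")
}

#' Convert pixel distances to millimetres
#'
#' @param value_px distance(s) in pixels.
#' @param scale a `pixel_scale` from [compute_scale()].
#' @return `value_px * mm_per_px`.
#' @export
px_to_mm <- function(value_px, scale) {
  stopifnot(inherits(scale, "pixel_scale"))
  value_px * scale$mm_per_px
}
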