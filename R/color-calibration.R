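# Color-checker based color correction.
#
# A 24-patch checker photographed in both a reference frame and a working
# frame gives 24 paired RGB observations; a 3x3 (or affine 3x3 + offset)
# matrix M is estimated by least squares so that M * source ~ reference,
# then applied per pixel (with clipping) to bring the working image into
# the reference color frame.

#' Construct a chip-grid specification for a 24-patch color checker
#'
#' The grid locates the 24 chips of a 4 x 6 checker as axis-aligned pixel
#' rectangles in row-major order. Rectangles use 0-based, half-open
#' `(x_min, y_min, x_max, y_max)` coordinates: pixel column `x` is inside
#' when `x_min <= x < x_max`.
#'
#' @param boxes numeric `24 x 4` matrix (or data frame) of rectangles,
#'   columns `x_min, y_min, x_max, y_max`.
#' @param sample_margin fraction of each rectangle's width/height excluded
#'   at every border before averaging, in `[0, 0.5)`. Default `0.2`.
#' @param rows,cols grid shape; must multiply to 24.
#' @return An object of class `chip_grid`.
#' @export
chip_grid <- function(boxes, sample_margin = 0.2, rows = 4L, cols = 6L) {
  boxes <- as.matrix(boxes)
  if (rows * cols != 24L) stop("chip grid must have 24 chips", call. = FALSE)
  if (!is.numeric(boxes) || nrow(boxes) != 24L || ncol(boxes) != 4L)
    stop("boxes must be a 24 x 4 numeric matrix", call. = FALSE)
  if (any(boxes[, 3] <= boxes[, 1]) || any(boxes[, 4] <= boxes[, 2]))
    stop("each chip box must have positive width and height", call. = FALSE)
  if (sample_margin < 0 || sample_margin >= 0.5)
    stop("sample_margin must lie in [0, 0.5)", call. = FALSE)
  # pairwise disjointness (axis-aligned half-open rectangles)
  for (i in seq_len(23L)) {
    for (j in seq(i + 1L, 24L)) {
      overlap_x <- boxes[i, 1] < boxes[j, 3] && boxes[j, 1] < boxes[i, 3]
      overlap_y <- boxes[i, 2] < boxes[j, 4] && boxes[j, 2] < boxes[i, 4]
      if (overlap_x && overlap_y)
        stop("chip boxes ", i, " and ", j, " overlap", call. = FALSE)
    }
  }
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  structure(list(boxes = boxes, sample_margin = sample_margin,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "chip_grid")
}

#' Build a regularly spaced chip grid
#'
#' Convenience constructor for a checker rendered as a regular 4 x 6 array
#' of square chips, as produced by [generate_scene()].
#'
#' @param x0,y0 0-based pixel coordinates of the top-left corner of chip 1.
#' @param chip_px side length of each chip in pixels.
#' @param gap_px gap between neighbouring chips in pixels.
#' @param sample_margin see [chip_grid()].
#' @return A `chip_grid` object.
#' @export
regular_chip_grid <- function(x0, y0, chip_px, gap_px = 0, sample_margin = 0.2) {
  idx <- expand.grid(col = 0:5, row = 0:3)
  xmin <- x0 + idx$col * (chip_px + gap_px)
  ymin <- y0 + idx$row * (chip_px + gap_px)
  chip_grid(cbind(xmin, ymin, xmin + chip_px, ymin + chip_px),
            sample_margin = sample_margin)
}

#' Read or write a chip grid as JSON/YAML
#'
#' The on-disk format is a list of 24 rectangles `(x_min, y_min, x_max,
#' y_max)` (0-based, half-open) plus the `sample_margin`.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_chip_grid` returns a `chip_grid`; `write_chip_grid`
#'   returns `path` invisibly.
#' @export
read_chip_grid <- function(path) {
  obj <- read_config_file(path)
  boxes <- if (is.matrix(obj$boxes)) obj$boxes else
    do.call(rbind, lapply(obj$boxes, function(b) unlist(b)[1:4]))
  chip_grid(boxes, sample_margin = obj$sample_margin %||% 0.2)
}

#' @rdname read_chip_grid
#' @param grid a `chip_grid` object.
#' @export
write_chip_grid <- function(grid, path) {
  obj <- list(sample_margin = grid$sample_margin,
              boxes = lapply(seq_len(24), function(k) as.numeric(grid$boxes[k, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Average RGB of each color-checker chip
#'
#' For each of the 24 chip rectangles, shrinks the rectangle by the grid's
#' `sample_margin` on every side and averages the remaining pixels per
#' channel.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param grid a [chip_grid()] locating the 24 chips.
#' @return Numeric `24 x 3` matrix of per-chip mean RGB in `[0, 1]`.
#' @export
extract_chip_means <- function(image, grid) {
  validate_image(image)
  stopifnot(inherits(grid, "chip_grid"))
  H <- dim(image)[1]; W <- dim(image)[2]
  b <- grid$boxes
  if (any(b[, 1] < 0) || any(b[, 2] < 0) || any(b[, 3] > W) || any(b[, 4] > H))
    stop("chip box outside image bounds", call. = FALSE)
  means <- matrix(NA_real_, 24L, 3L, dimnames = list(NULL, c("r", "g", "b")))
  m <- grid$sample_margin
  for (k in seq_len(24L)) {
    w <- b[k, 3] - b[k, 1]; h <- b[k, 4] - b[k, 2]
    x0 <- b[k, 1] + m * w; x1 <- b[k, 3] - m * w
    y0 <- b[k, 2] + m * h; y1 <- b[k, 4] - m * h
    cols <- seq.int(floor(x0) + 1L, ceiling(x1))        # 1-based columns
    rows <- seq.int(floor(y0) + 1L, ceiling(y1))
    cols <- cols[cols - 1 >= x0 - 1e-9 & cols - 1 < x1 - 1e-9]
    rows <- rows[rows - 1 >= y0 - 1e-9 & rows - 1 < y1 - 1e-9]
    if (length(cols) < 1L || length(rows) < 1L)
      stop("chip ", k, " is empty after margin shrink", call. = FALSE)
    means[k, ] <- apply(image[rows, cols, , drop = FALSE], 3, mean)
  }
  means
}

#' Fit a color-correction matrix from paired chip colors
#'
#' Estimates the matrix `M` (and, for the affine model, offset `b`) that
#' minimizes the summed squared RGB residuals `sum_k || M s_k (+ b) - r_k ||^2`
#' over the 24 chip pairs, so that applying the result to the source image
#' reproduces the reference colors.
#'
#' @param source numeric `24 x 3` chip means of the image to be corrected.
#' @param reference numeric `24 x 3` chip means of the reference image.
#' @param model `"linear"` for a pure 3x3 matrix (the default) or
#'   `"affine"` for a 3x3 matrix plus 3-vector offset.
#' @param max_condition fits are rejected when the condition number of the
#'   source chip matrix exceeds this bound (near-collinear chip colors make
#'   the normal equations meaningless). Default `1e8`.
#' @return An object of class `correction_matrix` with elements `M` (3x3),
#'   `offset` (3-vector, zero for the linear model), `model`, `condition`
#'   and `residual` (root-mean-square residual over chips).
#' @export
fit_correction_matrix <- function(source, reference,
                                  model = c("linear", "affine"),
                                  max_condition = 1e8) {
  model <- match.arg(model)
  source <- as.matrix(source); reference <- as.matrix(reference)
  if (nrow(source) != 24L || nrow(reference) != 24L ||
      ncol(source) != 3L || ncol(reference) != 3L)
    stop("source and reference must both be 24 x 3 chip matrices", call. = FALSE)
  sv <- svd(source)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf(
      "ill-conditioned fit: source chip matrix condition number %.3g exceeds %.3g",
      cond, max_condition), call. = FALSE)
  X <- if (model == "affine") cbind(source, 1) else source
  beta <- qr.solve(X, reference)           # solves X beta ~ reference, LS
  if (model == "affine") {
    M <- t(beta[1:3, , drop = FALSE])
    offset <- as.numeric(beta[4, ])
  } else {
    M <- t(beta)
    offset <- c(0, 0, 0)
  }
  fitted <- source %*% t(M) + rep(offset, each = 24L)
  rss <- sum((fitted - reference)^2)
  structure(list(M = unname(M), offset = offset, model = model,
                 condition = cond, residual = sqrt(rss / 24)),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("color correction matrix (%s model), condition %.3g, RMS residual %.3g\n",
              x$model, x$condition, x$residual))
  print(x$M)
  if (any(x$offset != 0)) cat("offset:", format(x$offset), "\n")
  invisible(x)
}

#' Apply a color-correction matrix to an image
#'
#' Every pixel `p` is replaced by `clip(M p + offset, 0, 1)`. The number of
#' out-of-gamut samples clipped is attached as attribute `n_clipped`.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param cm a [fit_correction_matrix()] result, or a plain 3x3 matrix.
#' @return Corrected image of identical dimensions.
#' @export
apply_correction <- function(image, cm) {
  validate_image(image)
  if (is.matrix(cm)) cm <- list(M = cm, offset = c(0, 0, 0))
  if (!all(is.finite(cm$M)) || !all(is.finite(cm$offset)))
    stop("correction matrix must be finite", call. = FALSE)
  d <- dim(image)
  px <- matrix(image, ncol = 3L)           # (H*W) x 3, column-major per channel
  out <- px %*% t(cm$M) + rep(cm$offset, each = nrow(px))
  n_clipped <- sum(out < 0 | out > 1)
  out <- clip01(out)
  res <- array(out, d)
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Per-channel linearity diagnostics for checker chips
#'
#' Under stable lighting, reference chip values should be an affine
#' function of source chip values channel by channel. This fits the
#' least-squares line reference ~ source per channel and flags chips whose
#' residual exceeds `flag_sd` residual standard deviations — the
#' "problematic chips" that deviate from the linear trend.
#'
#' @param source,reference numeric `24 x 3` chip matrices.
#' @param flag_sd flagging threshold in residual standard deviations
#'   (default 2).
#' @return A list with one element per channel (`r`, `g`, `b`), each
#'   containing `slope`, `intercept`, `r_squared`, `flagged` (chip indices)
#'   and `undefined` (TRUE when the source channel has zero variance).
#' @export
linearity_report <- function(source, reference, flag_sd = 2) {
  source <- as.matrix(source); reference <- as.matrix(reference)
  stopifnot(nrow(source) == 24L, nrow(reference) == 24L)
  out <- lapply(1:3, function(ch) {
    x <- source[, ch]; y <- reference[, ch]
    if (stats::var(x) < 1e-20) {
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, flagged = integer(0),
                  undefined = TRUE))
    }
    fit <- stats::lm.fit(cbind(1, x), y)
    resid <- fit$residuals
    ssr <- sum(resid^2); sst <- sum((y - mean(y))^2)
    r2 <- if (sst < 1e-20) 1 else 1 - ssr / sst
    s <- sqrt(ssr / max(1L, length(x) - 2L))
    flagged <- if (s < 1e-12) integer(0) else which(abs(resid) > flag_sd * s)
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r_squared = r2, flagged = as.integer(flagged), undefined = FALSE)
  })
  names(out) <- c("r", "g", "b")
  out
}

#' Read or write a correction matrix as JSON
#'
#' The JSON carries the 3x3 matrix row-major plus the optional offset.
#'
#' @param path JSON file path.
#' @return `read_correction_matrix` returns a `correction_matrix`;
#'   `write_correction_matrix` returns `path` invisibly.
#' @export
read_correction_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(as.numeric(obj$M), 3L, 3L, byrow = TRUE)
  offset <- as.numeric(obj$offset %||% c(0, 0, 0))
  structure(list(M = M, offset = offset,
                 model = obj$model %||% "linear",
                 condition = obj$condition %||% NA_real_,
                 residual = obj$residual %||% NA_real_),
            class = "correction_matrix")
}

#' @rdname read_correction_matrix
#' @param cm a `correction_matrix` object.
#' @export
write_correction_matrix <- function(cm, path) {
  obj <- list(M = as.numeric(t(cm$M)), offset = cm$offset, model = cm$model,
              condition = cm$condition, residual = cm$residual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared JSON/YAML config reader.
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format: ", ext, call. = FALSE)
}
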