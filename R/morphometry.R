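# Morphometry of masked pumpkin components.
#
# Lengths come from the medial-axis skeleton of the mask: the mask is
# thinned to a one-pixel-wide skeleton, the longest 8-connected path
# through it is taken as the centerline, and its length is the pixel sum
# along the path (calibration factor 1 per pixel). Widths come either
# from affine axis alignment (fit ellipse, rotate the mask so the major
# axis is horizontal, take the perpendicular pixel extent) or, for curved
# tubes such as vines, from twice the median medial-axis radius.

#' Fit an ellipse to a mask by image moments
#'
#' The center is the foreground centroid; axis lengths and orientation
#' come from the eigen-decomposition of the second central moment matrix,
#' scaled so that a solid ellipse is recovered exactly (full axis length
#' `4 * sqrt(eigenvalue)`).
#'
#' @param mask logical matrix with at least 5 non-collinear foreground
#'   pixels.
#' @return List of class `ellipse_params` with `cx, cy` (0-based center),
#'   `major_px, minor_px` (full axis lengths) and `theta_deg` (major-axis
#'   angle from the +x axis in the image frame, in `(-90, 90]`).
#' @export
fit_ellipse <- function(mask) {
  mask <- validate_mask(mask)
  idx <- which(mask)
  if (length(idx) < 5L)
    stop("degenerate mask: fewer than 5 foreground pixels", call. = FALSE)
  H <- nrow(mask)
  y <- (idx - 1L) %% H
  x <- (idx - 1L) %/% H
  cx <- mean(x); cy <- mean(y)
  xc <- x - cx; yc <- y - cy
  cov <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2L)
  eg <- eigen(cov, symmetric = TRUE)
  if (eg$values[2] < 1e-9)
    stop("degenerate mask: foreground pixels are collinear", call. = FALSE)
  major <- 4 * sqrt(eg$values[1])
  minor <- 4 * sqrt(eg$values[2])
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  structure(list(cx = cx, cy = cy, major_px = major, minor_px = minor,
                 theta_deg = theta),
            class = "ellipse_params")
}

#' Rotate a mask so its major axis is horizontal
#'
#' Applies the affine rotation by `-theta` about the ellipse center with
#' nearest-neighbour resampling. The output canvas is enlarged so no
#' foreground pixel is clipped.
#'
#' @param mask logical matrix.
#' @param ellipse an [fit_ellipse()] result (or any list with `cx, cy,
#'   theta_deg`).
#' @return Logical matrix containing the rotated mask.
#' @export
align_to_axes <- function(mask, ellipse) {
  mask <- validate_mask(mask)
  theta <- ellipse$theta_deg * pi / 180
  H <- nrow(mask); W <- ncol(mask)
  ct <- cos(-theta); st <- sin(-theta)
  # forward-map the canvas corner pixel centers to size the output
  corners_x <- c(0, W - 1, 0, W - 1)
  corners_y <- c(0, 0, H - 1, H - 1)
  fx <- ct * (corners_x - ellipse$cx) - st * (corners_y - ellipse$cy) + ellipse$cx
  fy <- st * (corners_x - ellipse$cx) + ct * (corners_y - ellipse$cy) + ellipse$cy
  off_x <- floor(min(fx)); off_y <- floor(min(fy))
  out_W <- ceiling(max(fx)) - off_x + 1L
  out_H <- ceiling(max(fy)) - off_y + 1L
  # inverse-map every output pixel center and sample nearest neighbour
  gx <- rep(seq_len(out_W) - 1L + off_x, each = out_H)
  gy <- rep(seq_len(out_H) - 1L + off_y, times = out_W)
  ci <- cos(theta); si <- sin(theta)
  sx <- round(ci * (gx - ellipse$cx) - si * (gy - ellipse$cy) + ellipse$cx)
  sy <- round(si * (gx - ellipse$cx) + ci * (gy - ellipse$cy) + ellipse$cy)
  ok <- sx >= 0 & sx < W & sy >= 0 & sy < H
  vals <- rep(FALSE, out_H * out_W)
  vals[ok] <- mask[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  matrix(vals, out_H, out_W)
}

#' Perpendicular extent of an axis-aligned mask
#'
#' For a mask already aligned so its major axis is parallel to x, the
#' width is the farthest-point extent perpendicular to it:
#' `max(y) - min(y) + 1` over foreground pixels.
#'
#' @param mask logical matrix (axis-aligned).
#' @return Width in pixels.
#' @export
measure_width_px <- function(mask) {
  mask <- validate_mask(mask)
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0L)
    stop("degenerate mask: no foreground pixels", call. = FALSE)
  max(rows) - min(rows) + 1
}

#' Medial-axis skeleton of a mask
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen iterative
#' thinning), attaches the medial-axis radius (Euclidean distance to the
#' nearest background pixel) at every skeleton pixel, and extracts the
#' longest path through the 8-connected skeleton graph by a double
#' breadth-first search from the lexicographically smallest endpoint (ties
#' broken toward the smaller `(x, y)`).
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return List of class `skeleton` with `pixels` (n x 2 matrix of 0-based
#'   `(x, y)` skeleton pixels), `radius` (medial radius per skeleton
#'   pixel), `path` (m x 2 ordered pixel sequence of the longest path) and
#'   `path_radius`.
#' @export
skeletonize_mask <- function(mask) {
  mask <- validate_mask(mask)
  idx <- which(mask)
  if (length(idx) == 0L)
    stop("degenerate mask: no foreground pixels", call. = FALSE)
  H <- nrow(mask)
  y_all <- (idx - 1L) %% H
  x_all <- (idx - 1L) %/% H
  # crop to bounding box (+4 px background ring) for speed; exact because
  # everything outside the bounding box is background
  y0 <- min(y_all); y1 <- max(y_all); x0 <- min(x_all); x1 <- max(x_all)
  sub <- matrix(FALSE, y1 - y0 + 9L, x1 - x0 + 9L)
  sub[cbind(y_all - y0 + 5L, x_all - x0 + 5L)] <- TRUE
  dm <- EBImage::distmap(sub)
  skel <- zhang_suen_thin(sub, anchor = maximal_ball_centers(sub, dm))
  sk_idx <- which(skel)
  hs <- nrow(sub)
  sy <- (sk_idx - 1L) %% hs
  sx <- (sk_idx - 1L) %/% hs
  radius <- dm[sk_idx]
  # back to full-image 0-based coordinates
  px <- cbind(x = sx - 5L + x0, y = sy - 5L + y0)
  path_i <- skeleton_longest_path(sx, sy, hs)
  path <- cbind(x = sx[path_i] - 5L + x0, y = sy[path_i] - 5L + y0)
  structure(list(pixels = px, radius = as.numeric(radius),
                 path = path, path_radius = as.numeric(radius[path_i])),
            class = "skeleton")
}

# Centers of maximal inscribed disks: off the medial axis the distance
# transform grows at unit rate along the direction away from the nearest
# boundary point; on the distance ridge no direction grows that fast.
# Pixels where no probe direction exceeds a quantization- and
# jitter-corrected growth rate are kept as medial-axis anchors during
# thinning, so blunt shapes keep their true medial axis instead of
# collapsing to a point.
maximal_ball_centers <- function(m, dm) {
  H <- nrow(m); W <- ncol(m)
  contained <- matrix(FALSE, H, W)
  # probe rings of radius 1..4. A probe at angular mismatch psi from the
  # true growth direction measures rate cos(psi); rasterized boundaries
  # additionally jitter distances by about half a pixel. Each ring's
  # threshold backs off its direction-set quantization plus the jitter
  # spread over its length: long probes resolve slow-looking growth that
  # short probes cannot, while the radius-1 ring doubles as non-maximum
  # suppression one step below a ridge crest.
  probes <- NULL
  ring_rate <- c(0.95, 0.85, 0.85, 0.82)
  for (r in 1:4) {
    off <- unique(rbind(cbind(-r:r, -r), cbind(-r:r, r),
                        cbind(-r, -r:r), cbind(r, -r:r)))
    probes <- rbind(probes, cbind(off, ring_rate[r]))
  }
  dist <- sqrt(probes[, 1]^2 + probes[, 2]^2)
  pad <- 4L
  core_r <- (pad + 1L):(H - pad); core_c <- (pad + 1L):(W - pad)
  ctr <- dm[core_r, core_c]
  for (k in seq_len(nrow(probes))) {
    nbv <- dm[core_r + probes[k, 1], core_c + probes[k, 2]]
    contained[core_r, core_c] <- contained[core_r, core_c] |
      (nbv - ctr >= probes[k, 3] * dist[k])
  }
  # below the 2-px probe scale the discrete distance transform is
  # dominated by boundary jaggedness; such rim pixels of blunt shapes are
  # not reliable ridge evidence. Thin structures need no anchoring:
  # thinning already preserves them.
  m & !contained & dm >= 2
}

# Vectorized Zhang-Suen thinning; input and output are logical matrices
# with a guaranteed one-pixel background border. Pixels in `anchor` are
# never removed (medial-axis anchoring).
zhang_suen_thin <- function(m, anchor = NULL) {
  H <- nrow(m); W <- ncol(m)
  nb <- function(mat, dy, dx) {
    out <- matrix(FALSE, H, W)
    out[2:(H - 1L), 2:(W - 1L)] <-
      mat[(2:(H - 1L)) + dy, (2:(W - 1L)) + dx]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- nb(m, -1L, 0L); p3 <- nb(m, -1L, 1L); p4 <- nb(m, 0L, 1L)
      p5 <- nb(m, 1L, 1L);  p6 <- nb(m, 1L, 0L);  p7 <- nb(m, 1L, -1L)
      p8 <- nb(m, 0L, -1L); p9 <- nb(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (!is.null(anchor)) cond <- cond & !anchor
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Longest path through the 8-connected skeleton pixel graph restricted to
# its largest connected component: double BFS with lexicographic (x, y)
# tie-breaking. Arguments are 0-based pixel coordinates within a matrix of
# height hs; returns indices into (sx, sy).
skeleton_longest_path <- function(sx, sy, hs) {
  n <- length(sx)
  if (n == 1L) return(1L)
  key <- sx * hs + sy           # unique integer per pixel
  lookup <- new.env(hash = TRUE, size = n)
  # vectorized neighbour edges via coordinate matching
  ord_key <- order(key)
  pos <- integer(0)
  edges <- NULL
  km <- key
  shifts <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in seq_len(nrow(shifts))) {
    nk <- (sx + shifts[s, 1]) * hs + (sy + shifts[s, 2])
    mt <- match(nk, km)
    ok <- !is.na(mt)
    if (any(ok)) edges <- rbind(edges, cbind(which(ok), mt[ok]))
  }
  if (is.null(edges)) {
    # isolated pixels only: return the lexicographically smallest
    return(order(sx, sy)[1L])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  lex <- function(cand) cand[order(sx[cand], sy[cand])][1L]
  farthest <- function(from) {
    d <- as.numeric(igraph::distances(g, v = from, to = members))
    reach <- members[is.finite(d)]
    dd <- d[is.finite(d)]
    cand <- reach[dd == max(dd)]
    lex(cand)
  }
  u <- farthest(lex(members))
  v <- farthest(u)
  p <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
  as.integer(p)
}

#' Skeleton-path length in pixels
#'
#' With `step_model = "pixel_count"` (the default) the length is the
#' number of pixels along the longest skeleton path — a unit contribution
#' per pixel, i.e. a direct pixel summation with calibration factor 1.
#' `"euclidean"` instead sums the step distances (1 for axial moves,
#' `sqrt(2)` for diagonal moves). `scope = "total_pixels"` counts every
#' skeleton pixel rather than only the longest path (literal pixel
#' summation over a possibly branched skeleton).
#'
#' @param skel a [skeletonize_mask()] result.
#' @param step_model `"pixel_count"` or `"euclidean"`.
#' @param scope `"longest_path"` (default) or `"total_pixels"`.
#' @return Length in pixel units.
#' @export
measure_length_px <- function(skel,
                              step_model = c("pixel_count", "euclidean"),
                              scope = c("longest_path", "total_pixels")) {
  step_model <- match.arg(step_model)
  scope <- match.arg(scope)
  stopifnot(inherits(skel, "skeleton"))
  if (scope == "total_pixels") return(nrow(skel$pixels))
  path <- skel$path
  if (nrow(path) == 0L) stop("empty skeleton path", call. = FALSE)
  if (step_model == "pixel_count") return(nrow(path))
  if (nrow(path) == 1L) return(0)
  steps <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  sum(steps)
}

#' Tube width from medial-axis radii
#'
#' Twice the median medial-axis radius over the longest-path pixels —
#' a thickness estimate for elongated tube-like components (vines) that is
#' unaffected by curvature. Not meaningful for round blobs.
#'
#' @param skel a [skeletonize_mask()] result.
#' @return Width in pixels.
#' @export
tube_width_px <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  if (length(skel$path_radius) == 0L)
    stop("empty skeleton path", call. = FALSE)
  2 * stats::median(skel$path_radius)
}

#' Default HSV ranges for the three peel-color categories
#'
#' Orange: hue 10-40 degrees with saturation and value at least 0.30.
#' Green: hue 60-170 with saturation at least 0.25 and value below 0.65.
#' Light green: hue 60-170 with low saturation (below 0.25) or high value
#' (at least 0.65). The three category regions are pairwise disjoint.
#' Each category is a list of HSV boxes `(h, s, v)` with lower-closed,
#' upper-open intervals (upper bounds equal to the channel maximum are
#' closed).
#'
#' @return Named list of categories `orange`, `green`, `light_green`.
#' @export
default_hsv_ranges <- function() {
  list(
    orange = list(list(h = c(10, 40), s = c(0.30, 1), v = c(0.30, 1))),
    green = list(list(h = c(60, 170), s = c(0.25, 1), v = c(0, 0.65))),
    light_green = list(
      list(h = c(60, 170), s = c(0, 0.25), v = c(0, 1)),
      list(h = c(60, 170), s = c(0.25, 1), v = c(0.65, 1)))
  )
}

# membership of HSV rows in one box; upper bound open unless at channel max
hsv_in_box <- function(hsv, box, h_max = 360, sv_max = 1) {
  inside <- function(vals, iv, vmax) {
    hi_ok <- if (iv[2] >= vmax) vals <= vmax else vals < iv[2]
    vals >= iv[1] & hi_ok
  }
  inside(hsv[, 1], box$h, h_max) &
    inside(hsv[, 2], box$s, sv_max) &
    inside(hsv[, 3], box$v, sv_max)
}

#' Classify fruit peel color by HSV pixel majority
#'
#' Converts the masked pixels to HSV, counts how many fall inside each
#' category's HSV region, and returns the category with the highest count.
#' Count ties are resolved by the priority orange > green > light_green.
#'
#' @param image numeric `H x W x 3` array in `[0, 1]`.
#' @param mask logical matrix selecting the fruit pixels.
#' @param ranges category HSV regions, see [default_hsv_ranges()].
#' @return Single character: `"OR"`, `"G"` or `"LG"`, with the per-category
#'   pixel counts attached as attribute `counts`. Errors with class
#'   `fpc_unclassified` (carrying the counts) when no pixel falls in any
#'   region.
#' @export
classify_fpc <- function(image, mask, ranges = default_hsv_ranges()) {
  validate_image(image)
  mask <- validate_mask(mask, image)
  idx <- which(mask)
  if (length(idx) == 0L)
    stop("degenerate mask: no foreground pixels", call. = FALSE)
  n <- length(idx)
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  hsv <- rgb_rows_to_hsv(rgb)
  counts <- vapply(ranges, function(boxes) {
    member <- rep(FALSE, n)
    for (b in boxes) member <- member | hsv_in_box(hsv, b)
    sum(member)
  }, numeric(1))
  if (all(counts == 0)) {
    cond <- structure(
      class = c("fpc_unclassified", "error", "condition"),
      list(message = "no masked pixel falls in any peel-color HSV range",
           call = sys.call(-1), counts = counts))
    stop(cond)
  }
  priority <- c("orange", "OR", "green", "G", "light_green", "LG")
  codes <- c(orange = "OR", green = "G", light_green = "LG")
  cats <- names(counts)
  best <- cats[counts == max(counts)]
  pick <- best[order(match(best, c("orange", "green", "light_green")))][1]
  out <- unname(codes[pick])
  if (is.na(out)) out <- pick
  attr(out, "counts") <- counts
  out
}

#' Measure one pumpkin component
#'
#' Length is the millimetre length of the longest medial-axis skeleton
#' path. Width for `role = "fruit"` uses the affine method (ellipse fit,
#' axis alignment, perpendicular extent); for `role = "vine"` the default
#' is the medial-radius tube width, because the farthest-point extent of a
#' curved vine measures its bend rather than its thickness. Both width
#' methods are available for both roles via `width_method`. Fruits are
#' additionally classified for peel color. Only the largest connected
#' component of the mask is measured.
#'
#' @param image numeric `H x W x 3` array (used for peel color).
#' @param mask logical component mask.
#' @param scale a `pixel_scale` from [compute_scale()].
#' @param role `"fruit"` or `"vine"`.
#' @param width_method `"affine"` or `"tube"`; default depends on role.
#' @param hsv_ranges peel-color ranges, see [default_hsv_ranges()].
#' @param step_model length step model, see [measure_length_px()].
#' @return List with `length_mm`, `width_mm`, `fpc` (fruit only, else
#'   `NA`), and `details` (ellipse, skeleton, pixel values).
#' @export
measure_component <- function(image, mask, scale,
                              role = c("fruit", "vine"),
                              width_method = NULL,
                              hsv_ranges = default_hsv_ranges(),
                              step_model = "pixel_count") {
  role <- match.arg(role)
  mask <- validate_mask(mask, image)
  stopifnot(inherits(scale, "pixel_scale"))
  if (!any(mask))
    stop("degenerate ", role, " mask: no foreground pixels", call. = FALSE)
  if (is.null(width_method))
    width_method <- if (role == "fruit") "affine" else "tube"
  width_method <- match.arg(width_method, c("affine", "tube"))
  mask <- largest_component(mask)
  skel <- skeletonize_mask(mask)
  length_px <- measure_length_px(skel, step_model = step_model)
  width_px <- if (width_method == "affine") {
    ell <- fit_ellipse(mask)
    measure_width_px(align_to_axes(mask, ell))
  } else {
    tube_width_px(skel)
  }
  fpc <- if (role == "fruit") {
    as.character(classify_fpc(image, mask, hsv_ranges))
  } else NA_character_
  list(length_mm = px_to_mm(length_px, scale),
       width_mm = px_to_mm(width_px, scale),
       fpc = fpc,
       details = list(length_px = length_px, width_px = width_px,
                      width_method = width_method,
                      n_skeleton_px = nrow(skel$pixels)))
}

#' Assemble the biophysical record of one sample
#'
#' Runs [measure_component()] on the fruit and vine masks and collects
#' fruit length/width/peel color and vine length/width into one record.
#' A missing component (NULL mask) leaves its fields `NA`.
#'
#' @param image numeric `H x W x 3` array.
#' @param fruit_mask,vine_mask logical masks or `NULL`.
#' @param scale a `pixel_scale`.
#' @param sample_id record label.
#' @param ... passed on to [measure_component()].
#' @return One-row data frame with columns `sample_id, FL_mm, FW_mm,
#'   VL_mm, VW_mm, FPC`.
#' @export
measure_sample <- function(image, fruit_mask, vine_mask, scale,
                           sample_id = "sample", ...) {
  rec <- data.frame(sample_id = sample_id, FL_mm = NA_real_, FW_mm = NA_real_,
                    VL_mm = NA_real_, VW_mm = NA_real_, FPC = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(fruit_mask)) {
    fr <- measure_component(image, fruit_mask, scale, role = "fruit", ...)
    rec$FL_mm <- fr$length_mm; rec$FW_mm <- fr$width_mm; rec$FPC <- fr$fpc
  }
  if (!is.null(vine_mask)) {
    vn <- measure_component(image, vine_mask, scale, role = "vine", ...)
    rec$VL_mm <- vn$length_mm; rec$VW_mm <- vn$width_mm
  }
  rec
}

# Largest 4-connected foreground component (smaller fragments ignored).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(mask)
  counts <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(counts)
}
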