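# Shared fixture builders; everything is generated in code at test time.

# uniform-color image
uniform_image <- function(H, W, color) {
  array(rep(color, each = H * W), c(H, W, 3))
}

# solid rectangle mask, 1-based row/col ranges
rect_mask <- function(H, W, rows, cols) {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

mask_iou_frac <- function(a, b) sum(a & b) / sum(a | b)

px_scale <- function(mm_per_px) {
  structure(list(mm_per_px = mm_per_px), class = "pixel_scale")
}

# 90-degree counter-clockwise rotations sharing one convention
rot90_mask <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90_image <- function(img) {
  out <- array(0, c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) out[, , ch] <- rot90_mask(img[, , ch])
  out
}

# tiny mask from linear indices on an H x W canvas
tiny_mask <- function(idx, H = 8, W = 8) {
  m <- matrix(FALSE, H, W)
  m[idx] <- TRUE
  m
}

# independent brute-force oracles -------------------------------------------

# width: max pairwise y-extent over all foreground pixel pairs
brute_force_width <- function(mask) {
  ys <- which(mask, arr.ind = TRUE)[, 1]
  best <- 0
  for (i in seq_along(ys)) best <- max(best, abs(ys - ys[i]) + 1)
  best
}

# average precision by direct enumeration of every top-k prediction set:
# precision/recall computed from scratch per k, then exact integration of
# the right-envelope interpolated precision over a fine recall grid
oracle_ap <- function(preds, gts, iou_threshold = 0.5) {
  if (length(preds) == 0L) return(0)
  scores <- vapply(preds, function(p) p$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  n_gt <- length(gts)
  prec <- numeric(length(ord)); rec <- numeric(length(ord))
  for (k in seq_along(ord)) {
    sub <- preds[ord[seq_len(k)]]
    used <- rep(FALSE, n_gt)
    tp <- 0
    for (p in sub) {
      ious <- vapply(seq_len(n_gt), function(j)
        if (used[j]) -1 else mask_iou(p$mask, gts[[j]]$mask), numeric(1))
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) { used[j] <- TRUE; tp <- tp + 1 }
    }
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  grid <- seq(0, 1, by = 1 / 4096)
  p_at <- vapply(grid, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  # exact area of the step function via unique recall breakpoints
  bp <- sort(unique(c(0, rec, 1)))
  area <- 0
  for (i in seq_len(length(bp) - 1)) {
    ok <- rec >= bp[i + 1] - 1e-12
    h <- if (any(ok)) max(prec[ok]) else 0
    area <- area + (bp[i + 1] - bp[i]) * h
  }
  area
}
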