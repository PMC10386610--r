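# COCO-style instance JSON: masks are written as uncompressed RLE
# (column-major counts, background first); the reader additionally
# accepts polygon segmentations, rasterized with an even-odd scanline
# rule at pixel centers over 0-based half-open pixel boxes.

mask_to_rle <- function(mask) {
  v <- as.integer(mask)                 # column-major flattening
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

rle_to_mask <- function(size, counts) {
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), times = counts)
  matrix(as.logical(v), size[1], size[2])
}

#' Rasterize a polygon to a mask
#'
#' Even-odd scanline fill: a pixel belongs to the polygon when its center
#' `(x + 0.5, y + 0.5)` (0-based pixel coordinates) lies inside.
#'
#' @param xy numeric `n x 2` matrix of polygon vertices `(x, y)`.
#' @param H,W output mask dimensions.
#' @return Logical `H x W` matrix.
#' @export
rasterize_polygon <- function(xy, H, W) {
  mask <- matrix(FALSE, H, W)
  n <- nrow(xy)
  xs <- xy[, 1]; ys <- xy[, 2]
  for (row in seq_len(H)) {
    yc <- row - 1 + 0.5
    x_cross <- numeric(0)
    for (e in seq_len(n)) {
      j <- if (e == n) 1L else e + 1L
      y1 <- ys[e]; y2 <- ys[j]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        x_cross <- c(x_cross, xs[e] + (yc - y1) / (y2 - y1) * (xs[j] - xs[e]))
      }
    }
    if (length(x_cross) < 2L) next
    x_cross <- sort(x_cross)
    for (k in seq(1L, length(x_cross) - 1L, by = 2L)) {
      lo <- x_cross[k]; hi <- x_cross[k + 1L]
      cols <- which((0:(W - 1)) + 0.5 >= lo & (0:(W - 1)) + 0.5 < hi)
      if (length(cols)) mask[row, cols] <- TRUE
    }
  }
  mask
}

#' Write component masks as COCO-style instance JSON
#'
#' One image, categories named after the (non-NULL) masks, one annotation
#' per mask with uncompressed RLE segmentation.
#'
#' @param masks named list of logical matrices (NULL entries skipped).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco_instances <- function(masks, path) {
  masks <- Filter(Negate(is.null), masks)
  if (length(masks) == 0L) stop("no masks to export", call. = FALSE)
  dims <- dim(masks[[1]])
  cats <- lapply(seq_along(masks), function(i)
    list(id = i, name = names(masks)[i]))
  anns <- lapply(seq_along(masks), function(i) {
    rle <- mask_to_rle(masks[[i]])
    list(id = i, image_id = 1L, category_id = i,
         segmentation = list(size = rle$size, counts = rle$counts),
         area = sum(masks[[i]]), iscrowd = 0L)
  })
  obj <- list(images = list(list(id = 1L, height = dims[1], width = dims[2],
                                 file_name = "image.png")),
              categories = cats, annotations = anns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read component masks from COCO-style instance JSON
#'
#' Accepts uncompressed RLE (`segmentation` with `size`/`counts`) or
#' polygon segmentations (list of flat `x1, y1, x2, y2, ...` rings; rings
#' are unioned). Returns one mask per category name; multiple annotations
#' of the same category are unioned.
#'
#' @param path JSON path.
#' @param H,W image dimensions, required when only polygons are present
#'   and no `images` entry carries them.
#' @return Named list of logical matrices keyed by category name.
#' @export
read_coco_masks <- function(path, H = NULL, W = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(H) && length(obj$images)) {
    H <- obj$images[[1]]$height
    W <- obj$images[[1]]$width
  }
  cat_names <- vapply(obj$categories, function(ct) as.character(ct$name),
                      character(1))
  names(cat_names) <- vapply(obj$categories, function(ct) as.character(ct$id),
                             character(1))
  out <- list()
  for (ann in obj$annotations) {
    seg <- ann$segmentation
    if (!is.null(seg$counts)) {
      size <- as.integer(unlist(seg$size))
      mask <- rle_to_mask(size, as.integer(unlist(seg$counts)))
    } else {
      if (is.null(H) || is.null(W))
        stop("image dimensions required to rasterize polygons", call. = FALSE)
      mask <- matrix(FALSE, H, W)
      for (ring in seg) {
        v <- as.numeric(unlist(ring))
        xy <- cbind(v[seq(1, length(v), by = 2)],
                    v[seq(2, length(v), by = 2)])
        mask <- mask | rasterize_polygon(xy, H, W)
      }
    }
    nm <- cat_names[[as.character(ann$category_id)]]
    out[[nm]] <- if (is.null(out[[nm]])) mask else out[[nm]] | mask
  }
  out
}
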