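# Pixel-grid primitives: boxes, masks, polygons, rasterization, cropping, IoU.
# Grid conventions are documented in ?berrybruise (utils.R).

#' Construct a bounding box
#'
#' Boxes are half-open integer pixel rectangles `[x0, x1) x [y0, y1)` in
#' 0-based coordinates, so `area = (x1 - x0) * (y1 - y0)`.
#'
#' @param x0,y0,x1,y1 integer pixel coordinates with `x0 < x1`, `y0 < y1`.
#' @return a named integer vector of class `bbox`.
#' @export
bbox <- function(x0, y0, x1, y1) {
  b <- c(x0 = as.integer(x0), y0 = as.integer(y0),
         x1 = as.integer(x1), y1 = as.integer(y1))
  if (anyNA(b)) stopf("bounding box coordinates must be finite integers")
  if (b["x0"] >= b["x1"] || b["y0"] >= b["y1"]) {
    stopf("invalid box: need x0 < x1 and y0 < y1, got (%d,%d,%d,%d)",
          b["x0"], b["y0"], b["x1"], b["y1"])
  }
  class(b) <- "bbox"
  b
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%d,%d) x [%d,%d), area %d px>\n",
              x["x0"], x["x1"], x["y0"], x["y1"], box_area(x)))
  invisible(x)
}

#' Area of a bounding box in pixels
#' @param box a `bbox`.
#' @return integer pixel count.
#' @export
box_area <- function(box) {
  as.integer((box[["x1"]] - box[["x0"]]) * (box[["y1"]] - box[["y0"]]))
}

#' Intersection-over-union of two bounding boxes
#'
#' Areas follow the half-open convention, so IoU of identical boxes is
#' exactly 1 and disjoint boxes give 0.
#'
#' @param a,b `bbox` objects.
#' @return overlap ratio in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0L, min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]]))
  iy <- max(0L, min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]]))
  inter <- as.double(ix) * as.double(iy)
  union <- as.double(box_area(a)) + as.double(box_area(b)) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices on the same pixel grid.
#' @return `|a & b| / |a | b|`; 0 when the union is empty.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stopf("mask dimensions differ: %dx%d vs %dx%d",
          nrow(a), ncol(a), nrow(b), ncol(b))
  }
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0L) return(0)
  inter / union
}

#' Tight bounding box of a nonempty mask
#' @param mask logical matrix.
#' @return a `bbox` covering exactly the member pixels.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("cannot take the bounding box of an empty mask")
  bbox(min(idx[, 2L]) - 1L, min(idx[, 1L]) - 1L, max(idx[, 2L]), max(idx[, 1L]))
}

#' Construct a polygon outline
#'
#' Vertices are normalized to \[0, 1\] relative to image width/height and the
#' outline is implicitly closed (last vertex connects to the first).
#'
#' @param vertices two-column numeric matrix of (x, y) normalized coordinates.
#' @param class_id integer class label (default 0).
#' @param confidence optional prediction confidence in \[0, 1\].
#' @return an object of class `polygon_outline`.
#' @export
polygon_outline <- function(vertices, class_id = 0L, confidence = NULL) {
  vertices <- matrix(as.double(vertices), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3L) {
    stopf("invalid annotation: a polygon needs at least 3 vertices, got %d",
          nrow(vertices))
  }
  if (anyNA(vertices) || any(vertices < -1e-6) || any(vertices > 1 + 1e-6)) {
    stopf("polygon vertices must be normalized coordinates in [0, 1]")
  }
  vertices[] <- pmin(pmax(vertices, 0), 1)
  structure(list(vertices = vertices, class_id = as.integer(class_id),
                 confidence = confidence),
            class = "polygon_outline")
}

#' Rasterize a normalized polygon onto a pixel grid
#'
#' A pixel is a member iff its center `(x + 0.5, y + 0.5)` lies inside the
#' polygon under the even-odd (ray crossing) rule. Denormalization multiplies
#' x by `width` and y by `height`. Points exactly on a horizontal-crossing
#' boundary follow the standard half-open crossing convention, which keeps
#' adjacent polygons non-overlapping.
#'
#' @param poly a `polygon_outline` (or a bare two-column vertex matrix).
#' @param width,height grid dimensions in pixels.
#' @return logical `height x width` mask.
#' @export
rasterize_polygon <- function(poly, width, height) {
  if (inherits(poly, "polygon_outline")) {
    v <- poly$vertices
  } else {
    v <- matrix(as.double(poly), ncol = 2L)
    if (nrow(v) < 3L) stopf("invalid annotation: fewer than 3 vertices")
  }
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stopf("grid dimensions must be >= 1")
  px <- v[, 1L] * width
  py <- v[, 2L] * height

  mask <- matrix(FALSE, nrow = height, ncol = width)
  # Restrict evaluation to the polygon's pixel-aligned bounding window.
  cx0 <- max(0L, floor(min(px)) - 1L); cx1 <- min(width - 1L, ceiling(max(px)))
  cy0 <- max(0L, floor(min(py)) - 1L); cy1 <- min(height - 1L, ceiling(max(py)))
  if (cx0 > cx1 || cy0 > cy1) return(mask)
  xs <- (cx0:cx1) + 0.5
  ys <- (cy0:cy1) + 0.5
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))

  inside <- rep(FALSE, length(gx))
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    # Edge (j -> i); half-open in y so each crossing counts once.
    crosses <- (py[i] > gy) != (py[j] > gy)
    if (any(crosses)) {
      xint <- px[i] + (gy[crosses] - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      hit <- gx[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  mask[cbind(gy[inside] + 0.5, gx[inside] + 0.5)] <- TRUE
  mask
}

#' Crop an image (or mask) to a padded bounding box
#'
#' The box is expanded by `pad` pixels on all sides and clipped to the image
#' bounds. The returned crop carries an `offset` attribute (0-based x, y of
#' its top-left corner on the parent grid) so masks computed on the crop can
#' be placed back on the plate grid exactly.
#'
#' @param img `h x w x 3` image array or `h x w` logical mask.
#' @param box a `bbox`; must intersect the image.
#' @param pad non-negative padding in pixels (default 4).
#' @return the cropped array with attributes `offset` and `parent_dim`.
#' @export
crop <- function(img, box, pad = 4L) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  x0 <- max(0L, box[["x0"]] - as.integer(pad))
  y0 <- max(0L, box[["y0"]] - as.integer(pad))
  x1 <- min(w, box[["x1"]] + as.integer(pad))
  y1 <- min(h, box[["y1"]] + as.integer(pad))
  if (box[["x0"]] >= w || box[["y0"]] >= h || box[["x1"]] <= 0L ||
      box[["y1"]] <= 0L) {
    stopf("crop box lies fully outside the %dx%d image", w, h)
  }
  out <- if (length(d) == 3L) {
    img[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  } else {
    img[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  }
  attr(out, "offset") <- c(x = x0, y = y0)
  attr(out, "parent_dim") <- c(h = h, w = w)
  out
}

#' Place a crop-grid mask back onto its parent grid
#'
#' Inverse of [crop()] for masks: uses the crop's `offset` and `parent_dim`
#' attributes (or explicit arguments) to embed the mask in a full-size frame.
#'
#' @param mask logical matrix on the crop grid.
#' @param offset 0-based (x, y) of the crop's top-left corner; defaults to the
#'   mask's `offset` attribute.
#' @param parent_dim (h, w) of the parent grid; defaults to the mask's
#'   `parent_dim` attribute.
#' @return logical matrix on the parent grid.
#' @export
uncrop_mask <- function(mask, offset = attr(mask, "offset"),
                        parent_dim = attr(mask, "parent_dim")) {
  if (is.null(offset) || is.null(parent_dim)) {
    stopf("uncrop_mask needs the crop offset and parent dimensions")
  }
  out <- matrix(FALSE, nrow = parent_dim[[1L]], ncol = parent_dim[[2L]])
  out[(offset[[2L]] + 1L):(offset[[2L]] + nrow(mask)),
      (offset[[1L]] + 1L):(offset[[1L]] + ncol(mask))] <- mask
  out
}

#' Read an RGB image from a PNG or JPEG file
#' @param path file path.
#' @return `h x w x 3` numeric array in \[0, 255\].
#' @export
read_image <- function(path) {
  ei <- EBImage::readImage(path)
  a <- EBImage::imageData(ei)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  out <- aperm(a, c(2L, 1L, 3L)) * 255
  round(out)
}

#' Write an RGB image to a PNG or JPEG file
#' @param img `h x w x 3` array in \[0, 255\].
#' @param path destination; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  a <- aperm(pmin(pmax(img, 0), 255) / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as a single-channel 0/255 PNG
#' @param mask logical matrix.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}

#' Read a 0/255 single-channel PNG back into a logical mask
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  t(a) > 0.5
}
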