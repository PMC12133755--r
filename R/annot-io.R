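# YOLO-dialect label files: one record per line, class id first, then
# normalized coordinates; predictions carry a trailing confidence.

#' Construct an annotation set
#'
#' @param image_id image name (file stem).
#' @param boxes data frame with columns `class_id, cx, cy, w, h` (normalized
#'   center-size records) and, for predictions, `confidence`.
#' @param polygons list of [polygon_outline()] objects.
#' @param source `"ground-truth"` or `"prediction"`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, boxes = empty_boxes(), polygons = list(),
                           source = c("ground-truth", "prediction")) {
  source <- match.arg(source)
  if (nrow(boxes) > 0) {
    vals <- unlist(boxes[c("cx", "cy", "w", "h")])
    if (any(vals < -1e-6) || any(vals > 1 + 1e-6)) {
      stopf("box coordinates must be normalized to [0, 1]")
    }
    if (source == "prediction" && is.null(boxes$confidence)) {
      stopf("prediction records must carry a confidence")
    }
  }
  structure(list(image_id = image_id, boxes = boxes, polygons = polygons,
                 source = source),
            class = "annotation_set")
}

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = double(), cy = double(),
             w = double(), h = double(), confidence = double())
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s' (%s): %d boxes, %d polygons>\n",
              x$image_id, x$source, nrow(x$boxes), length(x$polygons)))
  invisible(x)
}

parse_numeric_fields <- function(line, lineno) {
  fields <- strsplit(trimws(line), "[ \t]+")[[1L]]
  vals <- suppressWarnings(as.numeric(fields))
  if (anyNA(vals)) {
    stopf("parse error, line %d: non-numeric field '%s'",
          lineno, fields[which(is.na(vals))[1L]])
  }
  vals
}

check_unit_interval <- function(vals, lineno, what) {
  if (any(vals < -1e-6) || any(vals > 1 + 1e-6)) {
    stopf("parse error, line %d: %s outside [0, 1]", lineno, what)
  }
  pmin(pmax(vals, 0), 1)
}

#' Read a YOLO-dialect label file
#'
#' Box lines hold 5 numbers (`class cx cy w h`), or 6 with a trailing
#' confidence for predictions. Polygon lines hold a class id followed by an
#' even number (>= 6) of normalized coordinates, plus an optional trailing
#' confidence. Malformed lines raise an error naming the line number.
#'
#' @param path label file path.
#' @param kind `"box"` or `"polygon"`.
#' @param image_id image name; defaults to the file stem.
#' @return an [annotation_set()]; `source` is `"prediction"` iff any record
#'   carries a confidence.
#' @export
read_labels <- function(path, kind = c("box", "polygon"),
                        image_id = sub("\\.[^.]*$", "", basename(path))) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("label file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  has_conf <- FALSE
  boxes <- empty_boxes()
  polys <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    vals <- parse_numeric_fields(lines[i], i)
    cls <- vals[1L]
    if (cls != round(cls) || cls < 0) {
      stopf("parse error, line %d: class id must be a non-negative integer", i)
    }
    rest <- vals[-1L]
    if (kind == "box") {
      if (!(length(rest) %in% c(4L, 5L))) {
        stopf("parse error, line %d: box record needs 4 coordinates (optionally a confidence), got %d fields",
              i, length(rest))
      }
      conf <- if (length(rest) == 5L) rest[5L] else NA_real_
      coords <- check_unit_interval(rest[1:4], i, "box coordinates")
      if (!is.na(conf)) {
        conf <- check_unit_interval(conf, i, "confidence")
        has_conf <- TRUE
      }
      boxes <- rbind(boxes, data.frame(class_id = as.integer(cls),
                                       cx = coords[1L], cy = coords[2L],
                                       w = coords[3L], h = coords[4L],
                                       confidence = conf))
    } else {
      conf <- NA_real_
      if (length(rest) %% 2L == 1L) {  # trailing confidence
        conf <- check_unit_interval(rest[length(rest)], i, "confidence")
        rest <- rest[-length(rest)]
        has_conf <- TRUE
      }
      if (length(rest) < 6L) {
        stopf("parse error, line %d: polygon record needs >= 3 vertices, got %d coordinates",
              i, length(rest))
      }
      coords <- check_unit_interval(rest, i, "polygon coordinates")
      v <- matrix(coords, ncol = 2L, byrow = TRUE)
      polys[[length(polys) + 1L]] <-
        polygon_outline(v, class_id = cls,
                        confidence = if (is.na(conf)) NULL else conf)
    }
  }
  annotation_set(image_id, boxes, polys,
                 source = if (has_conf) "prediction" else "ground-truth")
}

#' Write an annotation set as a YOLO-dialect label file
#'
#' Coordinates are written with 6 decimals in stable record order, so
#' `read_labels(write_labels(s))` recovers `s` to 1e-6.
#'
#' @param set an [annotation_set()].
#' @param path destination file.
#' @param kind write the box records (`"box"`) or the polygon records
#'   (`"polygon"`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(set, path, kind = c("box", "polygon")) {
  kind <- match.arg(kind)
  fmt <- function(x) sprintf("%.6f", x)
  lines <- character()
  if (kind == "box" && nrow(set$boxes) > 0) {
    for (i in seq_len(nrow(set$boxes))) {
      b <- set$boxes[i, ]
      rec <- paste(b$class_id, fmt(b$cx), fmt(b$cy), fmt(b$w), fmt(b$h))
      if (!is.na(b$confidence %||% NA)) rec <- paste(rec, fmt(b$confidence))
      lines <- c(lines, rec)
    }
  }
  if (kind == "polygon") {
    for (p in set$polygons) {
      rec <- paste(p$class_id,
                   paste(fmt(t(p$vertices)), collapse = " "))
      if (!is.null(p$confidence)) rec <- paste(rec, fmt(p$confidence))
      lines <- c(lines, rec)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Deterministically split image ids into train/validation/test
#'
#' Partition sizes are `floor(n * ratio)` for validation and test with the
#' remainder assigned to train, matching the convention in which 185 images
#' at 8:1:1 yield 149/18/18. Shuffling is driven only by `seed`.
#'
#' @param image_ids character vector of image names (>= 3).
#' @param ratio train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return a list of class `split_plan` with `train`, `validation`, `test`,
#'   `ratio`, `seed`.
#' @export
split_dataset <- function(image_ids, ratio = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(image_ids)
  if (n < 3L) stopf("need at least 3 images to split, got %d", n)
  if (abs(sum(ratio) - 1) > 1e-9) stopf("split ratios must sum to 1")
  if (anyDuplicated(image_ids)) stopf("image ids must be unique")
  shuffled <- with_seed(seed, sample(image_ids))
  n_val <- floor(n * ratio[2L])
  n_test <- floor(n * ratio[3L])
  n_train <- n - n_val - n_test
  structure(list(train = shuffled[seq_len(n_train)],
                 validation = shuffled[n_train + seq_len(n_val)],
                 test = shuffled[n_train + n_val + seq_len(n_test)],
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %d/%d/%d (train/validation/test), seed %d>\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Write a split plan as JSON
#' @param plan a `split_plan`.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# ---- augmentation -----------------------------------------------------------

AUGMENT_OPS <- c("hflip", "vflip", "rotate", "saturation", "brightness",
                 "exposure")

transform_points <- function(xy, op, angle, w, h) {
  switch(op,
    hflip = cbind(1 - xy[, 1L], xy[, 2L]),
    vflip = cbind(xy[, 1L], 1 - xy[, 2L]),
    rotate = {
      # rotate in pixel space about the image center (aspect-correct)
      px <- xy[, 1L] * w - w / 2
      py <- xy[, 2L] * h - h / 2
      th <- angle * pi / 180
      rx <- px * cos(th) - py * sin(th)
      ry <- px * sin(th) + py * cos(th)
      cbind(pmin(pmax((rx + w / 2) / w, 0), 1),
            pmin(pmax((ry + h / 2) / h, 0), 1))
    },
    xy
  )
}

box_corners <- function(b) {
  x0 <- b$cx - b$w / 2; x1 <- b$cx + b$w / 2
  y0 <- b$cy - b$h / 2; y1 <- b$cy + b$h / 2
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

hull_to_box <- function(xy, row) {
  row$cx <- (min(xy[, 1L]) + max(xy[, 1L])) / 2
  row$cy <- (min(xy[, 2L]) + max(xy[, 2L])) / 2
  row$w <- max(xy[, 1L]) - min(xy[, 1L])
  row$h <- max(xy[, 2L]) - min(xy[, 2L])
  row
}

rotate_image_nn <- function(img, angle, bg) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  th <- -angle * pi / 180  # inverse map
  xs <- rep(seq_len(w) - 0.5 - w / 2, each = h)
  ys <- rep(seq_len(h) - 0.5 - h / 2, times = w)
  sx <- xs * cos(th) - ys * sin(th) + w / 2
  sy <- xs * sin(th) + ys * cos(th) + h / 2
  ci <- ceiling(sx); ri <- ceiling(sy)
  ok <- ci >= 1L & ci <= w & ri >= 1L & ri <= h
  out <- array(0, dim = dim(img))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], nrow = h, ncol = w)
    src <- img[, , ch]
    plane[ok] <- src[cbind(ri[ok], ci[ok])]
    out[, , ch] <- plane
  }
  out
}

apply_photometric <- function(img, op, scale) {
  x <- img / 255
  x <- switch(op,
    saturation = {
      gray <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
      g3 <- array(rep(gray, 3L), dim = dim(x))
      g3 + (x - g3) * scale
    },
    brightness = x * scale,
    exposure = x^(1 / scale),
    x
  )
  pmin(pmax(x, 0), 1) * 255
}

apply_geometric_image <- function(img, op, angle, bg) {
  switch(op,
    hflip = img[, rev(seq_len(dim(img)[2L])), , drop = FALSE],
    vflip = img[rev(seq_len(dim(img)[1L])), , , drop = FALSE],
    rotate = {
      if (abs(angle %% 90) < 1e-9) {
        k <- as.integer(round(angle / 90)) %% 4L
        out <- img
        for (i in seq_len(k)) {
          # 90 deg clockwise-on-screen rotation (y axis points down)
          out <- aperm(out, c(2L, 1L, 3L))[, rev(seq_len(dim(out)[1L])), ,
                                           drop = FALSE]
        }
        out
      } else {
        rotate_image_nn(img, angle, bg)
      }
    },
    img
  )
}

transform_annotations <- function(set, op, angle, w, h) {
  polys <- lapply(set$polygons, function(p) {
    p$vertices <- transform_points(p$vertices, op, angle, w, h)
    p
  })
  boxes <- set$boxes
  paired <- nrow(boxes) > 0 && length(polys) == nrow(boxes)
  if (nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      corners <- if (paired) polys[[i]]$vertices else
        transform_points(box_corners(boxes[i, ]), op, angle, w, h)
      boxes[i, ] <- hull_to_box(corners, boxes[i, ])
    }
  }
  annotation_set(set$image_id, boxes, polys, source = set$source)
}

#' Annotation-preserving augmentation
#'
#' Produces `n_copies` augmented (image, annotation) pairs. Each copy applies
#' every requested op with a parameter drawn from the seeded stream: flips
#' with probability 1/2, rotation angles uniform in \[-180, 180) degrees, and
#' photometric scales uniform in \[0.7, 1.3\]. Geometric ops transform polygon
#' vertices exactly and rebuild boxes as axis-aligned hulls; photometric ops
#' leave annotations unchanged. Rotation keeps the canvas size and fills
#' exposed pixels with `background`.
#'
#' @param img `h x w x 3` image array.
#' @param set the image's [annotation_set()].
#' @param ops character vector drawn from `hflip, vflip, rotate, saturation,
#'   brightness, exposure`.
#' @param n_copies number of augmented copies (default 3).
#' @param seed integer seed.
#' @param background RGB fill color for pixels exposed by rotation.
#' @return list of `n_copies` elements, each `list(image, set)`; copy ids are
#'   appended to the image id.
#' @export
augment <- function(img, set, ops = c("hflip", "vflip", "rotate"),
                    n_copies = 3L, seed = 1L,
                    background = c(245, 245, 240)) {
  bad <- setdiff(ops, AUGMENT_OPS)
  if (length(bad) > 0) {
    stopf("unknown augmentation op(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(AUGMENT_OPS, collapse = ", "))
  }
  h <- dim(img)[1L]; w <- dim(img)[2L]
  with_seed(seed, {
    lapply(seq_len(n_copies), function(k) {
      out_img <- img
      out_set <- set
      for (op in ops) {
        if (op %in% c("hflip", "vflip")) {
          if (stats::runif(1) < 0.5) {
            out_img <- apply_geometric_image(out_img, op, 0, background)
            out_set <- transform_annotations(out_set, op, 0, w, h)
          }
        } else if (op == "rotate") {
          angle <- stats::runif(1, -180, 180)
          out_img <- apply_geometric_image(out_img, op, angle, background)
          out_set <- transform_annotations(out_set, op, angle, w, h)
        } else {
          scale <- stats::runif(1, 0.7, 1.3)
          out_img <- apply_photometric(out_img, op, scale)
        }
      }
      out_set$image_id <- sprintf("%s_aug%d", set$image_id, k)
      list(image = out_img, set = out_set)
    })
  })
}

#' Apply one named augmentation op with an explicit parameter
#'
#' Deterministic single-op variant of [augment()] used for exact-area tests
#' and custom pipelines: flips take no parameter, `rotate` takes an angle in
#' degrees, photometric ops a scale factor.
#'
#' @inheritParams augment
#' @param op one op name.
#' @param param rotation angle (degrees) or photometric scale.
#' @return `list(image, set)`.
#' @export
augment_one <- function(img, set, op, param = NULL,
                        background = c(245, 245, 240)) {
  if (!op %in% AUGMENT_OPS) stopf("unknown augmentation op: %s", op)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (op %in% c("hflip", "vflip", "rotate")) {
    angle <- param %||% 0
    list(image = apply_geometric_image(img, op, angle, background),
         set = transform_annotations(set, op, angle, w, h))
  } else {
    list(image = apply_photometric(img, op, param %||% 1), set = set)
  }
}
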