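# The three-stage pipeline: detect each berry on the plate, segment its
# cross-section on a padded crop, segment the bruise inside it, and compute
# the bruising ratio. Detection and segmentation engines are pluggable
# backends behind one contract, so trained-model predictions (file backend)
# and the classical image-processing reference backend are interchangeable.

#' Construct a pipeline backend
#'
#' A backend is a named predictor bound to one of the three cascade roles.
#' Detection backends receive the full plate image and return
#' `list(boxes = list of bbox, confidences = numeric)`. Segmentation
#' backends receive a padded crop (carrying its `offset` attribute) plus a
#' context list and return a logical mask on the crop grid (berry), or a
#' mask given the berry mask as well (bruise). Backends never mutate their
#' inputs.
#'
#' @param name backend name (recorded in results).
#' @param task `"detect"`, `"segment-berry"` or `"segment-bruise"`.
#' @param predict the prediction function.
#' @return an object of class `bb_backend`.
#' @export
backend <- function(name, task = c("detect", "segment-berry",
                                   "segment-bruise"), predict) {
  task <- match.arg(task)
  structure(list(name = name, task = task, predict = predict),
            class = "bb_backend")
}

#' @export
print.bb_backend <- function(x, ...) {
  cat(sprintf("<backend '%s' (%s)>\n", x$name, x$task))
  invisible(x)
}

to_gray_ebi <- function(img) {
  g <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3 / 255
  EBImage::Image(t(g))
}

#' Classical berry detector
#'
#' Reference detection backend for plates of dark berries on a light
#' background: Otsu-thresholds the grayscale image (berries are the dark
#' class), applies morphological opening then closing with a disc of radius
#' `r_morph`, labels connected components, and keeps components with area in
#' `[area_min, area_max]`. Each surviving component yields its tight box
#' with confidence `min(1, area / (2 * area_min))`.
#'
#' @param r_morph disc radius in pixels for opening/closing.
#' @param area_min,area_max component area bounds in pixels.
#' @return a detection [backend()].
#' @export
classical_detector <- function(r_morph = 1L, area_min = 400,
                               area_max = 1e5) {
  brush <- EBImage::makeBrush(2L * r_morph + 1L, shape = "disc")
  backend("classical", "detect", function(img, context = list()) {
    g <- to_gray_ebi(img)
    thr <- EBImage::otsu(g)
    fg <- g < thr  # berries darker than background
    # the pale flesh can sit above the threshold, leaving each berry as a
    # thin dark skin ring: fill holes first so the ring becomes a solid
    # component that survives the morphological cleaning
    fg <- EBImage::fillHull(fg)
    fg <- EBImage::closing(EBImage::opening(fg, brush), brush)
    lab <- EBImage::bwlabel(fg)
    m <- t(EBImage::imageData(lab))  # back to row/col = y/x
    n <- max(m)
    boxes <- list(); confs <- double()
    if (n > 0) {
      for (i in seq_len(n)) {
        comp <- m == i
        area <- sum(comp)
        if (area < area_min || area > area_max) next
        boxes[[length(boxes) + 1L]] <- mask_bbox(comp)
        confs <- c(confs, min(1, area / (2 * area_min)))
      }
    }
    list(boxes = boxes, confidences = confs)
  })
}

#' Classical berry cross-section segmenter
#'
#' Reference segmentation backend for a single-berry crop: estimates the
#' background color as the median of the crop's border pixels, computes each
#' pixel's Euclidean color distance to it, Otsu-thresholds the distance map,
#' cleans it with a small opening, keeps the largest connected component and
#' fills its holes (the pale flesh interior is recovered even where its
#' color is near the background, because the dark skin annulus encloses it).
#'
#' @param r_clean disc radius for the cleaning opening.
#' @return a segment-berry [backend()]; raises a segmentation-failure error
#'   when no foreground survives.
#' @export
classical_berry_segmenter <- function(r_clean = 1L) {
  brush <- EBImage::makeBrush(2L * r_clean + 1L, shape = "disc")
  backend("classical", "segment-berry", function(crop_img, context = list()) {
    h <- dim(crop_img)[1L]; w <- dim(crop_img)[2L]
    bg <- vapply(1:3, function(ch) {
      p <- crop_img[, , ch]
      stats::median(c(p[1L, ], p[h, ], p[, 1L], p[, w]))
    }, 0)
    d2 <- (crop_img[, , 1L] - bg[1L])^2 + (crop_img[, , 2L] - bg[2L])^2 +
      (crop_img[, , 3L] - bg[3L])^2
    dist <- sqrt(d2) / 442  # normalize by max possible RGB distance
    thr <- EBImage::otsu(EBImage::Image(t(dist)))
    fg <- dist > thr
    # the threshold may keep only the dark skin ring (pale flesh can sit
    # near the background color): fill holes before cleaning so the berry
    # is one solid component
    filled <- EBImage::fillHull(EBImage::Image(t(fg) * 1))
    fg_e <- EBImage::opening(filled, brush)
    lab <- EBImage::bwlabel(fg_e)
    m <- t(EBImage::imageData(lab))
    if (max(m) == 0) stopf("segmentation failure: no foreground in crop")
    sizes <- tabulate(m[m > 0])
    comp <- m == which.max(sizes)
    mask <- comp
    if (!any(mask)) stopf("segmentation failure: empty mask")
    attr(mask, "offset") <- attr(crop_img, "offset")
    attr(mask, "parent_dim") <- attr(crop_img, "parent_dim")
    mask
  })
}

otsu_on_values <- function(vals) {
  # Otsu threshold of a numeric vector in [0, 1] via a 256-bin histogram.
  EBImage::otsu(EBImage::Image(matrix(pmin(pmax(vals, 0), 1), ncol = 1L)))
}

#' Classical bruise segmenter
#'
#' Reference bruise backend: within the berry mask eroded by the estimated
#' skin thickness (`skin_frac` of the equivalent radius), scores flesh
#' pixels by a redness index `(R - G)` (the reddish-brown bruise against
#' pale green-ish flesh), Otsu-splits the index restricted to those pixels,
#' keeps the red class only if its mean redness exceeds `min_redness`
#' (otherwise the berry is called unbruised), removes components smaller
#' than `min_area`, and clips to the berry mask. An empty mask is the valid
#' "no bruise" outcome.
#'
#' @param skin_frac skin thickness as a fraction of the equivalent radius.
#' @param min_redness minimum mean normalized redness of the bruise class.
#' @param min_area minimum bruise component area in pixels.
#' @return a segment-bruise [backend()].
#' @export
classical_bruise_segmenter <- function(skin_frac = 0.12, min_redness = 0.15,
                                       min_area = 30L) {
  backend("classical", "segment-bruise",
          function(crop_img, berry_mask, context = list()) {
    area <- sum(berry_mask)
    if (area == 0L) return(berry_mask)
    r_eq <- sqrt(area / pi)
    r_er <- max(1L, round(skin_frac * r_eq))
    brush <- EBImage::makeBrush(2L * r_er + 1L, shape = "disc")
    flesh <- t(EBImage::imageData(
      EBImage::erode(EBImage::Image(t(berry_mask) * 1), brush))) > 0.5
    if (!any(flesh)) return(berry_mask & FALSE)
    redness <- (crop_img[, , 1L] - crop_img[, , 2L]) / 255  # in [-1, 1]
    idx <- (redness + 1) / 2
    vals <- idx[flesh]
    thr <- otsu_on_values(vals)
    cand <- flesh & idx > thr
    if (!any(cand)) return(berry_mask & FALSE)
    if (mean(redness[cand]) < min_redness) return(berry_mask & FALSE)
    # fully discolored flesh: when the Otsu "pale" class is itself red, the
    # split is within the bruise and the whole flesh is bruised
    low <- flesh & !cand
    if (any(low) && mean(redness[low]) >= min_redness) cand <- flesh
    lab <- EBImage::bwlabel(EBImage::Image(t(cand) * 1))
    m <- t(EBImage::imageData(lab))
    sizes <- tabulate(m[m > 0])
    keep <- which(sizes >= min_area)
    out <- matrix(m %in% keep, nrow = nrow(m)) & berry_mask
    attr(out, "offset") <- attr(berry_mask, "offset")
    attr(out, "parent_dim") <- attr(berry_mask, "parent_dim")
    out
  })
}

#' File-based backends from prediction label files
#'
#' Wraps a directory of YOLO-dialect prediction files (or ground-truth
#' files) as the three cascade backends, so externally produced model
#' output can drive the pipeline without any learning-framework dependency.
#' Detection uses `<id>_boxes.txt`; berry and bruise segmentation rasterize
#' `<id>_berry.txt` / `<id>_bruise.txt` polygons on the plate grid and, for
#' a given crop, return the stored object overlapping that crop window
#' most. A missing file yields an empty prediction with a warning.
#'
#' @param dir directory of label files as written by [export_annotations()].
#' @return list with backends `detector`, `berry`, `bruise`.
#' @export
file_backend <- function(dir) {
  cache <- new.env(parent = emptyenv())
  load_masks <- function(image_id, which, dim_hw) {
    key <- paste(image_id, which, sep = "/")
    if (!is.null(cache[[key]])) return(cache[[key]])
    path <- file.path(dir, sprintf("%s_%s.txt", image_id, which))
    if (!file.exists(path)) {
      warning(sprintf("no prediction file for image '%s' (%s)", image_id,
                      which), call. = FALSE)
      masks <- list()
    } else {
      set <- read_labels(path, kind = "polygon")
      masks <- lapply(set$polygons, function(p) {
        list(mask = rasterize_polygon(p, dim_hw[2L], dim_hw[1L]),
             confidence = p$confidence %||% 1)
      })
    }
    cache[[key]] <- masks
    masks
  }
  pick_for_crop <- function(masks, crop_dims, offset) {
    if (length(masks) == 0L) return(NULL)
    rows <- offset[["y"]] + seq_len(crop_dims[1L])
    cols <- offset[["x"]] + seq_len(crop_dims[2L])
    ov <- vapply(masks, function(m) sum(m$mask[rows, cols]), 0)
    if (max(ov) == 0) return(NULL)
    best <- masks[[which.max(ov)]]
    list(mask = best$mask[rows, cols], confidence = best$confidence)
  }
  detector <- backend("files", "detect", function(img, context = list()) {
    id <- context$image_id %||% stopf("file backend needs an image_id")
    path <- file.path(dir, sprintf("%s_boxes.txt", id))
    if (!file.exists(path)) {
      warning(sprintf("no prediction file for image '%s' (boxes)", id),
              call. = FALSE)
      return(list(boxes = list(), confidences = double()))
    }
    set <- read_labels(path, kind = "box")
    h <- dim(img)[1L]; w <- dim(img)[2L]
    boxes <- list(); confs <- double()
    if (nrow(set$boxes) > 0) {
      for (i in seq_len(nrow(set$boxes))) {
        boxes[[i]] <- norm_box_to_bbox(set$boxes[i, ], w, h)
      }
      confs <- ifelse(is.na(set$boxes$confidence), 1, set$boxes$confidence)
    }
    list(boxes = boxes, confidences = confs)
  })
  seg_fn <- function(which) {
    function(crop_img, berry_mask, context = list()) {
      id <- context$image_id %||% stopf("file backend needs an image_id")
      offset <- attr(crop_img, "offset")
      parent <- attr(crop_img, "parent_dim")
      masks <- load_masks(id, which, parent)
      hit <- pick_for_crop(masks, dim(crop_img)[1:2], offset)
      out <- if (is.null(hit)) {
        if (which == "berry") stopf("segmentation failure: no stored mask overlaps the crop")
        matrix(FALSE, dim(crop_img)[1L], dim(crop_img)[2L])
      } else hit$mask
      attr(out, "offset") <- offset
      attr(out, "parent_dim") <- parent
      out
    }
  }
  berry_fn <- seg_fn("berry")
  bruise_fn <- seg_fn("bruise")
  list(detector = detector,
       berry = backend("files", "segment-berry",
                       function(crop_img, context = list())
                         berry_fn(crop_img, NULL, context)),
       bruise = backend("files", "segment-bruise", bruise_fn))
}

#' Ground-truth backends from generated plates
#'
#' Injects a plate's exact ground truth as the three backends (the identity
#' path): detection returns the true boxes at confidence 1 and the
#' segmenters return the true masks cropped to the window.
#'
#' @param plate a [generate_plate()] result.
#' @return list with backends `detector`, `berry`, `bruise`.
#' @export
truth_backend <- function(plate) {
  pick <- function(field, crop_img) {
    offset <- attr(crop_img, "offset")
    rows <- offset[["y"]] + seq_len(dim(crop_img)[1L])
    cols <- offset[["x"]] + seq_len(dim(crop_img)[2L])
    ov <- vapply(plate$berries,
                 function(b) sum(b$berry_mask[rows, cols]), 0)
    if (max(ov) == 0) stopf("segmentation failure: no ground-truth berry in crop")
    m <- plate$berries[[which.max(ov)]][[field]][rows, cols]
    attr(m, "offset") <- offset
    attr(m, "parent_dim") <- attr(crop_img, "parent_dim")
    m
  }
  list(
    detector = backend("truth", "detect", function(img, context = list()) {
      list(boxes = lapply(plate$berries, `[[`, "box"),
           confidences = rep(1, length(plate$berries)))
    }),
    berry = backend("truth", "segment-berry",
                    function(crop_img, context = list())
                      pick("berry_mask", crop_img)),
    bruise = backend("truth", "segment-bruise",
                     function(crop_img, berry_mask, context = list())
                       pick("bruise_mask", crop_img))
  )
}

#' Run the three-stage cascade on one plate image
#'
#' For each detection at or above the confidence threshold: crop the plate
#' with padding, segment the berry cross-section, segment the bruise, clip
#' the bruise to the berry mask, map both masks back to plate coordinates,
#' and compute `ratio = bruise pixels / berry pixels`. Berries whose
#' segmentation fails are recorded with a null ratio and excluded from
#' aggregates. Indices follow reading order (row-major by box top-left).
#'
#' @param img `h x w x 3` plate image.
#' @param detector,berry_segmenter,bruise_segmenter [backend()]s with the
#'   matching tasks.
#' @param conf_threshold minimum detection confidence (default 0.25).
#' @param pad crop padding in pixels (default 4).
#' @param image_id image name recorded in the result.
#' @return an object of class `plate_result`.
#' @export
run_plate <- function(img, detector, berry_segmenter, bruise_segmenter,
                      conf_threshold = 0.25, pad = 4L,
                      image_id = "plate") {
  if (detector$task != "detect" || berry_segmenter$task != "segment-berry" ||
      bruise_segmenter$task != "segment-bruise") {
    stopf("backend task mismatch: need detect / segment-berry / segment-bruise, got %s / %s / %s",
          detector$task, berry_segmenter$task, bruise_segmenter$task)
  }
  context <- list(image_id = image_id)
  det <- detector$predict(img, context)
  keep <- which(det$confidences >= conf_threshold)
  boxes <- det$boxes[keep]
  confs <- det$confidences[keep]
  if (length(boxes) > 0) {
    ord <- order(vapply(boxes, function(b) b[["y0"]], 0L),
                 vapply(boxes, function(b) b[["x0"]], 0L))
    boxes <- boxes[ord]; confs <- confs[ord]
  }
  berries <- vector("list", length(boxes))
  failures <- character()
  for (i in seq_along(boxes)) {
    cr <- crop(img, boxes[[i]], pad = pad)
    rec <- list(index = i, box = boxes[[i]], confidence = confs[i],
                berry_mask = NULL, bruise_mask = NULL, ratio = NA_real_)
    res <- tryCatch({
      bmask <- berry_segmenter$predict(cr, context)
      rmask <- bruise_segmenter$predict(cr, bmask, context)
      rmask <- rmask & bmask  # clip overhanging bruise predictions
      rec$berry_mask <- uncrop_mask(bmask, attr(cr, "offset"),
                                    attr(cr, "parent_dim"))
      rec$bruise_mask <- uncrop_mask(rmask, attr(cr, "offset"),
                                     attr(cr, "parent_dim"))
      rec$ratio <- sum(rmask & bmask) / sum(bmask)
      rec
    }, error = function(e) {
      failures <<- c(failures, sprintf("berry %d: %s", i, conditionMessage(e)))
      rec
    })
    berries[[i]] <- res
  }
  structure(list(image_id = image_id, berries = berries,
                 backends = c(detector = detector$name,
                              berry = berry_segmenter$name,
                              bruise = bruise_segmenter$name),
                 conf_threshold = conf_threshold, pad = as.integer(pad),
                 failures = failures),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  ratios <- vapply(x$berries, `[[`, 0, "ratio")
  cat(sprintf("<plate_result '%s': %d berries (%d failed), mean ratio %.3f>\n",
              x$image_id, length(x$berries), sum(is.na(ratios)),
              mean(ratios, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.plate_result <- function(x, ...) {
  if (length(x$berries) == 0L) {
    return(data.frame(image_id = character(), berry_index = integer(),
                      x0 = integer(), y0 = integer(), x1 = integer(),
                      y1 = integer(), berry_area_px = integer(),
                      bruise_area_px = integer(), ratio = double()))
  }
  do.call(rbind, lapply(x$berries, function(b) {
    data.frame(image_id = x$image_id, berry_index = b$index,
               x0 = b$box[["x0"]], y0 = b$box[["y0"]],
               x1 = b$box[["x1"]], y1 = b$box[["y1"]],
               berry_area_px = if (is.null(b$berry_mask)) NA_integer_ else
                 sum(b$berry_mask),
               bruise_area_px = if (is.null(b$bruise_mask)) NA_integer_ else
                 sum(b$bruise_mask),
               ratio = b$ratio)
  }))
}

#' Summary of a plate result
#' @param object a `plate_result`.
#' @param ... unused.
#' @export
summary.plate_result <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Plate '%s': %d berries, %d segmentation failures\n",
              object$image_id, nrow(df), length(object$failures)))
  if (nrow(df) > 0) {
    cat(sprintf("  ratio: mean %.3f, range [%.3f, %.3f]\n",
                mean(df$ratio, na.rm = TRUE), min(df$ratio, na.rm = TRUE),
                max(df$ratio, na.rm = TRUE)))
  }
  invisible(df)
}
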