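# Synthetic plate images with exact per-berry ground truth.
#
# The generator emulates the imaging protocol the pipeline is built for:
# sliced berry halves laid out on white paper and photographed from above.
# Each berry half is a filled rotated ellipse with a dark blue-purple skin
# annulus and pale flesh; an impact bruise is a rim-anchored angular wedge of
# discolored flesh reaching toward the center. Because masks are rasterized
# first and colored second, every berry's true bruising ratio is known
# exactly.

#' Synthetic plate configuration
#'
#' @param seed integer base seed; together with the plate index it fixes the
#'   plate's private RNG stream.
#' @param n_berries berry halves per plate.
#' @param image_size square plate side in pixels.
#' @param berry_radius_range min/max geometric-mean radius in pixels.
#' @param ellipse_eccentricity_range min/max major/minor axis ratio.
#' @param skin_thickness_frac skin annulus thickness as a fraction of the
#'   local radius.
#' @param bruise_fraction_dist target bruise-area fraction distribution:
#'   `list(family = "uniform", min, max)`, `list(family = "fixed", value)`, or
#'   `list(family = "beta", shape1, shape2, scale)` (a scaled Beta on
#'   \[0, scale\]). All supports must lie in \[0, 0.9\].
#' @param color_model reference RGB colors (`background`, `skin`, `flesh`,
#'   `bruise`) plus a per-berry uniform `jitter` magnitude in 8-bit units.
#' @param noise_sd per-pixel Gaussian color noise, 8-bit units.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_berries = 20L,
                         image_size = 640L,
                         berry_radius_range = c(24, 32),
                         ellipse_eccentricity_range = c(1.0, 1.3),
                         skin_thickness_frac = 0.12,
                         bruise_fraction_dist = list(family = "uniform",
                                                     min = 0.05, max = 0.45),
                         color_model = list(background = c(245, 245, 240),
                                            skin = c(45, 35, 80),
                                            flesh = c(225, 230, 190),
                                            bruise = c(150, 75, 60),
                                            jitter = 10),
                         noise_sd = 5) {
  stopifnot(is_count(n_berries), is_count(image_size), image_size >= 32,
            length(berry_radius_range) == 2L,
            berry_radius_range[1L] <= berry_radius_range[2L],
            ellipse_eccentricity_range[1L] >= 1,
            skin_thickness_frac >= 0, skin_thickness_frac < 1,
            noise_sd >= 0)
  fam <- bruise_fraction_dist$family %||% "uniform"
  if (!fam %in% c("uniform", "fixed", "beta")) {
    stopf("unknown bruise fraction distribution family: %s", fam)
  }
  structure(list(seed = as.integer(seed), n_berries = as.integer(n_berries),
                 image_size = as.integer(image_size),
                 berry_radius_range = berry_radius_range,
                 ellipse_eccentricity_range = ellipse_eccentricity_range,
                 skin_thickness_frac = skin_thickness_frac,
                 bruise_fraction_dist = bruise_fraction_dist,
                 color_model = color_model, noise_sd = noise_sd),
            class = "synth_config")
}

draw_bruise_fraction <- function(dist, n) {
  f <- switch(dist$family,
    fixed = rep(dist$value, n),
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2) * (dist$scale %||% 0.9)
  )
  pmin(pmax(f, 0), 0.9)
}

# Solve berry geometry on its local bounding window. Returns full-plate-grid
# masks plus the exact rasterized ratio.
draw_berry <- function(cx, cy, r, q, phi, skin_frac, target_frac, psi, size) {
  a <- r * sqrt(q); b <- r / sqrt(q)
  ext <- ceiling(a) + 2L
  x0 <- max(0L, floor(cx - ext)); x1 <- min(size - 1L, ceiling(cx + ext))
  y0 <- max(0L, floor(cy - ext)); y1 <- min(size - 1L, ceiling(cy + ext))
  xs <- (x0:x1) + 0.5; ys <- (y0:y1) + 0.5
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(phi) + gy * sin(phi)
  v <- -gx * sin(phi) + gy * cos(phi)
  berry <- (u / a)^2 + (v / b)^2 <= 1
  flesh <- (u / (a * (1 - skin_frac)))^2 + (v / (b * (1 - skin_frac)))^2 <= 1
  n_berry <- sum(berry)

  bruise <- rep(FALSE, length(gx))
  if (target_frac > 0 && n_berry > 0) {
    # Wedge anchored at rim direction psi: take the k flesh pixels whose
    # polar angle is closest to psi, k chosen to hit the target fraction of
    # the rasterized berry area exactly (up to angular ties).
    ang <- atan2(gy[flesh], gx[flesh])
    d <- abs(((ang - psi + pi) %% (2 * pi)) - pi)
    k <- round(target_frac * n_berry)
    if (k >= length(d)) {
      bruise[flesh] <- TRUE
    } else if (k > 0) {
      thr <- sort(d, partial = k)[k]
      sel <- d <= thr
      b2 <- rep(FALSE, sum(flesh)); b2[sel] <- TRUE
      bruise[flesh] <- b2
    }
  }

  to_mask <- function(member) {
    m <- matrix(FALSE, nrow = size, ncol = size)
    m[cbind(rep(ys, times = length(xs))[member] + 0.5,
            rep(xs, each = length(ys))[member] + 0.5)] <- TRUE
    m
  }
  list(berry_mask = to_mask(berry), flesh = to_mask(flesh),
       bruise_mask = to_mask(bruise),
       true_ratio = if (n_berry > 0) sum(bruise) / n_berry else 0)
}

#' Generate a synthetic plate image with exact ground truth
#'
#' Berries are placed on a jittered grid so masks never overlap; placement
#' is refused before drawing when `n_berries` exceeds the grid capacity.
#' The bruise wedge's angular extent is solved per berry so that the
#' rasterized bruise-to-berry pixel fraction matches the drawn target (exact
#' up to angular ties, well within 0.02). Identical `(seed, plate_index)`
#' give bit-identical output.
#'
#' @param cfg a [synth_config()].
#' @param plate_index non-negative integer; selects the plate's RNG stream.
#' @return `list(image, berries, image_id)` where `image` is an
#'   `h x w x 3` array in \[0, 255\] and `berries` is a list of ground-truth
#'   records `list(box, berry_mask, bruise_mask, true_ratio)` in reading
#'   order.
#' @export
generate_plate <- function(cfg, plate_index = 0L) {
  size <- cfg$image_size
  q_max <- cfg$ellipse_eccentricity_range[2L]
  r_max <- cfg$berry_radius_range[2L]
  ext_max <- r_max * sqrt(q_max)
  cell <- 2 * (ext_max + 6)
  k <- floor(size / cell)
  if (cfg$n_berries > k * k) {
    stopf("cannot place %d non-overlapping berries of radius <= %.0f on a %dx%d plate (capacity %d)",
          cfg$n_berries, r_max, size, size, k * k)
  }
  cm <- cfg$color_model

  with_seed(derive_seed(cfg$seed, plate_index), {
    cells <- sample(k * k, cfg$n_berries)
    jit_max <- cell / 2 - ext_max - 2
    fracs <- draw_bruise_fraction(cfg$bruise_fraction_dist, cfg$n_berries)

    img <- array(0, dim = c(size, size, 3L))
    for (ch in 1:3) img[, , ch] <- cm$background[ch]

    berries <- vector("list", cfg$n_berries)
    for (i in seq_len(cfg$n_berries)) {
      ci <- cells[i] - 1L
      cx <- (ci %% k) * cell + cell / 2 + stats::runif(1, -jit_max, jit_max)
      cy <- (ci %/% k) * cell + cell / 2 + stats::runif(1, -jit_max, jit_max)
      r <- stats::runif(1, cfg$berry_radius_range[1L], cfg$berry_radius_range[2L])
      q <- stats::runif(1, cfg$ellipse_eccentricity_range[1L],
                        cfg$ellipse_eccentricity_range[2L])
      phi <- stats::runif(1, 0, pi)
      psi <- stats::runif(1, -pi, pi)
      g <- draw_berry(cx, cy, r, q, phi, cfg$skin_thickness_frac,
                      fracs[i], psi, size)
      jit <- stats::runif(3, -cm$jitter, cm$jitter)
      skin_col <- pmin(pmax(cm$skin + jit, 0), 255)
      flesh_col <- pmin(pmax(cm$flesh + jit, 0), 255)
      bruise_col <- pmin(pmax(cm$bruise + jit, 0), 255)
      skin_px <- g$berry_mask & !g$flesh
      flesh_px <- g$flesh & !g$bruise_mask
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[skin_px] <- skin_col[ch]
        plane[flesh_px] <- flesh_col[ch]
        plane[g$bruise_mask] <- bruise_col[ch]
        img[, , ch] <- plane
      }
      berries[[i]] <- list(box = mask_bbox(g$berry_mask),
                           berry_mask = g$berry_mask,
                           bruise_mask = g$bruise_mask,
                           true_ratio = g$true_ratio)
    }
    if (cfg$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = cfg$noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))

    # reading order: row-major by box top-left
    ord <- order(vapply(berries, function(b) b$box[["y0"]], 0),
                 vapply(berries, function(b) b$box[["x0"]], 0))
    berries <- berries[ord]
    list(image = img, berries = berries,
         image_id = sprintf("plate_%04d", plate_index))
  })
}

# Trace the outer contour of a mask as a normalized polygon (sub-pixel,
# <= 1 px chordal deviation). Level-0.5 contour lines pass halfway between
# member and non-member pixel centers.
mask_to_polygon <- function(mask, class_id = 0L, confidence = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  z <- matrix(0, nrow = w + 2L, ncol = h + 2L)
  z[2:(w + 1L), 2:(h + 1L)] <- t(mask) * 1
  cl <- grDevices::contourLines(x = seq_len(w + 2L) - 1.5,
                                y = seq_len(h + 2L) - 1.5, z = z,
                                levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  best <- cl[[which.max(vapply(cl, function(c) length(c$x), 0))]]
  v <- cbind(best$x / w, best$y / h)
  # contourLines closes the loop by repeating the first point
  n <- nrow(v)
  if (n > 1 && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) return(NULL)
  polygon_outline(pmin(pmax(v, 0), 1), class_id = class_id,
                  confidence = confidence)
}

#' Export ground truth as YOLO-dialect annotation files
#'
#' Writes one box label file (berry detection), one berry-polygon file and
#' one bruise-polygon file, with polygons traced from the rasterized masks
#' at sub-pixel resolution.
#'
#' @param plate a [generate_plate()] result.
#' @param dir output directory (created if needed).
#' @param confidences optional numeric vector; when given the files are
#'   written as prediction-dialect records with per-berry confidences.
#' @return named character vector of the written file paths, invisibly.
#' @export
export_annotations <- function(plate, dir, confidences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  size_h <- dim(plate$image)[1L]; size_w <- dim(plate$image)[2L]
  id <- plate$image_id
  boxes <- empty_boxes()
  berry_polys <- list(); bruise_polys <- list()
  for (i in seq_along(plate$berries)) {
    b <- plate$berries[[i]]
    conf <- if (is.null(confidences)) NA_real_ else confidences[i]
    boxes <- rbind(boxes, data.frame(
      class_id = 0L,
      cx = (b$box[["x0"]] + b$box[["x1"]]) / 2 / size_w,
      cy = (b$box[["y0"]] + b$box[["y1"]]) / 2 / size_h,
      w = (b$box[["x1"]] - b$box[["x0"]]) / size_w,
      h = (b$box[["y1"]] - b$box[["y0"]]) / size_h,
      confidence = conf))
    pconf <- if (is.null(confidences)) NULL else confidences[i]
    bp <- mask_to_polygon(b$berry_mask, confidence = pconf)
    if (!is.null(bp)) berry_polys[[length(berry_polys) + 1L]] <- bp
    if (sum(b$bruise_mask) > 0) {
      rp <- mask_to_polygon(b$bruise_mask, confidence = pconf)
      if (!is.null(rp)) bruise_polys[[length(bruise_polys) + 1L]] <- rp
    }
  }
  src <- if (is.null(confidences)) "ground-truth" else "prediction"
  paths <- c(box = file.path(dir, paste0(id, "_boxes.txt")),
             berry = file.path(dir, paste0(id, "_berry.txt")),
             bruise = file.path(dir, paste0(id, "_bruise.txt")))
  write_labels(annotation_set(id, boxes = boxes, source = src),
               paths[["box"]], kind = "box")
  write_labels(annotation_set(id, polygons = berry_polys, source = src),
               paths[["berry"]], kind = "polygon")
  write_labels(annotation_set(id, polygons = bruise_polys, source = src),
               paths[["bruise"]], kind = "polygon")
  invisible(paths)
}

#' Cultivar simulation specification
#'
#' Describes a two-group population of cultivars (bruise-resistant vs
#' bruise-susceptible) with per-berry ratio noise and a firmness covariate
#' linear in the cultivar's mean ratio with negative slope. Default firmness
#' parameters put YM20_BrSt-like values in the 2-5 MPa/% range.
#'
#' @param n_cultivars number of cultivars (split as evenly as possible
#'   between the two groups).
#' @param group_means mean bruising ratio of the resistant and susceptible
#'   groups, both in (0, 1).
#' @param within_cultivar_sd berry-to-berry (and cultivar-to-cultivar) ratio
#'   standard deviation.
#' @param berries_per_cultivar samples per cultivar-year.
#' @param firmness_intercept,firmness_slope,firmness_noise_sd parameters of
#'   `firmness = intercept + slope * mean_ratio + noise`; the slope is
#'   negative (firmer berries bruise less).
#' @param years character vector of year labels.
#' @param seed integer seed.
#' @return a list of class `cultivar_sim_spec`.
#' @export
cultivar_sim_spec <- function(n_cultivars = 20L,
                              group_means = c(resistant = 0.12,
                                              susceptible = 0.32),
                              within_cultivar_sd = 0.03,
                              berries_per_cultivar = 20L,
                              firmness_intercept = 6,
                              firmness_slope = -10,
                              firmness_noise_sd = 0.3,
                              years = "2021",
                              seed = 1L) {
  stopifnot(is_count(n_cultivars), n_cultivars >= 2,
            all(group_means > 0), all(group_means < 1),
            firmness_slope < 0, within_cultivar_sd >= 0)
  structure(list(n_cultivars = as.integer(n_cultivars),
                 group_means = sort(group_means),
                 within_cultivar_sd = within_cultivar_sd,
                 berries_per_cultivar = as.integer(berries_per_cultivar),
                 firmness_intercept = firmness_intercept,
                 firmness_slope = firmness_slope,
                 firmness_noise_sd = firmness_noise_sd,
                 years = years, seed = as.integer(seed)),
            class = "cultivar_sim_spec")
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(pmax(mean, 0), 1), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

#' Simulate per-berry bruising ratios and firmness for a cultivar panel
#'
#' Each cultivar is assigned to the resistant or susceptible group (balanced
#' random assignment), draws a cultivar-level mean ratio near its group
#' level, then per-berry ratios from a truncated normal on \[0, 1\] for each
#' year; firmness is `intercept + slope * cultivar_mean + noise`, one value
#' per cultivar-year. Generating labels are kept for recovery tests.
#'
#' @param spec a [cultivar_sim_spec()].
#' @return data frame with columns `cultivar, year, sample, ratio, group,
#'   firmness` (one row per berry).
#' @export
simulate_cultivars <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_cultivars
    half <- n %/% 2L
    groups <- sample(c(rep("resistant", n - half), rep("susceptible", half)))
    cultivars <- sprintf("cv%02d", seq_len(n))
    mu <- unname(spec$group_means[ifelse(groups == "resistant", 1L, 2L)]) +
      stats::rnorm(n, 0, spec$within_cultivar_sd / 2)
    mu <- pmin(pmax(mu, 0.01), 0.99)
    rows <- list()
    for (yi in seq_along(spec$years)) {
      for (i in seq_len(n)) {
        ratios <- rtruncnorm01(spec$berries_per_cultivar, mu[i],
                               spec$within_cultivar_sd)
        firm <- spec$firmness_intercept + spec$firmness_slope * mu[i] +
          stats::rnorm(1, 0, spec$firmness_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          cultivar = cultivars[i], year = spec$years[yi],
          sample = seq_len(spec$berries_per_cultivar),
          ratio = ratios, group = groups[i], firmness = firm)
      }
    }
    do.call(rbind, rows)
  })
}
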