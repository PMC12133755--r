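test_that("the classical detector finds every berry on a clean plate", {
  pl <- small_plate()
  det <- classical_detector()
  d <- det$predict(pl$image)
  expect_equal(length(d$boxes), length(pl$berries))
  for (b in d$boxes) {
    best <- max(vapply(pl$berries, function(g) box_iou(b, g$box), 0))
    expect_gte(best, 0.8)
  }
  expect_true(all(d$confidences > 0 & d$confidences <= 1))

  blank <- array(245, dim = c(64, 64, 3))
  expect_equal(length(det$predict(blank)$boxes), 0)
})

test_that("the classical berry segmenter recovers cross-section masks", {
  pl <- small_plate()
  seg <- classical_berry_segmenter()
  for (i in c(1, 3, 6)) {
    g <- pl$berries[[i]]
    cr <- crop(pl$image, g$box, pad = 4)
    mask <- seg$predict(cr)
    full <- uncrop_mask(mask)
    expect_gte(mask_iou(full, g$berry_mask), 0.95)
  }
  uniform <- array(245, dim = c(40, 40, 3))
  attr(uniform, "offset") <- c(x = 0L, y = 0L)
  attr(uniform, "parent_dim") <- c(h = 40L, w = 40L)
  expect_error(seg$predict(uniform), "segmentation failure")
})

test_that("the classical bruise segmenter tracks the true bruise fraction", {
  pl <- small_plate()  # true fraction 0.25
  seg_b <- classical_berry_segmenter()
  seg_r <- classical_bruise_segmenter()
  for (i in seq_along(pl$berries)) {
    g <- pl$berries[[i]]
    cr <- crop(pl$image, g$box, pad = 4)
    bmask <- seg_b$predict(cr)
    rmask <- seg_r$predict(cr, bmask)
    ratio <- sum(rmask & bmask) / sum(bmask)
    expect_lt(abs(ratio - g$true_ratio), 0.05)
  }

  # unbruised berries give an empty mask (ratio 0), not noise
  cfg0 <- synth_config(seed = 5, n_berries = 4, image_size = 320,
                       bruise_fraction_dist = list(family = "fixed",
                                                   value = 0))
  pl0 <- generate_plate(cfg0)
  for (g in pl0$berries) {
    cr <- crop(pl0$image, g$box, pad = 4)
    bmask <- seg_b$predict(cr)
    expect_equal(sum(seg_r$predict(cr, bmask)), 0)
  }

  # fully discolored flesh: ratio approaches 1 - skin fraction
  cfg1 <- synth_config(seed = 6, n_berries = 4, image_size = 320,
                       bruise_fraction_dist = list(family = "fixed",
                                                   value = 0.9))
  pl1 <- generate_plate(cfg1)
  flesh_frac <- mean(vapply(pl1$berries, `[[`, 0, "true_ratio"))
  expect_gt(flesh_frac, 0.7)  # capped at the flesh fraction, ~(1 - s)^2
  for (g in pl1$berries) {
    cr <- crop(pl1$image, g$box, pad = 4)
    bmask <- seg_b$predict(cr)
    rmask <- seg_r$predict(cr, bmask)
    expect_lt(abs(sum(rmask & bmask) / sum(bmask) - g$true_ratio), 0.08)
  }
})

test_that("ground-truth backends reproduce true ratios bit-exactly", {
  pl <- small_plate()
  tb <- truth_backend(pl)
  pr <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise,
                  image_id = pl$image_id)
  expect_identical(vapply(pr$berries, `[[`, 0, "ratio"),
                   vapply(pl$berries, `[[`, 0, "true_ratio"))
  # reading-order indices are 1..n and stable
  expect_equal(vapply(pr$berries, `[[`, 0L, "index"),
               seq_along(pl$berries))
})

test_that("the file backend replays exported predictions through the cascade", {
  pl <- small_plate()
  dir <- withr::local_tempdir()
  export_annotations(pl, dir, confidences = rep(0.9, length(pl$berries)))
  fb <- file_backend(dir)
  pr <- run_plate(pl$image, fb$detector, fb$berry, fb$bruise,
                  image_id = pl$image_id)
  expect_equal(length(pr$berries), length(pl$berries))
  got <- sort(vapply(pr$berries, `[[`, 0, "ratio"))
  want <- sort(vapply(pl$berries, `[[`, 0, "true_ratio"))
  expect_equal(got, want, tolerance = 0.02)  # polygon-trace discretization

  # missing files warn and yield empty predictions
  fb2 <- file_backend(withr::local_tempdir())
  expect_warning(d <- fb2$detector$predict(pl$image,
                                           list(image_id = "nope")),
                 "no prediction file")
  expect_equal(length(d$boxes), 0)
})

test_that("the cascade respects thresholds, padding and purity", {
  pl <- small_plate()
  tb <- truth_backend(pl)
  # threshold above every confidence -> empty result
  pr_none <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise,
                       conf_threshold = 1.01)
  expect_equal(length(pr_none$berries), 0)
  expect_equal(nrow(as.data.frame(pr_none)), 0)

  # ratio invariant to crop padding
  pr0 <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise, pad = 0)
  pr12 <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise, pad = 12)
  expect_identical(vapply(pr0$berries, `[[`, 0, "ratio"),
                   vapply(pr12$berries, `[[`, 0, "ratio"))

  # identical inputs -> identical output
  pr_a <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise)
  pr_b <- run_plate(pl$image, tb$detector, tb$berry, tb$bruise)
  expect_identical(as.data.frame(pr_a), as.data.frame(pr_b))

  # wrong task wiring is refused
  expect_error(run_plate(pl$image, tb$berry, tb$detector, tb$bruise),
               "task mismatch")
})

test_that("per-berry segmentation failures degrade gracefully", {
  pl <- small_plate()
  tb <- truth_backend(pl)
  failing <- backend("broken", "segment-berry", function(crop_img, context) {
    stop("segmentation failure: injected")
  })
  pr <- run_plate(pl$image, tb$detector, failing, tb$bruise)
  expect_equal(length(pr$failures), length(pl$berries))
  expect_true(all(is.na(vapply(pr$berries, `[[`, 0, "ratio"))))
  df <- as.data.frame(pr)
  expect_equal(nrow(df), length(pl$berries))  # rows kept, ratio null
})
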