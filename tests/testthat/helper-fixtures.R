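# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small plate reused by unit tests.
small_plate <- function() {
  cached("small_plate", generate_plate(
    synth_config(seed = 101, n_berries = 6, image_size = 320,
                 bruise_fraction_dist = list(family = "fixed", value = 0.25))))
}

# Pair classical pipeline output with ground truth by best box IoU and
# return detection and ratio recovery statistics.
classical_recovery <- function(n_plates, seed, n_berries = 20L) {
  key <- sprintf("recovery_%d_%d_%d", n_plates, seed, n_berries)
  cached(key, {
    cfg <- synth_config(seed = seed, n_berries = n_berries)
    det <- classical_detector()
    seg_b <- classical_berry_segmenter()
    seg_r <- classical_bruise_segmenter()
    tp <- 0L; fp <- 0L; fn <- 0L
    abs_err <- double()
    for (p in seq_len(n_plates) - 1L) {
      pl <- generate_plate(cfg, plate_index = p)
      pr <- run_plate(pl$image, det, seg_b, seg_r, image_id = pl$image_id)
      truths <- lapply(pl$berries, `[[`, "box")
      preds <- lapply(pr$berries, `[[`, "box")
      confs <- vapply(pr$berries, `[[`, 0, "confidence")
      mt <- match_predictions(preds, truths, confs, box_iou, 0.5)
      tp <- tp + mt$tp; fp <- fp + mt$fp; fn <- fn + mt$fn
      for (k in seq_len(nrow(mt$assignments))) {
        a <- mt$assignments[k, ]
        if (a$is_tp && !is.na(pr$berries[[a$pred]]$ratio)) {
          abs_err <- c(abs_err, abs(pr$berries[[a$pred]]$ratio -
                                      pl$berries[[a$truth]]$true_ratio))
        }
      }
    }
    f1 <- 2 * tp / (2 * tp + fp + fn)
    list(tp = tp, fp = fp, fn = fn, f1 = f1,
         mean_abs_ratio_err = mean(abs_err), n_ratio = length(abs_err))
  })
}

# One-year cultivar screen recovery for a given seed.
screen_recovery <- function(seed) {
  spec <- cultivar_sim_spec(seed = seed)
  df <- simulate_cultivars(spec)
  rep <- screen_report(df, firmness = unique(df[, c("cultivar", "year",
                                                    "firmness")]))
  r <- rep[[1L]]
  truth <- unique(df[, c("cultivar", "group")])
  labels <- r$cluster$labels[truth$cultivar]
  list(recovery = mean(labels == truth$group),
       threshold = r$cluster$threshold,
       firmness_p = if (is.null(r$firmness_test)) NA_real_ else
         r$firmness_test$p,
       slope = if (is.null(r$regression)) NA_real_ else r$regression$slope)
}
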