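# Overlay rendering: green = healthy cross-section, red = bruise, with
# "index: ratio" printed above each box.

blend_mask <- function(img, mask, color, alpha = 0.45) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Render a plate result as an annotated overlay PNG
#'
#' Blends the healthy cross-section region in green and the bruise region
#' in red over the plate image, draws each detection box, and prints
#' `index: ratio` above it.
#'
#' @param img the original `h x w x 3` plate image.
#' @param result a `plate_result` from [run_plate()].
#' @param path destination PNG path.
#' @param alpha mask blending opacity.
#' @return `path`, invisibly.
#' @export
overlay_plate <- function(img, result, path, alpha = 0.45) {
  out <- img
  for (b in result$berries) {
    if (is.null(b$berry_mask)) next
    healthy <- b$berry_mask & !b$bruise_mask
    out <- blend_mask(out, healthy, c(0, 200, 0), alpha)
    out <- blend_mask(out, b$bruise_mask, c(220, 0, 0), alpha)
  }
  h <- dim(out)[1L]; w <- dim(out)[2L]
  grDevices::png(path, width = w, height = h)
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0))
  graphics::rasterImage(out / 255, 0, h, w, 0)
  for (b in result$berries) {
    graphics::rect(b$box[["x0"]], b$box[["y0"]], b$box[["x1"]], b$box[["y1"]],
                   border = "yellow", lwd = 1.5)
    lab <- if (is.na(b$ratio)) sprintf("%d: failed", b$index) else
      sprintf("%d: %.2f", b$index, b$ratio)
    graphics::text((b$box[["x0"]] + b$box[["x1"]]) / 2,
                   max(b$box[["y0"]] - 4, 8), lab,
                   col = "black", cex = 0.7)
  }
  invisible(path)
}
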