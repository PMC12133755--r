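#' berrybruise: internal bruising quantification from sliced-fruit images
#'
#' Pixel-grid conventions used throughout the package:
#' \itemize{
#'   \item An image is a numeric array of dimension \code{c(height, width, 3)}
#'     holding 8-bit RGB samples in \[0, 255\], row-major with the origin at
#'     the top-left.
#'   \item A binary mask is a logical matrix of dimension
#'     \code{c(height, width)} on the same grid.
#'   \item A bounding box is an integer vector \code{c(x0, y0, x1, y1)} in
#'     0-based pixel coordinates, half-open: the box covers pixels with
#'     \code{x0 <= x < x1} and \code{y0 <= y < y1}, so its area is
#'     \code{(x1 - x0) * (y1 - y0)} with no off-by-one corrections.
#'   \item Pixel \code{(x, y)} (0-based) maps to matrix element
#'     \code{[y + 1, x + 1]}; its center sits at \code{(x + 0.5, y + 0.5)}.
#' }
#'
#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-unit stream seed from a base seed and an index, kept inside
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %%
    2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
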