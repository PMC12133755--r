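# Independent oracle implementations used to validate the package's
# primitives. These deliberately share no code with the implementation.

# Brute-force point-in-polygon by angle summation (winding number), checked
# pixel center by pixel center. Vertices in pixel coordinates.
oracle_rasterize <- function(px, py, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  n <- length(px)
  for (yy in seq_len(height)) {
    cy <- yy - 0.5
    for (xx in seq_len(width)) {
      cx <- xx - 0.5
      # even-odd rule via crossing count of a ray to the right
      crossings <- 0L
      for (i in seq_len(n)) {
        j <- if (i == 1L) n else i - 1L
        y1 <- py[i]; y2 <- py[j]
        if ((y1 > cy) != (y2 > cy)) {
          xi <- px[i] + (cy - y1) * (px[j] - px[i]) / (y2 - y1)
          if (cx < xi) crossings <- crossings + 1L
        }
      }
      mask[yy, xx] <- crossings %% 2L == 1L
    }
  }
  mask
}

# Greedy confidence-ordered matching directly on an IoU matrix.
oracle_match <- function(iou, conf, threshold) {
  np <- nrow(iou); nt <- ncol(iou)
  order_idx <- order(-conf, seq_len(np))
  used <- rep(FALSE, nt)
  tp <- logical(np)
  match_to <- rep(NA_integer_, np)
  for (i in order_idx) {
    best <- NA_integer_; best_iou <- -Inf
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] > best_iou) { best <- j; best_iou <- iou[i, j] }
    }
    if (!is.na(best) && best_iou >= threshold) {
      used[best] <- TRUE; tp[i] <- TRUE; match_to[i] <- best
    }
  }
  list(tp = tp, match_to = match_to)
}

# AP as the mean over ground-truth recall levels t/nt of the maximum
# precision among prediction prefixes reaching that recall (the direct
# Lebesgue-sum reading of the area under the enveloped PR curve).
oracle_ap <- function(iou, conf, threshold) {
  nt <- ncol(iou)
  if (nt == 0L) return(if (nrow(iou) == 0L) 1 else 0)
  m <- oracle_match(iou, conf, threshold)
  ord <- order(-conf, seq_len(nrow(iou)))
  tp_seq <- m$tp[ord]
  cum_tp <- cumsum(tp_seq)
  prec <- cum_tp / seq_along(cum_tp)
  rec <- cum_tp / nt
  total <- 0
  for (t in seq_len(nt)) {
    level <- t / nt
    ok <- which(rec >= level)
    total <- total + if (length(ok) == 0L) 0 else max(prec[ok])
  }
  total / nt
}

# WSS-optimal bipartition by exhaustive enumeration of all 2-subsets.
oracle_best_bipartition <- function(x) {
  n <- length(x)
  best <- list(wss = Inf, members = NULL)
  for (code in seq_len(2^n - 2L)) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    a <- x[sel]; b <- x[!sel]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best$wss - 1e-12) best <- list(wss = wss, members = sel)
  }
  best
}

# Random axis-aligned boxes on a small integer grid for IoU cross-checks.
random_box <- function(grid = 20L) {
  x <- sort(sample(0:grid, 2L)); y <- sort(sample(0:grid, 2L))
  if (x[1L] == x[2L]) x[2L] <- x[2L] + 1L
  if (y[1L] == y[2L]) y[2L] <- y[2L] + 1L
  bbox(x[1L], y[1L], x[2L], y[2L])
}

# Cell-by-cell IoU of two boxes by enumerating integer pixels.
oracle_box_iou <- function(a, b, grid = 40L) {
  cover <- function(bx) {
    m <- matrix(FALSE, grid, grid)
    m[(bx[["y0"]] + 1L):bx[["y1"]], (bx[["x0"]] + 1L):bx[["x1"]]] <- TRUE
    m
  }
  ma <- cover(a); mb <- cover(b)
  u <- sum(ma | mb)
  if (u == 0L) 0 else sum(ma & mb) / u
}
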