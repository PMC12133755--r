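# Per-cultivar susceptibility analysis: aggregation, the exact 1-D
# two-means split with a susceptibility threshold, Welch's t-test, the
# ratio-vs-firmness regression, and the per-year screen report.

#' Aggregate per-berry ratios to cultivar-year means
#'
#' @param records data frame with columns `cultivar`, `year`, `ratio`, and
#'   optionally `firmness` (constant within cultivar-year).
#' @return data frame with one row per (cultivar, year): `mean_ratio`, `n`,
#'   `n_null` (excluded missing ratios), and `firmness` if present.
#'   Cultivar-years with no valid ratio are dropped with a warning.
#' @export
aggregate_ratios <- function(records) {
  stopifnot(all(c("cultivar", "year", "ratio") %in% names(records)))
  key <- interaction(records$cultivar, records$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    valid <- !is.na(g$ratio)
    data.frame(cultivar = g$cultivar[1L], year = g$year[1L],
               mean_ratio = if (any(valid)) mean(g$ratio[valid]) else NA_real_,
               n = sum(valid), n_null = sum(!valid),
               firmness = if ("firmness" %in% names(g))
                 g$firmness[1L] else NA_real_)
  }))
  dropped <- out$n == 0L
  if (any(dropped)) {
    warning(sprintf("dropped %d cultivar-year(s) with no valid ratio: %s",
                    sum(dropped),
                    paste(out$cultivar[dropped], collapse = ", ")),
            call. = FALSE)
    out <- out[!dropped, ]
  }
  rownames(out) <- NULL
  out
}

#' Exact two-means clustering of a 1-D sample
#'
#' The globally optimal 2-partition of the values minimizing within-cluster
#' sum of squares. In one dimension the optimum is contiguous in sorted
#' order, so an exhaustive scan over the `n - 1` sorted split points finds
#' exactly the K = 2 K-means optimum, deterministically and without
#' initialization. The susceptibility threshold is the midpoint of the two
#' centroids; the midpoint between the closest cross-cluster members
#' (`boundary`) is also reported.
#'
#' @param means numeric vector (>= 2 values, not all identical).
#' @param names optional labels carried into the result.
#' @return an object of class `cluster_result`: `labels`
#'   (`"resistant"`/`"susceptible"` per value, resistant = lower centroid),
#'   `centroids`, `threshold`, `boundary`, `wss`, and the Welch test
#'   (`t_statistic`, `degrees_freedom`, `p_value`) between the two clusters
#'   of values (NA when a cluster has fewer than 2 members).
#' @export
two_means_cluster <- function(means, names = NULL) {
  n <- length(means)
  if (n < 2L) stopf("clustering needs at least 2 values")
  if (length(unique(means)) == 1L) {
    stopf("degenerate clustering: all %d values are identical", n)
  }
  ord <- order(means)
  x <- means[ord]
  cs <- cumsum(x); css <- cumsum(x^2)
  tot_s <- cs[n]; tot_ss <- css[n]
  wss <- vapply(seq_len(n - 1L), function(k) {
    s1 <- cs[k]; ss1 <- css[k]
    s2 <- tot_s - s1; ss2 <- tot_ss - ss1
    (ss1 - s1^2 / k) + (ss2 - s2^2 / (n - k))
  }, 0)
  k <- which.min(wss)
  lower <- x[seq_len(k)]; upper <- x[(k + 1L):n]
  centroids <- c(resistant = mean(lower), susceptible = mean(upper))
  labels <- rep("susceptible", n)
  labels[ord[seq_len(k)]] <- "resistant"
  if (!is.null(names)) names(labels) <- names
  welch <- if (k >= 2L && n - k >= 2L) {
    tryCatch(welch_t_test(lower, upper), error = function(e) NULL)
  } else NULL
  structure(list(labels = labels, centroids = centroids,
                 threshold = mean(centroids),
                 boundary = (max(lower) + min(upper)) / 2,
                 wss = wss[k], sizes = c(resistant = k, susceptible = n - k),
                 t_statistic = welch$t %||% NA_real_,
                 degrees_freedom = welch$df %||% NA_real_,
                 p_value = welch$p %||% NA_real_),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result: %d resistant / %d susceptible, centroids %.3f / %.3f, threshold %.3f>\n",
    x$sizes[1L], x$sizes[2L], x$centroids[1L], x$centroids[2L], x$threshold))
  if (!is.na(x$p_value)) {
    cat(sprintf("  Welch t = %.3f, df = %.2f, p = %.3g\n",
                x$t_statistic, x$degrees_freedom, x$p_value))
  }
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with unbiased
#' variances, Welch-Satterthwaite degrees of freedom, and a two-sided p
#' from the Student-t tail. Robust to unequal variances and sample sizes;
#' reduces to the pooled t-test when variances and sizes are equal.
#'
#' @param a,b numeric samples, each of size >= 2, with nonzero variance in
#'   at least one.
#' @return list `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stopf("Welch's t-test needs at least 2 observations per sample (got %d, %d)",
          na, nb)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stopf("both samples have zero variance")
  sa <- va / na; sb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Ordinary least-squares fit of mean ratio on firmness
#'
#' Simple linear regression via [stats::lm()], reporting the fitted slope,
#' intercept, coefficient of determination and RMSE over residuals
#' (`sqrt(mean(residuals^2))`). When the response is constant
#' (`SS_tot = 0`), R-squared is defined as 0.
#'
#' @param x predictor (firmness values), not constant, length >= 3.
#' @param y response (mean bruising ratios), same length.
#' @return list `slope`, `intercept`, `r_squared`, `rmse`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("regression needs at least 3 points")
  if (stats::var(x) == 0) stopf("predictor is constant")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, rmse = sqrt(mean(res^2)), n = length(x), fit = fit)
}

#' Per-year cultivar susceptibility screen
#'
#' For each year (or pooled across years): aggregate berry ratios to
#' cultivar means, cluster them into resistant/susceptible with
#' [two_means_cluster()], and, when firmness values are available, compare
#' the firmness of the two recovered groups with Welch's t-test and fit the
#' mean-ratio-vs-firmness regression. Years with fewer than 4 cultivars are
#' skipped with a warning.
#'
#' @param records per-berry data frame (`cultivar, year, ratio`, optional
#'   `firmness`).
#' @param firmness optional data frame (`cultivar, year, firmness`) merged
#'   onto the aggregates when `records` itself lacks firmness.
#' @param pool_years cluster all years together instead of per year.
#' @return an object of class `screen_report`: per-year list of
#'   `list(year, table, cluster, firmness_test, regression)`.
#' @export
screen_report <- function(records, firmness = NULL, pool_years = FALSE) {
  agg <- aggregate_ratios(records)
  if (!is.null(firmness)) {
    agg$firmness <- NULL
    agg <- merge(agg, firmness[, c("cultivar", "year", "firmness")],
                 by = c("cultivar", "year"), all.x = TRUE)
  }
  if (pool_years) agg$year <- "pooled"
  years <- unique(agg$year)
  out <- list()
  for (yr in years) {
    tab <- agg[agg$year == yr, ]
    if (nrow(tab) < 4L) {
      warning(sprintf("year '%s' skipped: only %d cultivar(s)", yr, nrow(tab)),
              call. = FALSE)
      next
    }
    cl <- two_means_cluster(tab$mean_ratio, names = tab$cultivar)
    tab$label <- unname(cl$labels)
    firm_test <- NULL
    regression <- NULL
    have_firm <- "firmness" %in% names(tab) && sum(!is.na(tab$firmness)) >= 4L
    if (have_firm) {
      fa <- tab$firmness[tab$label == "resistant" & !is.na(tab$firmness)]
      fb <- tab$firmness[tab$label == "susceptible" & !is.na(tab$firmness)]
      if (length(fa) >= 2L && length(fb) >= 2L) {
        firm_test <- welch_t_test(fa, fb)
      }
      ok <- !is.na(tab$firmness)
      if (sum(ok) >= 3L && stats::var(tab$firmness[ok]) > 0) {
        regression <- fit_linear(tab$firmness[ok], tab$mean_ratio[ok])
        regression$fit <- NULL
      }
    }
    out[[as.character(yr)]] <- list(year = yr, table = tab, cluster = cl,
                                    firmness_test = firm_test,
                                    regression = regression)
  }
  if (length(out) == 0L) stopf("no year had enough cultivars to screen")
  structure(out, class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  for (yr in names(x)) {
    r <- x[[yr]]
    cat(sprintf("Year %s: %d cultivars, threshold %.3f (centroids %.3f/%.3f)\n",
                yr, nrow(r$table), r$cluster$threshold,
                r$cluster$centroids[1L], r$cluster$centroids[2L]))
    if (!is.null(r$firmness_test)) {
      cat(sprintf("  firmness Welch test: t = %.2f, df = %.1f, p = %.3g\n",
                  r$firmness_test$t, r$firmness_test$df, r$firmness_test$p))
    }
    if (!is.null(r$regression)) {
      cat(sprintf("  ratio ~ firmness: slope %.4f, R^2 %.3f, RMSE %.4f\n",
                  r$regression$slope, r$regression$r_squared,
                  r$regression$rmse))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.screen_report <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r) {
    tab <- r$table
    tab$threshold <- r$cluster$threshold
    tab
  }))
}

#' Plot a screen report
#'
#' One panel per year: cultivar mean ratios ordered by value, colored by
#' recovered group, with the susceptibility threshold drawn; if firmness is
#' available, a second row of panels shows the ratio-vs-firmness scatter
#' with the fitted line.
#'
#' @param x a `screen_report`.
#' @param ... unused.
#' @export
plot.screen_report <- function(x, ...) {
  yrs <- names(x)
  have_reg <- any(vapply(x, function(r) !is.null(r$regression), TRUE))
  old <- graphics::par(mfrow = c(if (have_reg) 2L else 1L, length(yrs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- c(resistant = "#2C7BB6", susceptible = "#D7191C")
  for (yr in yrs) {
    r <- x[[yr]]
    tab <- r$table[order(r$table$mean_ratio), ]
    graphics::plot(seq_len(nrow(tab)), tab$mean_ratio,
                   col = cols[tab$label], pch = 19,
                   xlab = "cultivar (ranked)", ylab = "mean bruising ratio",
                   main = sprintf("%s (thr %.3f)", yr, r$cluster$threshold))
    graphics::abline(h = r$cluster$threshold, lty = 2)
  }
  if (have_reg) {
    for (yr in yrs) {
      r <- x[[yr]]
      tab <- r$table
      graphics::plot(tab$firmness, tab$mean_ratio, col = cols[tab$label],
                     pch = 19, xlab = "firmness (YM20_BrSt)",
                     ylab = "mean bruising ratio",
                     main = if (!is.null(r$regression))
                       sprintf("R2 = %.2f", r$regression$r_squared) else yr)
      if (!is.null(r$regression)) {
        graphics::abline(r$regression$intercept, r$regression$slope, lty = 2)
      }
    }
  }
  invisible(x)
}
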