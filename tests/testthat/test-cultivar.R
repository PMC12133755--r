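test_that("ratio aggregation averages per cultivar-year and reports nulls", {
  df <- data.frame(cultivar = c("a", "a", "a", "b", "b", "c"),
                   year = c("Y1", "Y1", "Y1", "Y1", "Y2", "Y1"),
                   ratio = c(0.1, 0.2, 0.3, NA, 0.4, NA))
  expect_warning(agg <- aggregate_ratios(df), "no valid ratio")
  a <- agg[agg$cultivar == "a", ]
  expect_equal(a$mean_ratio, 0.2)
  expect_equal(a$n, 3L)
  # b has two years -> only the valid year survives, with the null counted
  expect_equal(nrow(agg[agg$cultivar == "b", ]), 1L)
  expect_equal(agg$year[agg$cultivar == "b"], "Y2")
  # all-null cultivar dropped
  expect_false("c" %in% agg$cultivar)
})

test_that("two-means clustering finds the exact 1-D optimum", {
  cl <- two_means_cluster(c(0.10, 0.12, 0.30, 0.32))
  expect_equal(unname(cl$centroids), c(0.11, 0.31))
  expect_equal(cl$threshold, 0.21)
  expect_equal(unname(cl$sizes), c(2L, 2L))

  cl01 <- two_means_cluster(c(0, 1))
  expect_equal(unname(cl01$centroids), c(0, 1))
  expect_equal(cl01$threshold, 0.5)

  expect_error(two_means_cluster(rep(0.2, 5)), "degenerate")
  expect_error(two_means_cluster(0.3), "at least 2")
})

test_that("clustering equals exhaustive-partition and Lloyd's optima", {
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(3:12, 1)
    x <- round(c(rnorm(ceiling(n / 2), 0.15, 0.05),
                 rnorm(floor(n / 2), 0.35, 0.05)), 4)
    x <- pmin(pmax(x, 0.01), 0.99)
    if (length(unique(x)) < 2) next
    cl <- two_means_cluster(x)
    best <- oracle_best_bipartition(x)
    expect_equal(cl$wss, best$wss, tolerance = 1e-12)
    # same bipartition (up to label swap)
    got <- cl$labels == "resistant"
    expect_true(identical(got, best$members) ||
                  identical(got, !best$members))
    # Lloyd's from the best distinct-pair initialization agrees on WSS
    pairs <- t(combn(unique(x), 2))
    lloyd <- min(apply(pairs, 1, function(ctr) {
      stats::kmeans(x, centers = matrix(ctr), algorithm = "Lloyd",
                    iter.max = 50)$tot.withinss
    }))
    expect_equal(cl$wss, lloyd, tolerance = 1e-9)
    # order invariance
    cl2 <- two_means_cluster(rev(x))
    expect_equal(cl2$wss, cl$wss)
    expect_equal(unname(cl2$centroids), unname(cl$centroids))
  }
})

test_that("Welch's t-test reproduces the hand-derived example", {
  w <- welch_t_test(1:5, 2:6)
  expect_equal(w$t, -1, tolerance = 1e-12)
  expect_equal(w$df, 8, tolerance = 1e-12)
  expect_equal(w$p, 0.3466, tolerance = 1e-3)
  # cross-check against the reference implementation
  ref <- t.test(1:5, 2:6)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)

  # symmetry and identical samples
  sw <- welch_t_test(2:6, 1:5)
  expect_equal(sw$t, -w$t); expect_equal(sw$p, w$p)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  expect_error(welch_t_test(1, 1:5), "at least 2")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch reduces to the pooled t-test for equal variance and size", {
  set.seed(81)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    # force equal sample variances by standardizing
    a <- (a - mean(a)) / sd(a); b <- (b - mean(b)) / sd(b) + runif(1, -2, 2)
    w <- welch_t_test(a, b)
    expect_equal(w$df, 2 * n - 2, tolerance = 1e-9)
    pooled <- t.test(a, b, var.equal = TRUE)
    expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-9)
  }
})

test_that("the firmness regression recovers known lines and edge rules", {
  x <- c(1, 2, 3, 4, 6)
  y <- -0.05 * x + 0.4
  f <- fit_linear(x, y)
  expect_equal(f$slope, -0.05)
  expect_equal(f$intercept, 0.4)
  expect_equal(f$r_squared, 1)
  expect_equal(f$rmse, 0)

  fc <- fit_linear(x, rep(0.3, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  expect_error(fit_linear(rep(2, 5), y), "constant")
  expect_error(fit_linear(1:2, c(0.1, 0.2)), "at least 3")

  # seeded noisy line: slope within its analytic 95% CI, R^2 in band
  set.seed(91)
  n <- 40; sd_e <- 0.03; slope <- -0.05
  xs <- runif(n, 1, 6)
  ys <- slope * xs + 0.4 + rnorm(n, 0, sd_e)
  fn <- fit_linear(xs, ys)
  se_slope <- sd_e / sqrt(sum((xs - mean(xs))^2))
  expect_lt(abs(fn$slope - slope), qnorm(0.975) * se_slope * 1.5)
  # signal sd ~ 0.072 vs noise 0.03 puts the population R^2 near 0.85;
  # at n = 40 the sampling band is wide, so bound loosely
  expect_gt(fn$r_squared, 0.55)
})

test_that("the screen recovers simulated groups and firmness differences", {
  out <- screen_recovery(seed = 424)
  expect_equal(out$recovery, 1)
  expect_gt(out$threshold, 0.18); expect_lt(out$threshold, 0.26)
  expect_lt(out$firmness_p, 0.01)
  expect_lt(out$slope, 0)  # susceptible berries are softer

  # single-group data -> degenerate clustering surfaces as an error
  one_group <- data.frame(cultivar = rep(sprintf("c%d", 1:5), each = 3),
                          year = "Y1", ratio = rep(0.2, 15))
  expect_error(screen_report(one_group), "degenerate")

  # too-few cultivars in the only year
  tiny <- data.frame(cultivar = rep(c("a", "b"), each = 3), year = "Y1",
                     ratio = runif(6))
  expect_warning(expect_error(screen_report(tiny), "no year"), "skipped")
})

test_that("multi-year screens cluster each year independently", {
  spec <- cultivar_sim_spec(years = c("2021", "2022"), seed = 15)
  df <- simulate_cultivars(spec)
  rep_ <- screen_report(df)
  expect_setequal(names(rep_), c("2021", "2022"))
  for (yr in names(rep_)) {
    expect_lt(rep_[[yr]]$cluster$centroids[1], rep_[[yr]]$cluster$centroids[2])
    expect_gt(rep_[[yr]]$cluster$threshold, rep_[[yr]]$cluster$centroids[1])
    expect_lt(rep_[[yr]]$cluster$threshold, rep_[[yr]]$cluster$centroids[2])
  }
  pooled <- screen_report(df, pool_years = TRUE)
  expect_equal(names(pooled), "pooled")
})
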