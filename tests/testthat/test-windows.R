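test_that("window construction counts and membership follow the sliding rule", {
  expect_length(build_windows(meta_for(runif(12, 20, 80)), w = 10)$windows, 3)
  expect_length(build_windows(meta_for(runif(38, 24, 79)), w = 10)$windows, 29)
  one <- build_windows(meta_for(runif(10, 20, 80)), w = 10)
  expect_length(one$windows, 1)
  expect_length(one$windows[[1]], 10)

  # the stated-window-count overrides
  md38 <- meta_for(runif(38, 24, 79))
  expect_length(build_windows(md38, w = 10, drop_last = TRUE)$windows, 28)
  expect_length(build_windows(md38, w = 10, n_windows = 28)$windows, 28)

  # window k holds the samples ranked k..k+w-1 by age
  md <- meta_for(c(50, 30, 40, 60, 20))
  bw <- build_windows(md, w = 3)
  expect_equal(bw$windows[[1]], c("s005", "s002", "s003"))
  expect_equal(bw$windows[[3]], c("s003", "s001", "s004"))
  expect_equal(bw$mean_age, c(30, 40, 50))

  expect_error(build_windows(meta_for(runif(5, 20, 80)), w = 10), "at least")
})

test_that("window means match direct recomputation", {
  set.seed(4)
  m <- rand_expr(5, 12)
  md <- meta_for(sort(runif(12, 20, 80)))
  bw <- build_windows(md, w = 10)
  wm <- window_means(m, bw)
  for (k in seq_along(bw$windows))
    expect_equal(wm[, k], rowMeans(m[, bw$windows[[k]]]))
  # constant probe stays constant
  m2 <- m
  m2[1, ] <- 7
  expect_true(all(window_means(m2, bw)[1, ] == 7))
})

test_that("row z-scores use the population sd and flag constant probes", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)

  m <- rbind(a = c(2, 2, 2), b = c(1, 5, 9))
  z2 <- zscore_rows(m)
  expect_equal(unname(z2["a", ]), c(0, 0, 0))
  expect_equal(attr(z2, "constant"), c(a = TRUE, b = FALSE))
  expect_equal(mean(z2["b", ]), 0)
  expect_equal(mean(z2["b", ]^2), 1)  # population variance 1

  expect_error(zscore_rows(matrix(1, 2, 1)), ">= 2")
})

test_that("pearson_r and fold change match their closed forms", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:4, c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_warning(r <- pearson_r(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:3, 1:4), "equal length")

  wm <- matrix(c(5, 6), 1)
  attr(wm, "scale") <- "log2"
  expect_equal(fold_change_last_first(wm), 2)
  expect_equal(fold_change_last_first(matrix(c(4, 4), 1), scale = "log2"), 1)
  expect_equal(fold_change_last_first(matrix(c(6, 5.543), 1),
                                      scale = "log2"),
               2^-0.457, tolerance = 1e-12)
  expect_equal(fold_change_last_first(matrix(c(2, 5), 1),
                                      scale = "linear"), 2.5)
  expect_error(fold_change_last_first(matrix(c(-1, 5), 1),
                                      scale = "linear"), "positive")
})

test_that("trend classification reproduces the bundled screen hit list", {
  t1 <- load_fixture("table1")
  got <- classify_trend(t1$pearson_r, t1$fc_last_first)
  expect_equal(got, t1$trend)
  expect_equal(sum(got == "increasing"), 48)
  expect_equal(sum(got == "decreasing"), 21)
  expect_error(classify_trend(0.5, 2, r_threshold = 1.5), "r_threshold")
  expect_error(classify_trend(0.5, 2, fc_threshold = 0.9), "fc_threshold")
})

test_that("screen correlation is invariant to per-probe z-scoring", {
  sim <- simulate_cohort(n_probes = 50, seed = 21)
  scr <- age_trend_screen(sim$expr, sim$metadata)
  raw_r <- apply(scr$window_means, 1, function(row)
    if (sd(row) == 0) NA_real_ else cor(row, scr$windows$mean_age))
  expect_equal(unname(raw_r), scr$table$pearson_r, tolerance = 1e-9)
})

test_that("screen labels are deterministic and mutually exclusive", {
  sim <- simulate_cohort(seed = 13)
  s1 <- age_trend_screen(sim$expr, sim$metadata)
  s2 <- age_trend_screen(sim$expr, sim$metadata)
  expect_identical(s1$table, s2$table)
  expect_true(all(s1$table$trend %in% c("increasing", "decreasing", "none")))
  out <- capture.output(print(s1))
  expect_match(out[1], "Sliding-window")
})
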