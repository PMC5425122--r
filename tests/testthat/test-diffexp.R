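test_that("group split is inclusive on the young side of the cutoff", {
  g <- split_groups(meta_for(c(24, 50, 51, 79)))
  expect_equal(as.character(g), c("young", "young", "elder", "elder"))
  expect_error(split_groups(meta_for(c(24, 30, 40, 45))), "elder")
  g38 <- split_groups(meta_for(runif(38, 24, 79)))
  expect_equal(length(g38), 38)
})

test_that("without shrinkage the moderated t is the classical pooled t", {
  set.seed(31)
  m <- rand_expr(50, 12)
  labels <- setNames(rep(c("young", "elder"), each = 6), colnames(m))
  mt <- moderated_t(m, labels, prior_df_mode = "none")
  for (i in c(1, 17, 50)) {
    tt <- t.test(m[i, 7:12], m[i, 1:6], var.equal = TRUE)
    expect_equal(mt$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(mt$p_raw[i], tt$p.value, tolerance = 1e-9)
  }

  # hand case: n = 3 vs 3, textbook pooled formula
  hm <- expression_matrix(rbind(p1 = c(0.1, -0.1, 0, 1.1, 0.9, 1.0)),
                          "p1", paste0("s", 1:6))
  lab <- setNames(rep(c("young", "elder"), each = 3), colnames(hm))
  mt2 <- moderated_t(hm, lab, prior_df_mode = "none")
  x <- c(0.1, -0.1, 0); y <- c(1.1, 0.9, 1.0)
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  expect_equal(mt2$t, (mean(y) - mean(x)) / (sp * sqrt(2 / 3)),
               tolerance = 1e-12)
})

test_that("identical group means give t near 0 and p near 1", {
  m <- expression_matrix(rbind(p1 = rep(c(1, 2, 3), 2)), "p1",
                         paste0("s", 1:6))
  lab <- setNames(rep(c("young", "elder"), each = 3), colnames(m))
  mt <- moderated_t(m, lab, prior_df_mode = "none")
  expect_equal(mt$t, 0)
  expect_equal(mt$p_raw, 1)
})

test_that("empirical-Bayes moderated t matches an independent implementation", {
  set.seed(32)
  m <- rand_expr(300, 10)
  m[1:20, 6:10] <- m[1:20, 6:10] + 1
  labels <- setNames(rep(c("young", "elder"), each = 5), colnames(m))
  mt <- moderated_t(m, labels)
  design <- cbind(1, rep(0:1, each = 5))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(mt$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-9)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(33)
  for (i in 1:5) {
    p <- runif(37)^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_gte(min(bh_adjust(p) - p), 0)  # q >= p always
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null matrices control the type-I rate and BH kills discoveries", {
  set.seed(34)
  frac <- replicate(5, {
    sim <- simulate_cohort(n_probes = 1000, frac_increasing = 0,
                           frac_decreasing = 0)
    de <- diff_expression(sim$expr, sim$metadata)
    c(mean(de$table$p_raw < 0.05), sum(de$table$direction != "none"))
  })
  expect_equal(mean(frac[1, ]), 0.05, tolerance = 0.015)
  expect_lte(mean(frac[2, ]), 1)
})

test_that("truly shifted probes are recovered with high power", {
  set.seed(35)
  detected <- replicate(5, {
    sim <- simulate_cohort(n_probes = 500, frac_increasing = 0,
                           frac_decreasing = 0)
    elder <- sim$metadata$age > 50
    shifted <- 1:20
    sim$expr[shifted, elder] <- sim$expr[shifted, elder] + 1
    de <- diff_expression(sim$expr, sim$metadata)
    sum(de$table$direction[shifted] == "UP")
  })
  expect_gte(median(detected), 18)
})

test_that("fold-change signs reproduce the bundled DE hit list directions", {
  t2 <- load_fixture("table2")
  got <- ifelse(t2$fc_elder_young > 1, "UP", "DOWN")
  expect_equal(got, t2$direction)
  expect_true(all(t2$adj_p < 0.05))
})
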