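test_that("expression TSV bundle round-trips and validates", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "expr.tsv")
  dp <- file.path(dir, "meta.tsv")

  # hand-written 3 x 4 bundle
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "pA\t1.5\t2\t3\t4",
               "pB\t2\t2\t2\t2",
               "pC\t0.1\t0.2\t0.3\t0.4"), mp)
  write.table(meta_for(c(24, 30, 50, 79), paste0("s", 1:4)), dp,
              sep = "\t", quote = FALSE, row.names = FALSE)
  b <- read_expression(mp, dp)
  expect_equal(dim(b$expr), c(3L, 4L))
  expect_equal(b$metadata$age, c(24, 30, 50, 79))

  # write-read identity on a generated 100 x 38 matrix
  m <- rand_expr(100, 38, seed = 11)
  m2p <- file.path(dir, "big.tsv")
  write_expression(m, m2p)
  write.table(meta_for(runif(38, 24, 79)), dp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  b2 <- read_expression(m2p, dp)
  expect_equal(unclass(b2$expr)[, ], unclass(m)[, ], tolerance = 1e-9)

  # sample missing from metadata is named in the error
  write.table(meta_for(c(24, 30, 50), paste0("s", 1:3)), dp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp, dp), "s4")

  # non-numeric cell names the offending column
  writeLines(c("probe_id\ts1\ts2", "pA\t1\toops", "pB\t2\t3"), mp)
  write.table(meta_for(c(24, 30), paste0("s", 1:2)), dp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp, dp), "s2")
})

test_that("expression matrix construction rejects invalid input", {
  expect_error(expression_matrix(matrix(1:4, 2), c("a", "a"), c("x", "y")),
               "duplicate probe")
  expect_error(expression_matrix(matrix(c(1, NA, 3, 4), 2),
                                 c("a", "b"), c("x", "y")), "non-finite")
  md <- meta_for(c(30, NA))
  expect_error(validate_metadata(md), "s002")
})

test_that("age ordering is stable for tied ages", {
  md <- data.frame(sample_id = c("b", "a", "c", "d"),
                   age = c(50, 30, 50, 20), stringsAsFactors = FALSE)
  out <- order_by_age(md)
  expect_equal(out$sample_id, c("d", "a", "b", "c"))
})

test_that("bundled tables have the documented shapes", {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t5 <- load_fixture("table5")
  expect_equal(nrow(t1), 69)
  expect_named(t1, c("probeset", "type", "pearson_r", "fc_last_first",
                     "trend"))
  expect_equal(nrow(t2), 57)
  expect_named(t2, c("probeset", "type", "adj_p", "fc_elder_young",
                     "direction"))
  expect_equal(nrow(t3), 23)
  expect_equal(nrow(t5), 5)
  expect_error(load_fixture("table9"))

  prior <- prior_aging_set(t3)
  expect_equal(nrow(prior), length(unique(t3$name)))
  expect_false(anyDuplicated(prior$name) > 0)
})

test_that("GMT reading collapses duplicates and round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg3",
               "SET_B\tdesc\tg1\tg4\tg5\tg6\tg7"), p)
  gmt <- read_gmt(p)
  expect_equal(lengths(gmt), c(SET_A = 3L, SET_B = 5L))

  writeLines(c("SET_A\tdesc\tg1\tg1\tg2"), p)
  expect_equal(lengths(read_gmt(p)), c(SET_A = 2L))

  writeLines(c("SET_A\tdesc"), p)
  expect_error(read_gmt(p), "fewer than 3")

  set.seed(3)
  sets <- lapply(1:10, function(i)
    sprintf("G%03d", sample(500, sample(5:30, 1))))
  names(sets) <- sprintf("S%02d", 1:10)
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets, ignore_attr = TRUE)
})

test_that("MTI and Cq readers validate their invariants", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "mti.tsv")
  writeLines(c("mirna\ttarget_gene\tevidence",
               "hsa-miR-1\tTP53\tstrong",
               "hsa-miR-1\tTP53\tstrong",
               "hsa-miR-1\tBCL2\tweak"), p)
  expect_warning(mti <- read_mti(p), "duplicate")
  expect_equal(nrow(mti), 2)

  q <- file.path(dir, "cq.tsv")
  writeLines(c("sample_id\tassay\tcq", "s1\ta\t20", "s1\ta\t21"), q)
  expect_error(read_cq(q), "duplicate")
  writeLines(c("sample_id\tassay\tcq", "s1\ta\t50"), q)
  expect_error(read_cq(q), "within")
})
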