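test_that("set overlap obeys inclusion-exclusion on random inputs", {
  set.seed(41)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1), replace = TRUE)
    b <- sample(letters, sample(5:20, 1), replace = TRUE)
    ov <- set_overlap(a, b)
    expect_equal(ov$n_union, ov$n_a + ov$n_b - ov$n_intersect)
    expect_true(ov$pct_overlap_of_union >= 0 &&
                  ov$pct_overlap_of_union <= 100)
  }
  dis <- set_overlap(c("x1", "x2"), c("y1", "y2", "y3"))
  expect_equal(dis$n_intersect, 0)
  expect_equal(dis$n_union, 5)
})

test_that("the two screens overlap as reported per sncRNA class", {
  ov <- compare_screens(load_fixture("table1"), load_fixture("table2"))
  mi <- ov[ov$class == "miRNA", ]
  sn <- ov[ov$class == "snoRNA", ]
  expect_equal(mi$n_intersect, 25)
  expect_equal(mi$n_union, 71)
  expect_equal(mi$pct_overlap_of_union, 100 * 25 / 71, tolerance = 1e-9)
  expect_equal(sn$n_union, 24)
  expect_equal(sn$n_intersect, 6)
})

test_that("the candidate cascade reproduces the two-stage selection", {
  t1 <- load_fixture("table1")
  cand <- candidate_filter(t1, fc_cut = 2)
  expect_equal(nrow(cand$stage1), 15)
  # fold changes strictly inside (1/2, 2) never pass stage 1
  expect_false(any(cand$stage1$fc_last_first > 0.5 &
                     cand$stage1$fc_last_first < 2))
  expect_false("hsa-miR-423-5p_st" %in% cand$stage1$probeset)  # FC 1.998
  expect_setequal(cand$candidates$name,
                  c("miR-15a", "miR-30b", "let-7i", "let-7g", "miR-1281"))

  empty_prior <- prior_aging_set(data.frame(name = character(0)))
  none <- candidate_filter(t1, prior = empty_prior)
  expect_equal(nrow(none$candidates), 0)
  expect_error(candidate_filter(t1, fc_cut = 1), "exceed 1")
})

test_that("MTI filtering keeps the requested evidence level and dedups targets", {
  mti <- data.frame(
    mirna = c(rep("hsa-miR-1_st", 5), "hsa-miR-2_st", "hsa-miR-2_st"),
    target_gene = c("A", "B", "C", "D", "E", "A", "F"),
    evidence = c("strong", "strong", "strong", "weak", "weak",
                 "strong", "strong"),
    stringsAsFactors = FALSE)
  expect_setequal(filter_mti(mti, "hsa-miR-1_st"), c("A", "B", "C"))
  # two miRNAs sharing target A: counted once
  both <- filter_mti(mti, c("hsa-miR-1_st", "hsa-miR-2_st"))
  expect_setequal(both, c("A", "B", "C", "F"))
  expect_message(filter_mti(mti, "hsa-miR-99"), "absent")
  by_dir <- filter_mti(mti, c("hsa-miR-1_st", "hsa-miR-2_st"),
                       direction = c("increasing", "decreasing"))
  expect_setequal(by_dir$increasing, c("A", "B", "C"))
  expect_setequal(by_dir$decreasing, c("A", "F"))

  # counts equal a brute-force scan on a random structured table
  set.seed(42)
  big <- data.frame(
    mirna = sample(paste0("hsa-miR-", 1:8, "_st"), 200, replace = TRUE),
    target_gene = sample(sprintf("G%02d", 1:40), 200, replace = TRUE),
    evidence = sample(c("strong", "weak"), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  q <- paste0("hsa-miR-", 1:4, "_st")
  got <- filter_mti(big, q)
  brute <- unique(big$target_gene[big$evidence == "strong" &
                                    big$mirna %in% q])
  expect_setequal(got, brute)
})

test_that("hypergeometric tails match enumeration", {
  expect_equal(hypergeom_overlap(0, 5, 5, 20), 1)
  expect_equal(hypergeom_overlap(5, 5, 5, 10), 1 / choose(10, 5))
  set.seed(43)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_overlap(k, K, n, N), hyper_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_overlap(6, 5, 10, 20), "inconsistent")
})

test_that("enrichment ranks planted overlaps first and matches brute force", {
  set.seed(44)
  universe <- sprintf("G%03d", 1:200)
  gmt <- lapply(1:5, function(i) sample(universe, 12))
  names(gmt) <- paste0("SET", 1:5)
  query <- gmt$SET3
  res <- suppressMessages(enrich(query, gmt, fdr = 0.5))
  expect_equal(res$set_name[1], "SET3")
  # p-values equal the brute-force tail on every set
  for (nm in names(gmt)) {
    k <- length(intersect(gmt[[nm]], query))
    N <- length(unique(unlist(gmt)))
    expect_equal(
      hyper_oracle(k, length(gmt[[nm]]), length(intersect(query,
                                                          unlist(gmt))), N),
      hypergeom_overlap(k, length(gmt[[nm]]),
                        length(intersect(query, unlist(gmt))), N),
      tolerance = 1e-12)
  }

  none <- enrich(c("ZZZ1", "ZZZ2"), gmt)
  expect_equal(nrow(none), 0)
  expect_error(enrich(character(0), gmt), "empty")
  expect_message(enrich(c(query, "NOT_A_GENE"), gmt, fdr = 0.5), "dropped")
})

test_that("probe names normalize to canonical miRNA names", {
  expect_equal(normalize_mirna_name("hsa-miR-93-star_st", alias_table = NA),
               "hsa-miR-93*")
  expect_equal(normalize_mirna_name("hsa-let-7g_st", alias_table = NA),
               "hsa-let-7g")
  expect_equal(normalize_mirna_name("U43_x_st", alias_table = NA), "U43")
  expect_equal(normalize_mirna_name("U91_s_st", alias_table = NA), "U91")
  # bundled alias table maps star forms to arm names; unknowns pass through
  expect_equal(normalize_mirna_name("hsa-miR-93-star_st"), "hsa-miR-93-3p")
  expect_equal(normalize_mirna_name("hsa-miR-77-star_st"), "hsa-miR-77*")
})
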