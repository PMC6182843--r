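test_that("singlets and malformed sequences are filtered with reasons", {
  tags <- tibble::tibble(
    tag = paste0("t", 1:5),
    sequence = c(paste0("CATG", strrep("A", 22)),
                 paste0("GATG", strrep("A", 22)),
                 paste0("CATG", strrep("A", 10)),
                 paste0("CATG", strrep("C", 22)),
                 paste0("CATG", strrep("G", 22))),
    x = c(1, 10, 10, 1, 5), y = c(0, 10, 10, 1, 7))
  flt <- filter_tags(tags)
  expect_setequal(flt$removed$tag, c("t1", "t2", "t3"))
  reasons <- setNames(flt$removed$filtered_reason, flt$removed$tag)
  expect_equal(unname(reasons[c("t1", "t2", "t3")]),
               c("singlet", "bad_prefix", "bad_length"))
  expect_true("t4" %in% flt$kept$tag)   # x+y = 2: kept under total reading

  per_lib <- filter_tags(tags, singlet = "per_library")
  expect_true("t4" %in% per_lib$removed$tag)
  expect_error(filter_tags(tibble::tibble(x = -1, y = 2)),
               class = "qpcrstab_data_error")
})

test_that("the conditional test matches direct summation to 1e-10", {
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6), 1)
  grid <- expand.grid(x = c(0, 1, 2, 5, 10, 50, 120, 200),
                      y = c(0, 1, 3, 7, 20, 80, 150, 200),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; y <- grid$y[i]
    expect_equal(ac_pvalue(x, y, 1e6, 1e6),
                 oracle_ac_pvalue(x, y, 1e6, 1e6), tolerance = 1e-10)
    expect_equal(ac_pvalue(x, y, 5e5, 2e6),
                 oracle_ac_pvalue(x, y, 5e5, 2e6), tolerance = 1e-10)
  }
})

test_that("the test is exactly symmetric under swapping libraries", {
  set.seed(6)
  for (i in 1:50) {
    x <- rpois(1, 30); y <- rpois(1, 60)
    n1 <- runif(1, 5e5, 2e6); n2 <- runif(1, 5e5, 2e6)
    expect_equal(ac_pvalue(x, y, n1, n2), ac_pvalue(y, x, n2, n1),
                 tolerance = 1e-12)
  }
})

test_that("the conditional pmf is a proper distribution", {
  for (x in c(0, 3, 25)) {
    for (r in c(0.5, 1, 2)) {
      total <- sum(oracle_ac_pmf(0:2000, x, 1e6, r * 1e6))
      expect_gte(total, 1 - 1e-9)
      expect_lte(total, 1 + 1e-9)
    }
  }
})

test_that("fold changes use the zero-replaced-by-one convention", {
  fc <- tag_fold_change(0, 8, 1e6, 1e6)
  expect_equal(fc$ratio, 8)
  expect_equal(fc$fold_change, 8)
  fc2 <- tag_fold_change(8, 0, 1e6, 1e6)
  expect_equal(fc2$fold_change, -8)
  # library-size normalization: same counts, double-depth library 2
  fc3 <- tag_fold_change(10, 10, 1e6, 2e6)
  expect_equal(fc3$ratio, 0.5)
  # agreement with the ratio-level convention wherever both apply
  fc4 <- tag_fold_change(5, 40, 1e6, 1e6)
  expect_equal(fc4$fold_change, fc_from_ratio(fc4$ratio))
  expect_equal(fc_from_ratio(1 / 8), -fc_from_ratio(8))
})

test_that("regulation calls follow the ratio and significance jointly", {
  de <- tag_de(tibble::tibble(tag = c("up", "down", "weak", "flat"),
                              x = c(10, 200, 22, 50),
                              y = c(120, 25, 28, 50)),
               n1 = 1e6, n2 = 1e6)
  expect_equal(de$call[de$tag == "up"], "UR")
  expect_equal(de$call[de$tag == "down"], "DR")
  expect_equal(de$call[de$tag == "weak"], "ns")
  expect_equal(de$call[de$tag == "flat"], "ns")
})

test_that("tag_de integrates filtering, testing and calls; BH is optional", {
  sim <- simulate_tags(n_null = 200, n_de = 10, fold = 8, seed = 12)
  de <- tag_de(sim$tags, n1 = sim$N1, n2 = sim$N2)
  expect_equal(nrow(de), 210)
  expect_true(all(de$call[de$true_de] == "UR"))
  de_bh <- tag_de(sim$tags, n1 = sim$N1, n2 = sim$N2, adjust = "BH")
  expect_true(all(de_bh$p_value >= de$p_value - 1e-15))

  with_singlet <- dplyr::bind_rows(
    sim$tags, tibble::tibble(tag = "lonely", x = 1L, y = 0L,
                             rate1 = 0, rate2 = 0, true_de = FALSE))
  de2 <- tag_de(with_singlet, n1 = sim$N1, n2 = sim$N2)
  lonely <- de2[de2$tag == "lonely", ]
  expect_equal(lonely$filtered_reason, "singlet")
  expect_true(is.na(lonely$p_value))
})
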