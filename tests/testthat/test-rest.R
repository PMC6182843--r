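test_that("efficiency-corrected ratios follow the closed form", {
  # target shifts one cycle, references flat, E = 2 -> R = 2
  expect_equal(pfaffl_ratio(c(21, 21), c(20, 20),
                            list(c(18, 18)), list(c(18, 18))), 2)
  # nothing moves -> R = 1
  expect_equal(pfaffl_ratio(c(20, 20), c(20, 20),
                            list(c(18, 18)), list(c(18, 18))), 1)
  # two references moving +1 and -1 cancel in the geometric mean
  expect_equal(pfaffl_ratio(c(22, 22), c(20, 20),
                            list(c(19, 19), c(19, 19)),
                            list(c(18, 18), c(20, 20))), 4)
  expect_error(pfaffl_ratio(numeric(0), c(20), list(c(18)), list(c(18))),
               class = "qpcrstab_size_error")
})

test_that("ratios are invariant to per-sample loading shifts at equal E", {
  set.seed(8)
  tc <- rnorm(3, 24, 0.3); tt <- rnorm(3, 22, 0.3)
  r1c <- rnorm(3, 18, 0.2); r1t <- rnorm(3, 18, 0.2)
  r2c <- rnorm(3, 16, 0.2); r2t <- rnorm(3, 16, 0.2)
  load_c <- rnorm(3, 0, 2); load_t <- rnorm(3, 0, 2)
  r_plain <- pfaffl_ratio(tc, tt, list(r1c, r2c), list(r1t, r2t))
  r_shift <- pfaffl_ratio(tc + load_c, tt + load_t,
                          list(r1c + load_c, r2c + load_c),
                          list(r1t + load_t, r2t + load_t))
  expect_equal(r_shift, r_plain, tolerance = 1e-12)
})

test_that("exact randomization enumerates all allocations like brute force", {
  set.seed(21)
  tc <- rnorm(3, 22, 0.5); tt <- rnorm(3, 20.5, 0.5)
  rc <- rnorm(3, 18, 0.2); rt <- rnorm(3, 18, 0.2)
  res <- randomization_test(tc, tt, list(rc), list(rt))
  expect_identical(res$iterations, "exact")
  lc <- -tc + rc; lt <- -tt + rt
  expect_equal(res$p_value, oracle_perm_p(lc, lt), tolerance = 1e-12)
})

test_that("degenerate and separated 3v3 designs hit the discrete bounds", {
  # identical groups sample-by-sample: every allocation >= observed 0
  same <- c(20, 20.5, 21)
  refs <- list(c(18, 18, 18))
  res <- randomization_test(same, same, refs, refs)
  expect_equal(res$p_value, 1)
  # complete separation: only the allocation and its mirror are extreme
  res2 <- randomization_test(c(25, 25.1, 25.2), c(20, 20.1, 20.2),
                             refs, refs)
  expect_equal(res2$p_value, 2 / 20)
})

test_that("label swap inverts the ratio and keeps the exact p-value", {
  set.seed(33)
  tc <- rnorm(4, 22, 0.4); tt <- rnorm(4, 21, 0.4)
  rc <- rnorm(4, 18, 0.3); rt <- rnorm(4, 18, 0.3)
  a <- randomization_test(tc, tt, list(rc), list(rt))
  b <- randomization_test(tt, tc, list(rt), list(rc))
  expect_equal(a$ratio, 1 / b$ratio, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values converge to the exact enumeration", {
  set.seed(55)
  tc <- rnorm(5, 22, 0.6); tt <- rnorm(5, 21.2, 0.6)
  rc <- rnorm(5, 18, 0.3); rt <- rnorm(5, 18, 0.3)
  exact <- randomization_test(tc, tt, list(rc), list(rt))
  mc <- randomization_test(tc, tt, list(rc), list(rt),
                           iterations = 20000, seed = 4, exact_limit = 1)
  expect_identical(exact$iterations, "exact")
  expect_identical(mc$iterations, 20000)
  expect_lt(abs(mc$p_value - exact$p_value), 0.02)
})

test_that("regulation calls and signed fold changes follow the conventions", {
  expect_equal(regulation_call(c(2.80, 0.9, 0.2), c(0.01, 0.30, 0.001)),
               c("UR", "ns", "DR"))
  expect_equal(regulation_call(1, 0.001), "ns")
  expect_equal(fc_from_ratio(c(0.5, 1, 2.8)), c(-2, 1, 2.8))
  expect_equal(fc_from_ratio(1 / 1.94), -1.94)
  expect_error(fc_from_ratio(0), class = "qpcrstab_domain_error")
})

test_that("per-time expression analysis compares against time-0 controls", {
  sim <- simulate_cq(cq_sim_config(seed = 1))
  out <- rest_analysis(sim$cq, targets = "EF1a",
                       references = c("UE21D", "UNK", "ACT"))
  expect_equal(nrow(out), 6)   # 2 accessions x 3 times
  expect_true(all(out$ratio > 0))
  expect_true(all(out$call %in% c("UR", "DR", "ns")))
  expect_true(all(out$n_control == 3 & out$n_treated == 3))
  # the designed +1.5-cycle treatment shift depresses the ratio
  expect_true(mean(out$ratio < 1) >= 5 / 6)
  expect_error(rest_analysis(sim$cq, targets = "nope", references = "UNK"),
               class = "qpcrstab_input_error")

  # with 3v3 biological samples the exact test bottoms out at p = 0.10;
  # well-level permutation restores resolution below alpha = 0.05
  expect_true(all(out$p_value >= 0.1 - 1e-12))
  wells <- rest_analysis(sim$cq, targets = "EF1a",
                         references = c("UE21D", "UNK", "ACT"),
                         collapse_tech = FALSE)
  expect_true(all(wells$n_control == 9 & wells$n_treated == 9))
  expect_true(any(wells$call == "DR"))
})

test_that("cross-platform agreement needs one matching time point", {
  expect_true(agreement("UR", c("UR", "UR", "UR")))
  expect_false(agreement("UR", c("DR", "DR", "ns")))
  expect_true(agreement("ns", c("UR", "ns", "ns")))
  expect_error(agreement("UR", character(0)),
               class = "qpcrstab_input_error")
  expect_error(agreement("UP", "UR"), class = "qpcrstab_input_error")
})

test_that("the published call grid summarizes to 9 of 16 validated", {
  calls <- cowpea_expression_calls()
  expect_equal(nrow(calls), 48)
  s <- summarize_agreement(calls)
  expect_equal(s$n, 16)
  expect_equal(s$n_validated, 9)
  expect_equal(s$pct_validated, 56)
})
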