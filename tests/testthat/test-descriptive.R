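test_that("x-fold arithmetic uses each gene's efficiency", {
  # Cq {19,20,21}: AM = 20, ddof-1 SD exactly 1 cycle
  m <- rbind(a = c(19, 20, 21), b = c(20.4, 21.1, 20.9))
  colnames(m) <- paste0("s", 1:3)
  e <- efficiency_from_slope(-3.25)$efficiency_base
  bk <- bestkeeper(m, efficiencies = c(a = e, b = 2))
  a <- bk$stats[bk$stats$gene == "a", ]
  expect_equal(a$sd, 1.00, tolerance = 1e-12)
  expect_equal(round(a$xfold_sd, 2), 2.03)
  expect_true(a$xfold_min < 0 && a$xfold_max > 0)
})

test_that("a constant gene has degenerate descriptive statistics", {
  m <- rbind(flat = rep(20, 6), other = c(19, 20, 21, 20, 19, 21))
  colnames(m) <- paste0("s", 1:6)
  bk <- bestkeeper(m)
  flat <- bk$stats[bk$stats$gene == "flat", ]
  expect_equal(flat$gm, 20)
  expect_equal(flat$am, 20)
  expect_equal(flat$sd, 0)
  expect_equal(flat$cv_pct, 0)
  expect_equal(flat$xfold_sd, 1)
  expect_false(flat$inconsistent)
})

test_that("index correlations match a brute-force oracle", {
  m <- toy_cq_matrix(3, 6, seed = 8)
  bk <- bestkeeper(m)
  index <- apply(m, 2, function(col) exp(mean(log(col))))
  for (g in rownames(m)) {
    expect_equal(bk$stats$r_index[bk$stats$gene == g],
                 cor(m[g, ], index), tolerance = 1e-12)
  }
  expect_equal(bk$index$index, unname(index), tolerance = 1e-12)
})

test_that("ranking is by descending r with inconsistent genes demoted", {
  stats <- tibble::tibble(
    gene = c("a", "b", "c"),
    r_index = c(0.92, 0.98, 0.91),
    inconsistent = c(FALSE, FALSE, FALSE))
  rk <- rank_bestkeeper(stats)
  expect_equal(rk$gene, c("b", "a", "c"))

  stats$inconsistent[2] <- TRUE   # b has sd > 1
  rk2 <- rank_bestkeeper(stats)
  expect_equal(rk2$gene, c("a", "c", "b"))
  rk3 <- rank_bestkeeper(stats, demote_inconsistent = FALSE)
  expect_equal(rk3$gene, c("b", "a", "c"))
})

test_that("dispersion above one cycle flags a gene as inconsistent", {
  set.seed(14)
  m <- rbind(steady = rnorm(30, 20, 0.3), wild = rnorm(30, 17, 1.8))
  colnames(m) <- paste0("s", 1:30)
  bk <- bestkeeper(m)
  expect_false(bk$stats$inconsistent[bk$stats$gene == "steady"])
  expect_true(bk$stats$inconsistent[bk$stats$gene == "wild"])
  expect_true(bk$stats$sd[bk$stats$gene == "wild"] > 1)
})

test_that("single-gene panels degrade to the gene's own Cq with a warning", {
  m <- matrix(c(19, 20, 21), 1, 3,
              dimnames = list("only", paste0("s", 1:3)))
  expect_warning(bk <- bestkeeper(m), "single-gene")
  expect_equal(bk$index$index, c(19, 20, 21))
})

test_that("x-fold extremes bracket one when GM is interior", {
  set.seed(3)
  m <- matrix(rnorm(4 * 12, 20, 0.8), 4, 12,
              dimnames = list(letters[1:4], paste0("s", 1:12)))
  bk <- bestkeeper(m)
  interior <- bk$stats$min < bk$stats$gm & bk$stats$gm < bk$stats$max
  expect_true(all(-bk$stats$xfold_min[interior] > 1))
  expect_true(all(bk$stats$xfold_max[interior] > 1))
})

test_that("SD and MAD dispersion modes rank panels alike on symmetric noise", {
  # symmetric Gaussian noise clear of the 1-cycle inconsistency boundary
  specs <- tibble::tibble(gene = paste0("g", 1:5),
                          baseline_mu = c(16, 18, 19, 20, 22),
                          treat_effect = 0,
                          noise_sd = c(0.20, 0.45, 0.30, 0.40, 0.25))
  agree <- 0L
  for (s in 1:100) {
    sim <- simulate_cq(cq_sim_config(gene_specs = specs,
                                     sample_effect_sd = 0.5,
                                     seed = 3000 + s))
    m <- qpcrstab:::cq_matrix(sim$cq)
    r1 <- bestkeeper(m)$ranking$gene
    r2 <- bestkeeper(m, sd_mode = "mad")$ranking$gene
    agree <- agree + identical(r1, r2)
  }
  expect_gte(agree, 90)
})

test_that("delta-Ct pair SDs match brute force and detect shifted twins", {
  m <- toy_cq_matrix(4, 8, seed = 4)
  dct <- delta_ct(m)
  for (j in 1:3) for (k in (j + 1):4) {
    expect_equal(dct$pair_sd[j, k], sd(m[j, ] - m[k, ]), tolerance = 1e-12)
  }
  mean_sd <- rowSums(dct$pair_sd) / 3
  got <- setNames(dct$ranking$mean_sd, dct$ranking$gene)
  expect_equal(got[names(mean_sd)], mean_sd, tolerance = 1e-12)

  twin <- rbind(m, twin = m[1, ] + 1)
  dct2 <- delta_ct(twin)
  expect_equal(dct2$pair_sd["g1", "twin"], 0, tolerance = 1e-12)
})

test_that("delta-Ct is invariant to per-gene and shared per-sample shifts", {
  m <- toy_cq_matrix(4, 8, seed = 10)
  d0 <- delta_ct(m)
  per_gene <- m + matrix(c(1, -4, 2, 0), 4, 8)
  expect_equal(delta_ct(per_gene)$pair_sd, d0$pair_sd, tolerance = 1e-12)
  set.seed(2)
  per_sample <- sweep(m, 2, rnorm(8, 0, 2), "+")
  expect_equal(delta_ct(per_sample)$pair_sd, d0$pair_sd, tolerance = 1e-12)
})

test_that("descriptive methods enforce their size preconditions", {
  m <- toy_cq_matrix(2, 4)
  expect_error(delta_ct(m), class = "qpcrstab_size_error")
  neg <- toy_cq_matrix(3, 4); neg[1, 1] <- -1
  expect_error(bestkeeper(neg), class = "qpcrstab_domain_error")
})
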