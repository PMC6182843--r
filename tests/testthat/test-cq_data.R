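test_that("read/write round trip preserves Cq values and metadata", {
  sim <- simulate_cq(cq_sim_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(sim$cq, f)
  back <- read_cq_table(f)
  expect_equal(back$cq, sim$cq$cq, tolerance = 1e-6)
  for (col in c("sample_id", "assay", "accession", "group", "time_min",
                "bio_rep", "tech_rep", "gene")) {
    expect_identical(back[[col]], sim$cq[[col]])
  }
})

test_that("format and data errors are specific", {
  sim <- simulate_cq(cq_sim_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(sim$cq, -"gene"), f)
  expect_error(read_cq_table(f), "gene", class = "qpcrstab_format_error")

  dup <- dplyr::bind_rows(sim$cq, dplyr::mutate(sim$cq[1, ], cq = cq + 1))
  expect_error(validate_cq(dup), sim$cq$sample_id[1],
               class = "qpcrstab_data_error")

  bad <- sim$cq
  bad$group[1] <- "mock"
  expect_error(validate_cq(bad), "mock", class = "qpcrstab_data_error")
})

test_that("unparseable Cq rows are rejected with a report", {
  sim <- simulate_cq(cq_sim_config(seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  raw <- sim$cq
  raw$cq <- as.character(raw$cq)
  raw$cq[2] <- "not-a-number"
  readr::write_csv(raw, f)
  rep_file <- withr::local_tempfile(fileext = ".json")
  expect_warning(out <- read_cq_table(f, report = rep_file), "rejected")
  expect_equal(nrow(out), nrow(raw) - 1)
  report <- jsonlite::read_json(rep_file)
  expect_equal(report$n_rejected, 1)
})

test_that("technical replicates collapse to their mean", {
  base <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    assay = "salt", accession = "a", group = "control", time_min = 0L,
    bio_rep = rep(1:2, each = 3), tech_rep = rep(1:3, 2), gene = "g1",
    cq = c(20.0, 20.2, 20.4, 20.0, NA, NA))
  out <- collapse_technical_reps(base)
  expect_equal(nrow(out), 2)
  expect_equal(out$cq, c(20.2, 20.0))

  all_na <- dplyr::mutate(base, cq = dplyr::if_else(bio_rep == 2,
                                                    NA_real_, cq))
  expect_true(is.na(collapse_technical_reps(all_na)$cq[2]))

  # 3 bio x 3 tech -> 3 rows per gene
  sim <- simulate_cq(cq_sim_config(seed = 1, accessions = "tolerant",
                                   times = 30L))
  out <- collapse_technical_reps(sim$cq)
  counts <- dplyr::count(out, gene, group)
  expect_true(all(counts$n == 3))
})

test_that("dispersion screen computes ddof-1 SD and CV and applies the threshold", {
  two <- tibble::tibble(
    sample_id = paste0("s", 1:4), assay = "salt", accession = "a",
    group = "control", time_min = 0L, bio_rep = 1:4, tech_rep = 1L,
    gene = rep(c("flat", "wild"), 2),
    cq = c(20, 18, 20, 22))
  disp <- cq_dispersion(two)
  flat <- disp[disp$gene == "flat", ]
  wild <- disp[disp$gene == "wild", ]
  expect_equal(flat$sd, 0)
  expect_equal(flat$cv_pct, 0)
  expect_true(flat$passes_screen)
  expect_equal(wild$sd, sd(c(18, 22)))        # 2.828 with ddof 1
  expect_equal(wild$cv_pct, 100 * sd(c(18, 22)) / 20, tolerance = 1e-12)
  expect_false(wild$passes_screen)
})

test_that("dispersion is invariant to sample order and excludes singletons", {
  sim <- simulate_cq(cq_sim_config(seed = 9))
  set.seed(4)
  shuffled <- sim$cq[sample.int(nrow(sim$cq)), ]
  a <- dplyr::arrange(cq_dispersion(sim$cq), assay, gene)
  b <- dplyr::arrange(cq_dispersion(shuffled), assay, gene)
  expect_equal(a, b)

  single <- sim$cq |>
    dplyr::filter(gene != "UNK" | sample_id == sample_id[1])
  expect_warning(out <- cq_dispersion(single), "UNK")
  expect_false("UNK" %in% out$gene)
})

test_that("averaging technical replicates shrinks the dispersion estimate", {
  # independent technical noise: SD on tech means <= SD on raw wells
  shrunk <- 0L; total <- 0L
  for (rep in 1:100) {
    sim <- simulate_cq(cq_sim_config(seed = 1000 + rep,
                                     tech_noise_sd = 0.5))
    raw <- cq_dispersion(sim$cq)
    col <- cq_dispersion(sim$cq, use_tech_means = TRUE)
    j <- dplyr::inner_join(raw, col, by = c("assay", "gene"))
    shrunk <- shrunk + sum(j$sd.y <= j$sd.x)
    total <- total + nrow(j)
  }
  expect_gte(shrunk / total, 0.95)
})
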