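#' Seeded synthetic qPCR and tag-count data
#'
#' The simulators generate the three kinds of input the pipeline consumes —
#' long Cq tables, dilution series for standard curves, and tag-count
#' library pairs — from explicit generative models with known ground truth,
#' so every downstream method can be benchmarked without laboratory data.
#'
#' The Cq model is additive Gaussian noise on the Cq (log-quantity) scale:
#'
#' \deqn{Cq = \mu_g + \delta_g \cdot 1[\mathrm{treated}] + s_{sample} +
#'       e_{g,bio} + t_{g,well}}
#'
#' where `mu_g` is the per-gene baseline, `delta_g` a per-gene treatment
#' shift (0 for designed-stable genes), `s` a loading effect shared by all
#' genes of one biological sample (this induces the inter-gene correlation
#' that sample-centering normalization methods exploit), `e` gene-specific
#' biological noise and `t` technical (well) noise.
#'
#' @param gene_specs Tibble with columns `gene`, `baseline_mu` (cycles),
#'   `treat_effect` (cycles added under treatment) and `noise_sd`
#'   (biological SD, cycles).  The default panel mimics a seven-gene
#'   candidate reference set under stress: baselines 15.6–21.6 cycles;
#'   biological noise chosen so that the observed per-gene Cq SDs
#'   (noise + loading + treatment) span roughly 0.55–0.75 cycles for the
#'   six stable genes and about 1.35 for `EF1a`, the designed unstable
#'   gene, which carries a 1.5-cycle treatment effect on top of wide
#'   biological noise.
#' @param assay Assay label for the generated samples.
#' @param accessions Character vector of accession labels.
#' @param times Stress exposure times in minutes for the treated groups;
#'   controls are generated at 0 minutes.
#' @param n_bio,n_tech Biological and technical replicates per condition.
#' @param sample_effect_sd SD (cycles) of the shared per-sample loading
#'   effect.
#' @param tech_noise_sd SD (cycles) of technical replicate noise.
#' @param seed Integer seed; the same seed reproduces the data exactly.
#' @return `cq_sim_config()` returns the configuration as a list.
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 42))
#' sim$truth
#' @export
cq_sim_config <- function(gene_specs = NULL,
                          assay = "salt",
                          accessions = c("tolerant", "sensitive"),
                          times = c(30L, 60L, 90L),
                          n_bio = 3L, n_tech = 3L,
                          sample_effect_sd = 0.35,
                          tech_noise_sd = 0.2,
                          seed = 1L) {
  if (is.null(gene_specs)) {
    gene_specs <- tibble(
      gene = c("UNK", "bTUB", "FBOX", "UE21D", "UBQ10", "ACT", "EF1a"),
      baseline_mu = c(19.9, 19.8, 21.6, 18.4, 15.6, 20.4, 16.6),
      treat_effect = c(0, 0, 0, 0, 0, 0, 1.5),
      noise_sd = c(0.45, 0.50, 0.55, 0.40, 0.65, 0.50, 1.10))
  }
  gene_specs <- as_tibble(gene_specs)
  stopifnot(all(gene_specs$noise_sd >= 0), sample_effect_sd >= 0,
            tech_noise_sd >= 0, n_bio >= 1, n_tech >= 1,
            !anyDuplicated(gene_specs$gene))
  list(gene_specs = gene_specs, assay = assay, accessions = accessions,
       times = as.integer(times), n_bio = as.integer(n_bio),
       n_tech = as.integer(n_tech), sample_effect_sd = sample_effect_sd,
       tech_noise_sd = tech_noise_sd, seed = as.integer(seed))
}

# Run expr under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a long Cq table with known ground truth
#'
#' @param cfg A configuration from [cq_sim_config()].
#' @return A list with `cq` (a validated long Cq tibble, see
#'   [validate_cq()]) and `truth` (per-gene design: baseline, treatment
#'   effect, noise SD, and the designed stability class `stable`).
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 7))
#' head(sim$cq)
#' @export
simulate_cq <- function(cfg) {
  design <- tidyr::expand_grid(
    accession = cfg$accessions,
    condition = c(list(c("control", 0L)),
                  lapply(cfg$times, function(t) c("treated", t))),
    bio_rep = seq_len(cfg$n_bio)) |>
    dplyr::mutate(group = purrr::map_chr(.data$condition, 1),
                  time_min = as.integer(purrr::map_chr(.data$condition, 2))) |>
    dplyr::select(-"condition")

  g <- cfg$gene_specs
  cq <- with_seed(cfg$seed, {
    design$sample_effect <- rnorm(nrow(design), 0, cfg$sample_effect_sd)
    tidyr::expand_grid(design, gene = g$gene) |>
      dplyr::left_join(g, by = "gene") |>
      dplyr::mutate(
        bio_noise = rnorm(dplyr::n(), 0, .data$noise_sd)) |>
      tidyr::expand_grid(tech_rep = seq_len(cfg$n_tech)) |>
      dplyr::mutate(
        tech_noise = rnorm(dplyr::n(), 0, cfg$tech_noise_sd),
        cq = .data$baseline_mu +
          ifelse(.data$group == "treated", .data$treat_effect, 0) +
          .data$sample_effect + .data$bio_noise + .data$tech_noise)
  })
  cq <- cq |>
    dplyr::mutate(
      assay = cfg$assay,
      sample_id = paste(cfg$assay, .data$accession, .data$group,
                        .data$time_min, .data$bio_rep, .data$tech_rep,
                        sep = "_")) |>
    dplyr::select("sample_id", "assay", "accession", "group", "time_min",
                  "bio_rep", "tech_rep", "gene", "cq")
  truth <- g |> dplyr::mutate(stable = .data$treat_effect == 0)
  list(cq = validate_cq(cq), truth = truth)
}

#' Simulate a serial-dilution standard curve
#'
#' Generates a dilution series for a primer pair of known amplification
#' efficiency: `points` concentrations separated by `fold`-fold dilutions,
#' with Cq following the line `intercept + slope * log10(conc)` where
#' `slope = -1 / log10(E)` and `E = 1 + efficiency_pct / 100`, plus
#' Gaussian noise.
#'
#' @param efficiency_pct True amplification efficiency in percent (100 =
#'   perfect doubling).  Must correspond to an amplification base between
#'   1.5 and 2.2.
#' @param intercept Cq of the undiluted sample (cycles).
#' @param points Number of dilution points (default 5).
#' @param fold Dilution factor between consecutive points (default 10).
#' @param noise_sd Gaussian Cq noise SD (cycles).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param gene Gene label carried in the output.
#' @return A tibble with columns `gene`, `dilution_step`, `log10_conc`,
#'   `cq`, suitable for [fit_standard_curve()].
#' @examples
#' simulate_dilution_series(efficiency_pct = 103.09, intercept = 35.34)
#' @export
simulate_dilution_series <- function(efficiency_pct = 100, intercept = 35,
                                     points = 5, fold = 10, noise_sd = 0,
                                     seed = 1L, gene = "gene1") {
  e_base <- 1 + efficiency_pct / 100
  if (e_base < 1.5 || e_base > 2.2) {
    abort("Amplification base must lie in [1.5, 2.2].",
          class = "qpcrstab_config_error")
  }
  slope <- -1 / log10(e_base)
  log10_conc <- -(seq_len(points) - 1) * log10(fold)
  noise <- if (noise_sd > 0) {
    with_seed(seed, rnorm(points, 0, noise_sd))
  } else rep(0, points)
  tibble(gene = gene, dilution_step = seq_len(points),
         log10_conc = log10_conc,
         cq = intercept + slope * log10_conc + noise)
}

#' Simulate a pair of tag-count libraries
#'
#' Generates Poisson tag counts for two sequencing libraries.  `n_null`
#' tags share the same expression rate in both libraries; `n_de` tags are
#' differentially expressed with the given fold change in library 2.
#' Counts are `Poisson(rate * N / 1e6)` with `rate` in tags-per-million.
#'
#' @param n_null Number of null (equal-rate) tags.
#' @param n_de Number of designed differentially expressed tags.
#' @param base_rate Expression rate of null tags and of DE tags in library
#'   1, in tags per million.
#' @param fold Fold change of DE tags in library 2 (values < 1 mean
#'   down-regulation).
#' @param library_sizes Total tag counts `c(N1, N2)` of the two libraries.
#' @param seed Integer seed.
#' @param sequences Generate synthetic 26-base tag sequences with the
#'   `CATG` anchor prefix (default `FALSE`; ids `tag000001`... otherwise).
#' @return A list with `tags` (tibble: `tag`, optional `sequence`, `x`,
#'   `y`, `rate1`, `rate2`, `true_de`) and the library totals `N1`, `N2`.
#' @examples
#' sim <- simulate_tags(n_null = 100, n_de = 5, fold = 8, seed = 3)
#' head(sim$tags)
#' @export
simulate_tags <- function(n_null = 1000, n_de = 0, base_rate = 100,
                          fold = 8, library_sizes = c(1e6, 1e6),
                          seed = 1L, sequences = FALSE) {
  stopifnot(base_rate >= 0, all(library_sizes > 0), fold > 0)
  n <- n_null + n_de
  rate1 <- rep(base_rate, n)
  rate2 <- c(rep(base_rate, n_null), rep(base_rate * fold, n_de))
  N1 <- library_sizes[1]; N2 <- library_sizes[2]
  tags <- with_seed(seed, {
    out <- tibble(
      tag = sprintf("tag%06d", seq_len(n)),
      x = rpois(n, rate1 * N1 / 1e6),
      y = rpois(n, rate2 * N2 / 1e6),
      rate1 = rate1, rate2 = rate2,
      true_de = c(rep(FALSE, n_null), rep(TRUE, n_de)))
    if (sequences) {
      out$sequence <- vapply(seq_len(n), function(i) {
        paste0("CATG", paste(sample(c("A", "C", "G", "T"), 22,
                                    replace = TRUE), collapse = ""))
      }, character(1))
    }
    out
  })
  list(tags = tags, N1 = N1, N2 = N2)
}
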