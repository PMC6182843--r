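#' Efficiency-corrected relative expression ratio
#'
#' The expression ratio of a target gene between control and treated
#' groups, corrected for amplification efficiency and normalized to one or
#' more reference genes:
#'
#' \deqn{R = E_t^{\Delta Cq_t} / \mathrm{geomean}_r\, E_r^{\Delta Cq_r}}
#'
#' with `dCq = mean(control Cq) - mean(treated Cq)` for each gene.  With
#' several reference genes the denominator is the geometric mean of the
#' per-reference correction factors, i.e. normalization against the
#' geometric-mean normalization factor.
#'
#' @param target_control,target_treated Numeric vectors of target-gene Cq
#'   values for the control and treated replicates.
#' @param refs_control,refs_treated Lists of numeric vectors (one per
#'   reference gene) of reference Cq values for each side.
#' @param e_target Amplification base of the target (default 2).
#' @param e_refs Amplification base(s) of the references: one number or a
#'   vector matching the references.
#' @return The ratio R (> 1 means up-regulation under treatment).
#' @examples
#' pfaffl_ratio(c(21, 21.2), c(20, 20.2),
#'              refs_control = list(c(18, 18.1)),
#'              refs_treated = list(c(18, 18.1)))
#' @export
pfaffl_ratio <- function(target_control, target_treated,
                         refs_control, refs_treated,
                         e_target = 2, e_refs = 2) {
  if (length(target_control) < 1 || length(target_treated) < 1) {
    abort("Both sides need at least one replicate.",
          class = "qpcrstab_size_error")
  }
  if (length(refs_control) == 0) {
    abort("At least one reference gene is required.",
          class = "qpcrstab_size_error")
  }
  e_refs <- rep_len(e_refs, length(refs_control))
  dcq_t <- mean(target_control) - mean(target_treated)
  ref_factors <- purrr::map2_dbl(seq_along(refs_control), e_refs,
    function(i, e) e^(mean(refs_control[[i]]) - mean(refs_treated[[i]])))
  e_target^dcq_t / geomean(ref_factors)
}

#' Fixed-reallocation randomization test for an expression ratio
#'
#' Tests the null hypothesis of no expression difference between control
#' and treated groups by reallocating whole samples (each sample's
#' normalized log expression, target corrected by the reference-gene
#' normalization factor) between the two groups, preserving group sizes.
#' The test statistic is `|log R|`.  All allocations are enumerated
#' exactly when their number does not exceed `exact_limit`; otherwise a
#' seeded Monte-Carlo sample of allocations is drawn and the observed
#' allocation is counted in both numerator and denominator, keeping p > 0.
#'
#' @inheritParams pfaffl_ratio
#' @param iterations Monte-Carlo iterations used beyond the exact limit.
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param exact_limit Maximum number of allocations enumerated exactly.
#' @return A list: `p_value`, `ratio` (the observed R), `statistic`
#'   (`|log2 R|`), `n_control`, `n_treated`, and `iterations` (`"exact"`
#'   or the Monte-Carlo count).
#' @examples
#' rt <- randomization_test(c(21, 21.1, 21.3), c(19, 19.2, 19.4),
#'                          refs_control = list(c(18, 18.1, 17.9)),
#'                          refs_treated = list(c(18, 18.2, 18.1)),
#'                          seed = 1)
#' rt$p_value
#' @export
randomization_test <- function(target_control, target_treated,
                               refs_control, refs_treated,
                               e_target = 2, e_refs = 2,
                               iterations = 2000, seed = 1L,
                               exact_limit = 1e5) {
  n1 <- length(target_control); n2 <- length(target_treated)
  if (n1 < 2 && n2 < 2) {
    abort("Randomization p is undefined with both groups of size 1.",
          class = "qpcrstab_size_error")
  }
  e_refs <- rep_len(e_refs, length(refs_control))
  bt <- log2(e_target); br <- log2(e_refs)
  # per-sample normalized log2 expression
  norm_log <- function(target, refs, idx) {
    ref_part <- rowMeans(vapply(seq_along(refs),
                                function(i) br[i] * refs[[i]][idx],
                                numeric(length(idx))))
    -bt * target[idx] + ref_part
  }
  lc <- norm_log(target_control, refs_control, seq_len(n1))
  lt <- norm_log(target_treated, refs_treated, seq_len(n2))
  pooled <- c(lc, lt)
  obs <- abs(mean(lt) - mean(lc))

  n <- n1 + n2
  n_alloc <- choose(n, n1)
  stat_for <- function(ctrl_idx) {
    abs(mean(pooled[-ctrl_idx]) - mean(pooled[ctrl_idx]))
  }
  if (n_alloc <= exact_limit) {
    allocs <- combn(n, n1)
    stats <- apply(allocs, 2, stat_for)
    p <- sum(stats >= obs - 1e-12) / n_alloc
    iters <- "exact"
  } else {
    stats <- with_seed(seed, {
      vapply(seq_len(iterations),
             function(i) stat_for(sample.int(n, n1)), numeric(1))
    })
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + iterations)
    iters <- iterations
  }
  list(p_value = p,
       ratio = 2^(mean(lt) - mean(lc)),
       statistic = obs, n_control = n1, n_treated = n2,
       iterations = iters)
}

#' Regulation call from a ratio and p-value
#'
#' `UR` (up-regulated) when `R > 1` and `p < alpha`; `DR` (down-regulated)
#' when `R < 1` and `p < alpha`; otherwise `ns`.
#'
#' @param ratio Expression ratio(s) R.
#' @param p_value Associated p-value(s).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of `"UR"`, `"DR"`, `"ns"`.
#' @examples
#' regulation_call(c(2.8, 0.9, 0.2), c(0.01, 0.3, 0.001))
#' @export
regulation_call <- function(ratio, p_value, alpha = 0.05) {
  dplyr::case_when(
    p_value < alpha & ratio > 1 ~ "UR",
    p_value < alpha & ratio < 1 ~ "DR",
    TRUE ~ "ns")
}

#' Signed fold change from a ratio
#'
#' Ratios below 1 are reported as negative reciprocal fold changes:
#' `FC = R` when `R >= 1`, else `-1/R`; negative values indicate
#' repression.
#'
#' @param ratio Expression ratio(s), strictly positive.
#' @return Signed fold change(s).
#' @examples
#' fc_from_ratio(c(0.5, 1, 2))   # -2, 1, 2
#' @export
fc_from_ratio <- function(ratio) {
  if (any(ratio <= 0)) {
    abort("Ratios must be strictly positive.",
          class = "qpcrstab_domain_error")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Relative expression of target genes across time points
#'
#' Runs the efficiency-corrected ratio and randomization test for each
#' target gene, accession and stress time point, comparing that time's
#' treated biological replicates against the accession's time-0 controls.
#' Technical replicates are averaged first; the reference-gene
#' normalization factor uses the geometric mean across `references`.
#'
#' @param data A validated long Cq tibble containing the target and
#'   reference genes.
#' @param targets Character vector of target gene names.
#' @param references Character vector of reference gene names.
#' @param efficiencies Efficiency spec as in [cq_to_quantity()].
#' @param alpha Significance level for regulation calls.
#' @param iterations,seed Passed to [randomization_test()].
#' @param collapse_tech Average technical replicates before testing
#'   (default `TRUE`), making biological samples the permutation units.
#'   With three biological replicates per side the exact test then has a
#'   smallest attainable two-sided p of 0.10; set `FALSE` to permute
#'   individual wells instead, which restores resolution at the cost of
#'   treating technical replicates as exchangeable samples.
#' @return A tibble with one row per target x assay x accession x time:
#'   `ratio`, `fold_change`, `p_value`, `call`, replicate counts.
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' rest_analysis(sim$cq, targets = "EF1a",
#'               references = c("UE21D", "UNK", "ACT"))
#' @export
rest_analysis <- function(data, targets, references, efficiencies = 2,
                          alpha = 0.05, iterations = 2000, seed = 1L,
                          collapse_tech = TRUE) {
  data <- validate_cq(data)
  if (collapse_tech) data <- collapse_technical_reps(data)
  missing <- setdiff(c(targets, references), unique(data$gene))
  if (length(missing) > 0) {
    abort(paste0("Gene(s) not in the data: ",
                 paste(missing, collapse = ", ")),
          class = "qpcrstab_input_error")
  }
  grid <- data |>
    dplyr::filter(.data$group == "treated") |>
    dplyr::distinct(.data$assay, .data$accession, .data$time_min)
  out <- purrr::map_dfr(targets, function(tg) {
    purrr::pmap_dfr(grid, function(assay, accession, time_min) {
      ctrl <- data |>
        dplyr::filter(.data$assay == !!assay,
                      .data$accession == !!accession,
                      .data$group == "control")
      trt <- data |>
        dplyr::filter(.data$assay == !!assay,
                      .data$accession == !!accession,
                      .data$group == "treated",
                      .data$time_min == !!time_min)
      cq_of <- function(d, g) {
        d |> dplyr::filter(.data$gene == g) |>
          dplyr::arrange(.data$bio_rep, .data$tech_rep) |>
          dplyr::pull("cq")
      }
      e <- eff_vector(c(tg, references), efficiencies)
      rt <- randomization_test(
        target_control = cq_of(ctrl, tg),
        target_treated = cq_of(trt, tg),
        refs_control = purrr::map(references, ~ cq_of(ctrl, .x)),
        refs_treated = purrr::map(references, ~ cq_of(trt, .x)),
        e_target = e[[tg]], e_refs = unname(e[references]),
        iterations = iterations, seed = seed)
      tibble(gene = tg, assay = assay, accession = accession,
             time_min = time_min, ratio = rt$ratio,
             fold_change = fc_from_ratio(rt$ratio),
             p_value = rt$p_value,
             call = regulation_call(rt$ratio, rt$p_value, alpha),
             n_control = rt$n_control, n_treated = rt$n_treated)
    })
  })
  dplyr::arrange(out, .data$gene, .data$assay, .data$accession,
                 .data$time_min)
}

#' Cross-platform agreement between tag-sequencing and qPCR calls
#'
#' A comparison (one gene in one accession under one assay) is validated
#' when the regulation call from the tag-sequencing libraries matches the
#' qPCR call in at least one time point; `ns` counts as a call.
#'
#' @param ht_call A single call from the sequencing libraries (`"UR"`,
#'   `"DR"` or `"ns"`).
#' @param qpcr_calls Character vector of per-time-point qPCR calls.
#' @return `agreement()` returns a logical scalar.
#' @examples
#' agreement("UR", c("ns", "ns", "UR"))   # TRUE
#' agreement("UR", c("DR", "DR", "ns"))   # FALSE
#' @export
agreement <- function(ht_call, qpcr_calls) {
  valid <- c("UR", "DR", "ns")
  if (length(qpcr_calls) == 0) {
    abort("Empty qPCR call list.", class = "qpcrstab_input_error")
  }
  if (!ht_call %in% valid || !all(qpcr_calls %in% valid)) {
    abort("Calls must be 'UR', 'DR' or 'ns'.",
          class = "qpcrstab_input_error")
  }
  any(qpcr_calls == ht_call)
}

#' @rdname agreement
#' @param calls A data frame with one row per comparison x time point:
#'   columns `gene`, `assay`, `accession`, `ht_call`, `qpcr_call` (and
#'   optionally `time_min`).
#' @return `summarize_agreement()` returns a list with `comparisons` (one
#'   row per comparison with `validated`), `n`, `n_validated` and
#'   `pct_validated` (rounded to the nearest integer percent).
#' @examples
#' summarize_agreement(cowpea_expression_calls())$pct_validated   # 56
#' @export
summarize_agreement <- function(calls) {
  calls <- as_tibble(calls)
  comparisons <- calls |>
    dplyr::group_by(.data$gene, .data$assay, .data$accession) |>
    dplyr::summarise(
      ht_call = unique(.data$ht_call),
      validated = agreement(unique(.data$ht_call), .data$qpcr_call),
      .groups = "drop")
  list(comparisons = comparisons,
       n = nrow(comparisons),
       n_validated = sum(comparisons$validated),
       pct_validated = round(100 * mean(comparisons$validated)))
}

#' Published cowpea tag-sequencing and qPCR regulation calls
#'
#' The printed per-comparison regulation calls for the four cowpea target
#' transcripts in four accessions under two stresses: the call from the
#' HT-SuperSAGE libraries and the qPCR call at each of three stress time
#' points.  Input data for the cross-platform agreement rule.
#'
#' @return A long tibble: `gene`, `assay`, `accession`, `tolerance`,
#'   `ht_call`, `time_min`, `qpcr_call`.
#' @examples
#' summarize_agreement(cowpea_expression_calls())
#' @export
cowpea_expression_calls <- function() {
  path <- system.file("extdata", "cowpea_expression_calls.csv",
                      package = "qpcrstab", mustWork = TRUE)
  readr::read_csv(path, col_types = "cccccic", progress = FALSE)
}
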