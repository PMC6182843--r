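#' End-to-end reference-gene selection and expression pipeline
#'
#' Orchestrates the full analysis: standard-curve calibration, the Cq
#' dispersion screen, the four stability methods, the cross-method
#' consensus, and (when target genes are named) efficiency-corrected
#' relative expression with regulation calls.  Each stage's table is
#' written under `out_dir` as CSV (plus a JSON summary), and the stage
#' results are returned invisibly as a list.  With a fixed `seed` the run
#' is fully deterministic.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   * `cq`: path to a long Cq CSV (see [read_cq_table()]) or a data
#'     frame; if omitted, the bundled synthetic preset
#'     ([cq_sim_config()]) is simulated with `seed`;
#'   * `curves`: optional dilution-series table (or CSV path) with
#'     `gene`, `log10_conc`, `cq` — fitted efficiencies are then used in
#'     every downstream stage (genes without a curve fall back to 2.0);
#'   * `methods`: subset of `c("genorm", "normfinder", "bestkeeper",
#'     "deltact")` (default all);
#'   * `targets`: optional character vector of target genes for the
#'     expression stage;
#'   * `references`: reference genes for the expression stage (default:
#'     the consensus-selected set);
#'   * `alpha` (default 0.05), `cutoff` (geNorm V cutoff, 0.15),
#'     `sd_threshold` (dispersion screen, 1), `n_select` (3),
#'     `iterations` (2000), `seed` (1).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the per-stage results (`calibration`,
#'   `screen`, `stability`, `consensus`, `expression`) and the resolved
#'   configuration.
#' @examples
#' res <- run_pipeline(list(seed = 1), out_dir = tempfile())
#' res$consensus$selected
#' @export
run_pipeline <- function(config = list(), out_dir = "qpcrstab-output") {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(methods = c("genorm", "normfinder", "bestkeeper",
                               "deltact"),
                   alpha = 0.05, cutoff = 0.15, sd_threshold = 1,
                   n_select = 3, iterations = 2000, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$cutoff > 0)
  unknown <- setdiff(cfg$methods, defaults$methods)
  if (length(unknown) > 0) {
    abort(paste0("Unknown method(s): ", paste(unknown, collapse = ", ")),
          class = "qpcrstab_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = cfg)

  # --- input data -------------------------------------------------------
  cq <- if (is.null(cfg$cq)) {
    simulate_cq(cq_sim_config(seed = cfg$seed))$cq
  } else if (is.character(cfg$cq)) {
    read_cq_table(cfg$cq)
  } else {
    validate_cq(cfg$cq)
  }

  # --- calibration ------------------------------------------------------
  efficiencies <- 2
  if (!is.null(cfg$curves)) {
    pts <- if (is.character(cfg$curves)) {
      readr::read_csv(cfg$curves, show_col_types = FALSE)
    } else as_tibble(cfg$curves)
    curves <- fit_standard_curve(pts)
    all_genes <- unique(cq$gene)
    eff_tbl <- tibble(gene = all_genes) |>
      dplyr::left_join(curves[, c("gene", "efficiency_base")],
                       by = "gene") |>
      dplyr::mutate(efficiency_base =
                      dplyr::coalesce(.data$efficiency_base, 2))
    efficiencies <- eff_tbl
    out$calibration <- curves
    readr::write_csv(curves, file.path(out_dir, "standard_curves.csv"))
  }

  # --- dispersion screen ------------------------------------------------
  candidates <- setdiff(unique(cq$gene), cfg$targets)
  cq_cand <- dplyr::filter(cq, .data$gene %in% candidates)
  screen <- cq_dispersion(cq_cand, sd_threshold = cfg$sd_threshold)
  out$screen <- screen
  readr::write_csv(screen, file.path(out_dir, "dispersion_screen.csv"))

  # --- stability methods ------------------------------------------------
  fits <- list()
  if ("genorm" %in% cfg$methods) {
    fits$genorm <- genorm(cq_cand, efficiencies, cutoff = cfg$cutoff)
  }
  if ("normfinder" %in% cfg$methods) {
    fits$normfinder <- normfinder(cq_cand, efficiencies = efficiencies)
  }
  if ("bestkeeper" %in% cfg$methods) {
    fits$bestkeeper <- bestkeeper(cq_cand, efficiencies)
  }
  if ("deltact" %in% cfg$methods) {
    fits$deltact <- delta_ct(cq_cand)
  }
  out$stability <- fits
  for (nm in names(fits)) {
    readr::write_csv(tidy(fits[[nm]]),
                     file.path(out_dir, paste0("stability_", nm, ".csv")))
  }

  # --- consensus --------------------------------------------------------
  consensus <- build_consensus(fits, n_select = cfg$n_select,
                               anchor = if ("genorm" %in% names(fits))
                                 "genorm" else NULL)
  out$consensus <- consensus
  readr::write_csv(tidy(consensus),
                   file.path(out_dir, "consensus_ranks.csv"))

  # --- expression calls -------------------------------------------------
  if (!is.null(cfg$targets)) {
    refs <- cfg$references %||% consensus$selected
    expr <- rest_analysis(cq, targets = cfg$targets, references = refs,
                          efficiencies = efficiencies, alpha = cfg$alpha,
                          iterations = cfg$iterations, seed = cfg$seed)
    out$expression <- expr
    readr::write_csv(expr, file.path(out_dir, "relative_expression.csv"))
  }

  summary <- list(
    seed = cfg$seed,
    n_samples = length(unique(cq$sample_id)),
    n_candidate_genes = length(candidates),
    genes_passing_screen = screen$gene[screen$passes_screen],
    selected_reference_set = consensus$selected,
    optimal_n_genorm = if (!is.null(fits$genorm))
      fits$genorm$optimal_n else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
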