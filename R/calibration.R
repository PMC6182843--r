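#' Amplification efficiency from a standard-curve slope
#'
#' The per-cycle amplification base is derived from the slope of the
#' dilution-series regression of Cq on log10 template concentration as
#' `E = 10^(-1/slope)`; a slope of -3.32 corresponds to perfect doubling
#' (E = 2, 100%).
#'
#' @param slope Standard-curve slope(s), cycles per log10 dilution; must be
#'   negative.
#' @return A tibble with columns `slope`, `efficiency_base` (e.g. 2.03) and
#'   `efficiency_pct` (`(E - 1) * 100`).
#' @examples
#' efficiency_from_slope(-3.25)   # 103.09 %
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) {
    abort("Standard-curve slopes must be negative.",
          class = "qpcrstab_domain_error")
  }
  e <- 10^(-1 / slope)
  tibble(slope = slope, efficiency_base = e,
         efficiency_pct = (e - 1) * 100)
}

#' @rdname efficiency_from_slope
#' @param efficiency_pct Efficiency in percent.
#' @return `slope_from_efficiency()` returns the (negative) slope.
#' @export
slope_from_efficiency <- function(efficiency_pct) {
  -1 / log10(1 + efficiency_pct / 100)
}

#' Fit serial-dilution standard curves
#'
#' Ordinary least-squares regression of Cq on log10 relative concentration,
#' per gene, with the derived amplification efficiency and the slope
#' acceptance window.  `r_squared` is the squared Pearson correlation of Cq
#' versus log10 concentration; because the dilution line falls, the raw
#' correlation is negative and its sign is reported separately in `r_sign`.
#'
#' @param data Data frame with columns `log10_conc` and `cq`, and
#'   optionally `gene` (one curve is fitted per gene).
#' @param slope_window Inclusive acceptable slope range, cycles per log10
#'   dilution.  The default -3.58 to -3.10 corresponds to efficiencies of
#'   roughly 90–110%.
#' @return A tibble with one row per gene: `gene`, `n_points`, `slope`,
#'   `y_intercept`, `r_squared`, `r_sign`, `efficiency_base`,
#'   `efficiency_pct`, `acceptable`, `reason`.
#' @examples
#' pts <- simulate_dilution_series(efficiency_pct = 100, intercept = 35)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(data, slope_window = c(-3.58, -3.10)) {
  data <- as_tibble(data)
  stopifnot(all(c("log10_conc", "cq") %in% names(data)))
  if (!"gene" %in% names(data)) data$gene <- "gene1"
  fit_one <- function(d, gene) {
    if (nrow(d) < 3) {
      abort("A standard curve needs at least 3 points.",
            class = "qpcrstab_design_error")
    }
    if (length(unique(d$log10_conc)) < 2) {
      abort("Degenerate dilution design: all concentrations identical.",
            class = "qpcrstab_design_error")
    }
    fit <- lm(cq ~ log10_conc, data = d)
    slope <- unname(coef(fit)[2])
    r <- cor(d$log10_conc, d$cq)
    eff <- if (slope < 0) efficiency_from_slope(slope) else
      tibble(efficiency_base = NA_real_, efficiency_pct = NA_real_)
    tibble(gene = gene, n_points = nrow(d), slope = slope,
           y_intercept = unname(coef(fit)[1]),
           r_squared = r^2, r_sign = sign(r),
           efficiency_base = eff$efficiency_base,
           efficiency_pct = eff$efficiency_pct)
  }
  curves <- purrr::map_dfr(split(data, data$gene)[unique(data$gene)],
                           ~ fit_one(.x, .x$gene[1]))
  check_acceptance(curves, slope_window)
}

#' Apply the slope acceptance window
#'
#' A fitted curve is acceptable when its slope lies inside the (inclusive)
#' window; the window on the slope is the operative rule, and the
#' corresponding efficiency range (90.3–110.2% for the default window) is
#' only a gloss.
#'
#' @param curves A tibble of fitted curves with a `slope` column (as
#'   returned by [fit_standard_curve()]).
#' @param slope_window Inclusive acceptable slope range.
#' @return The input with `acceptable` (logical) and `reason` (why a curve
#'   failed, `NA` when acceptable) columns added or replaced.
#' @examples
#' check_acceptance(tibble::tibble(slope = c(-3.25, -3.59, -3.05)))
#' @export
check_acceptance <- function(curves, slope_window = c(-3.58, -3.10)) {
  curves <- as_tibble(curves)
  lo <- min(slope_window); hi <- max(slope_window)
  curves |>
    dplyr::mutate(
      acceptable = .data$slope >= lo & .data$slope <= hi,
      reason = dplyr::case_when(
        .data$slope < lo ~ "slope too steep: efficiency below window",
        .data$slope > hi ~ "slope too shallow: efficiency above window",
        TRUE ~ NA_character_))
}

#' Published cowpea primer-pair standard-curve characteristics
#'
#' The printed standard-curve characterization of the eleven cowpea
#' primer pairs (seven candidate reference genes, four target
#' transcripts): slope magnitude, efficiency (%), regression coefficient
#' and y-intercept.  Shipped as plain CSV in `extdata`; used as the input
#' for the efficiency-arithmetic checks.
#'
#' @return A tibble with columns `category` (`CRG` or `TT`), `gene`,
#'   `slope_magnitude`, `efficiency_pct`, `r_squared_printed`,
#'   `y_intercept`.
#' @examples
#' cowpea_primer_slopes()
#' @export
cowpea_primer_slopes <- function() {
  path <- system.file("extdata", "cowpea_primer_slopes.csv",
                      package = "qpcrstab", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccdddd", progress = FALSE)
}
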