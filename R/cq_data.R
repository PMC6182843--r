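#' Long-format Cq tables
#'
#' The canonical container throughout the package is a *long* (tidy) tibble
#' of quantification-cycle (Cq) measurements, one row per well, with the
#' columns:
#'
#' * `sample_id` — unique identifier of the well-level sample,
#' * `assay` — `"root_dehydration"` or `"salt"`,
#' * `accession` — plant accession / cultivar label,
#' * `group` — `"control"` or `"treated"`,
#' * `time_min` — minutes of stress exposure (0 for controls),
#' * `bio_rep`, `tech_rep` — positive integer replicate indices,
#' * `gene` — gene / primer-pair identifier,
#' * `cq` — quantification cycle (typically 10–40; `NA` for failed wells).
#'
#' `validate_cq()` checks a data frame against this contract and returns it
#' as a tibble (invisibly unchanged apart from column coercion).
#'
#' @param data A data frame with the columns listed above.
#' @return `validate_cq()` returns the validated tibble.
#' @examples
#' cq <- simulate_cq(cq_sim_config(seed = 1))$cq
#' validate_cq(cq)
#' @export
validate_cq <- function(data) {
  required <- c("sample_id", "assay", "accession", "group", "time_min",
                "bio_rep", "tech_rep", "gene", "cq")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Cq table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "qpcrstab_format_error")
  }
  data <- as_tibble(data)
  data$time_min <- as.integer(data$time_min)
  data$bio_rep  <- as.integer(data$bio_rep)
  data$tech_rep <- as.integer(data$tech_rep)
  data$cq       <- as.numeric(data$cq)

  bad_group <- setdiff(unique(data$group), c("control", "treated"))
  if (length(bad_group) > 0) {
    abort(paste0("`group` must be 'control' or 'treated'; found: ",
                 paste(bad_group, collapse = ", ")),
          class = "qpcrstab_data_error")
  }
  if (any(data$time_min < 0, na.rm = TRUE)) {
    abort("`time_min` must be non-negative.", class = "qpcrstab_data_error")
  }
  if (any(is.infinite(data$cq))) {
    abort("Cq values must be finite where present.",
          class = "qpcrstab_data_error")
  }

  dup <- data |>
    dplyr::count(.data$sample_id, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- paste0("(", dup$sample_id, ", ", dup$gene, ")")
    abort(paste0("Duplicate (sample, gene) rows: ",
                 paste(head(keys, 5), collapse = "; "),
                 if (nrow(dup) > 5) " ..."),
          class = "qpcrstab_data_error")
  }

  # one sample_id must map to a single metadata tuple
  meta <- dplyr::distinct(data, .data$sample_id, .data$assay,
                          .data$accession, .data$group, .data$time_min,
                          .data$bio_rep, .data$tech_rep)
  if (anyDuplicated(meta$sample_id) > 0) {
    abort("`sample_id` maps to more than one metadata combination.",
          class = "qpcrstab_data_error")
  }
  invisible(data)
}

#' Read and write long-format Cq tables
#'
#' `read_cq_table()` reads a delimited text file into the validated long Cq
#' format (see [validate_cq()]).  Rows whose `cq` field cannot be parsed as
#' a number are dropped and reported; pass `report` to persist the
#' rejection report as JSON.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma; use `"\t"` for TSV).
#' @param report Optional path to write a JSON validation report.
#' @return A validated tibble of Cq measurements.  Rejected rows (if any)
#'   are attached as the `"rejected"` attribute.
#' @examples
#' cq <- simulate_cq(cq_sim_config(seed = 1))$cq
#' f <- tempfile(fileext = ".csv")
#' write_cq_table(cq, f)
#' identical_cq <- read_cq_table(f)
#' @export
read_cq_table <- function(path, sep = ",", report = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "qpcrstab_format_error")
  }
  header <- names(readr::read_delim(
    path, delim = sep, n_max = 0,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  missing_cols <- setdiff(c("sample_id", "assay", "accession", "group",
                            "time_min", "bio_rep", "tech_rep", "gene", "cq"),
                          header)
  if (length(missing_cols) > 0) {
    abort(paste0("Cq table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "qpcrstab_format_error")
  }
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(
    sample_id = readr::col_character(),
    assay = readr::col_character(),
    accession = readr::col_character(),
    group = readr::col_character(),
    time_min = readr::col_integer(),
    bio_rep = readr::col_integer(),
    tech_rep = readr::col_integer(),
    gene = readr::col_character(),
    cq = readr::col_character()
  ), progress = FALSE)
  cq_num <- suppressWarnings(as.numeric(raw$cq))
  unparseable <- !is.na(raw$cq) & raw$cq != "" & is.na(cq_num)
  rejected <- raw[unparseable, ]
  raw$cq <- cq_num
  out <- validate_cq(raw[!unparseable, ])
  if (nrow(rejected) > 0) {
    warn(paste0(nrow(rejected), " row(s) with unparseable Cq were rejected."))
  }
  if (!is.null(report)) {
    jsonlite::write_json(
      list(path = path, n_read = nrow(raw), n_kept = nrow(out),
           n_rejected = nrow(rejected), rejected = rejected),
      report, auto_unbox = TRUE, digits = NA)
  }
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_cq_table
#' @param data A validated long Cq tibble.
#' @export
write_cq_table <- function(data, path, sep = ",") {
  data <- validate_cq(data)
  readr::write_delim(data, path, delim = sep)
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses technical replicates to their arithmetic mean Cq, leaving one
#' row per biological replicate and gene.  Missing wells are ignored; a
#' triplet that is entirely missing stays missing.  Biological replicates
#' are never averaged: the stability statistics need biological variation.
#'
#' @param data A validated long Cq tibble.
#' @return A tibble in the same format with `tech_rep` set to 1 and
#'   `sample_id` taken as the lexicographically first id of each collapsed
#'   set of wells.
#' @examples
#' cq <- simulate_cq(cq_sim_config(seed = 1))$cq
#' collapse_technical_reps(cq)
#' @export
collapse_technical_reps <- function(data) {
  data <- validate_cq(data)
  data |>
    dplyr::group_by(.data$assay, .data$accession, .data$group,
                    .data$time_min, .data$bio_rep, .data$gene) |>
    dplyr::summarise(
      sample_id = min(.data$sample_id),
      cq = if (all(is.na(.data$cq))) NA_real_ else
        mean(.data$cq, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(tech_rep = 1L) |>
    dplyr::select("sample_id", "assay", "accession", "group", "time_min",
                  "bio_rep", "tech_rep", "gene", "cq") |>
    dplyr::arrange(.data$assay, .data$accession, .data$group,
                   .data$time_min, .data$bio_rep, .data$gene)
}

#' Cq dispersion screen
#'
#' Per-gene coefficient of variation and standard deviation of Cq values,
#' with the screening rule used to triage candidate reference genes: a gene
#' passes when its Cq standard deviation is below `sd_threshold` cycles
#' (default 1).
#'
#' @param data A validated long Cq tibble (one assay or several; statistics
#'   are computed within assay).
#' @param sd_threshold Screening threshold on the Cq SD, in cycles.
#' @param use_tech_means Average technical replicates before computing the
#'   dispersion (default `FALSE`: all wells enter the SD).
#' @return A tibble with columns `assay`, `gene`, `n`, `mean_cq`, `sd`,
#'   `cv_pct` and `passes_screen`.  Genes with fewer than two observations
#'   are dropped with a warning.
#' @examples
#' cq <- simulate_cq(cq_sim_config(seed = 1))$cq
#' cq_dispersion(cq)
#' @export
cq_dispersion <- function(data, sd_threshold = 1.0, use_tech_means = FALSE) {
  data <- validate_cq(data)
  if (use_tech_means) data <- collapse_technical_reps(data)
  out <- data |>
    dplyr::filter(!is.na(.data$cq)) |>
    dplyr::group_by(.data$assay, .data$gene) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_cq = mean(.data$cq),
                     sd = sd(.data$cq),
                     .groups = "drop") |>
    dplyr::mutate(cv_pct = 100 * .data$sd / .data$mean_cq,
                  passes_screen = .data$sd < sd_threshold)
  few <- out$n < 2
  if (any(few)) {
    warn(paste0("Excluding gene(s) with <2 observations: ",
                paste(unique(out$gene[few]), collapse = ", ")))
    out <- out[!few, ]
  }
  out
}

# Internal: collapsed long table -> complete-case genes x samples matrix.
# Samples missing any gene are dropped (the stability methods assume a
# complete matrix); the number dropped is reported via inform().
cq_matrix <- function(data, quiet = FALSE) {
  data <- validate_cq(data)
  if (length(unique(data$tech_rep)) > 1) data <- collapse_technical_reps(data)
  wide <- data |>
    dplyr::select("sample_id", "gene", "cq") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  complete <- colSums(is.na(m)) == 0
  if (!all(complete) && !quiet) {
    inform(paste0("Dropping ", sum(!complete),
                  " sample(s) with missing Cq (complete-case analysis)."))
  }
  m <- m[, complete, drop = FALSE]
  if (any(colSums(!is.na(m)) == 0)) {
    abort("A retained sample has no non-missing Cq.",
          class = "qpcrstab_data_error")
  }
  m
}

# Internal: sample metadata for the columns of cq_matrix(data)
cq_sample_meta <- function(data) {
  data <- validate_cq(data)
  if (length(unique(data$tech_rep)) > 1) data <- collapse_technical_reps(data)
  dplyr::distinct(data, .data$sample_id, .data$assay, .data$accession,
                  .data$group, .data$time_min, .data$bio_rep)
}
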