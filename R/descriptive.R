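#' BestKeeper descriptive statistics and index correlations
#'
#' Computes, on the raw Cq scale, the BestKeeper-style descriptive
#' statistics per candidate gene (geometric and arithmetic mean, extreme
#' values, dispersion, coefficient of variation), the x-fold expression
#' deviations implied by each gene's amplification efficiency, and the
#' Pearson correlation of each gene with the BestKeeper index (the
#' per-sample geometric mean of all candidates' Cq values).  Genes whose
#' Cq dispersion exceeds 1 cycle are flagged inconsistent.
#'
#' X-fold deviations are `E^(|Cq* - GM|)` for an extreme value `Cq*`,
#' signed negative when `Cq* < GM` (expression above the panel-typical
#' level); `SD [x-fold]` is `E^SD`.
#'
#' @inheritParams cq_to_quantity
#' @param sd_mode Dispersion statistic: `"sample_sd"` (ddof-1 SD about the
#'   arithmetic mean, default) or `"mad"` (mean absolute deviation about
#'   the arithmetic mean, as in the original spreadsheet tool).
#' @return An object of class `"bestkeeper"`: list with `stats` (one row
#'   per gene), `index` (per-sample index values) and `ranking` (from
#'   [rank_bestkeeper()]).
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' bk <- bestkeeper(sim$cq)
#' tidy(bk)
#' @export
bestkeeper <- function(data, efficiencies = 2,
                       sd_mode = c("sample_sd", "mad")) {
  sd_mode <- match.arg(sd_mode)
  m <- if (is.matrix(data)) data else cq_matrix(data)
  genes <- rownames(m)
  if (length(genes) < 2) {
    warn("BestKeeper index of a single-gene panel is that gene's Cq.")
  }
  if (length(genes) > 10) {
    warn("BestKeeper is intended for panels of up to 10 candidate genes.")
  }
  if (any(m <= 0)) {
    abort("Cq values must be positive (geometric mean undefined).",
          class = "qpcrstab_domain_error")
  }
  e <- eff_vector(genes, efficiencies)
  index <- apply(m, 2, geomean)
  n <- ncol(m)

  stats <- purrr::map_dfr(genes, function(gn) {
    cq <- m[gn, ]
    am <- mean(cq); gm <- geomean(cq)
    disp <- if (sd_mode == "sample_sd") sd0(cq) else mean(abs(cq - am))
    r <- if (n >= 3 && sd0(cq) > 0 && sd0(index) > 0) {
      cor(cq, index)
    } else NA_real_
    p <- if (!is.na(r) && abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = n - 2)
    } else if (!is.na(r)) 0 else NA_real_
    xfold <- function(cqstar) {
      if (cqstar < gm) -e[[gn]]^(gm - cqstar) else e[[gn]]^(cqstar - gm)
    }
    tibble(gene = gn, n = n, gm = gm, am = am,
           min = min(cq), max = max(cq),
           sd = disp, cv_pct = 100 * disp / am,
           xfold_min = xfold(min(cq)), xfold_max = xfold(max(cq)),
           xfold_sd = e[[gn]]^disp,
           r_index = r,
           p_value = if (is.na(p)) NA_real_ else max(p, 0.001),
           inconsistent = disp > 1)
  })
  ranking <- rank_bestkeeper(stats)
  structure(list(stats = stats,
                 index = tibble(sample_id = colnames(m),
                                index = unname(index)),
                 ranking = ranking),
            class = "bestkeeper")
}

#' Rank genes by correlation with the BestKeeper index
#'
#' Genes are ranked by descending Pearson correlation with the index; the
#' most correlated gene is the most stable.  Inconsistent genes (Cq
#' dispersion above 1 cycle) are flagged and by default demoted below all
#' consistent genes regardless of their correlation.
#'
#' @param stats The per-gene statistics tibble from [bestkeeper()].
#' @param demote_inconsistent Demote flagged genes to the bottom (default
#'   `TRUE`).
#' @return A tibble `gene`, `r_index`, `inconsistent`, `rank`.
#' @export
rank_bestkeeper <- function(stats, demote_inconsistent = TRUE) {
  key <- -stats$r_index
  if (demote_inconsistent) key <- key + ifelse(stats$inconsistent, 1e6, 0)
  ord <- order(key)
  if (anyDuplicated(stats$r_index[!is.na(stats$r_index)]) > 0) {
    warn("Tied index correlations; tied genes keep input order.")
  }
  tibble(gene = stats$gene[ord],
         r_index = stats$r_index[ord],
         inconsistent = stats$inconsistent[ord],
         rank = seq_along(ord))
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper descriptive statistics\n")
  print(x$stats)
  cat("\nRanking by correlation with the index:\n")
  print(x$ranking)
  invisible(x)
}

#' @rdname bestkeeper
#' @param x,object A `bestkeeper` object.
#' @param ... Unused.
#' @export
tidy.bestkeeper <- function(x, ...) x$stats

#' @rdname bestkeeper
#' @export
glance.bestkeeper <- function(x, ...) {
  tibble(n_genes = nrow(x$stats),
         n_samples = x$stats$n[1],
         best_gene = x$ranking$gene[1],
         best_r = x$ranking$r_index[1],
         n_inconsistent = sum(x$stats$inconsistent))
}

#' @rdname bestkeeper
#' @export
autoplot.bestkeeper <- function(object, ...) {
  d <- object$ranking |>
    dplyr::mutate(gene = factor(.data$gene, levels = .data$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$r_index,
                                  fill = .data$inconsistent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Pearson r with BestKeeper index") +
    ggplot2::theme_minimal()
}

#' Comparative delta-Ct stability method
#'
#' Compares all pairwise combinations of candidate genes: for each pair,
#' the per-sample Cq difference is formed and its ddof-1 standard deviation
#' over samples recorded; a gene's stability score is its mean pairwise SD
#' (lower = more stable).  Because only between-gene differences enter,
#' the statistic is invariant both to per-gene additive Cq shifts and to
#' shared per-sample loading shifts.
#'
#' @inheritParams cq_to_quantity
#' @return An object of class `"delta_ct"`: list with `pair_sd` (symmetric
#'   genes-by-genes matrix) and `ranking` (tibble `gene`, `mean_sd`,
#'   `rank`).
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' tidy(delta_ct(sim$cq))
#' @export
delta_ct <- function(data) {
  m <- if (is.matrix(data)) data else cq_matrix(data)
  if (nrow(m) < 3) {
    abort("The delta-Ct method needs at least 3 genes.",
          class = "qpcrstab_size_error")
  }
  if (ncol(m) < 2) {
    abort("The delta-Ct method needs at least 2 samples.",
          class = "qpcrstab_size_error")
  }
  g <- nrow(m)
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      pair_sd[j, k] <- pair_sd[k, j] <- sd(m[j, ] - m[k, ])
    }
  }
  mean_sd <- rowSums(pair_sd) / (g - 1)
  ord <- order(mean_sd)
  ranking <- tibble(gene = rownames(m)[ord],
                    mean_sd = unname(mean_sd[ord]),
                    rank = seq_along(ord))
  structure(list(pair_sd = pair_sd, ranking = ranking), class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, ...) {
  cat("Comparative delta-Ct stability (lower mean SD = more stable)\n")
  print(x$ranking)
  invisible(x)
}

#' @rdname delta_ct
#' @param x,object A `delta_ct` object.
#' @param ... Unused.
#' @export
tidy.delta_ct <- function(x, ...) x$ranking

#' @rdname delta_ct
#' @export
glance.delta_ct <- function(x, ...) {
  tibble(n_genes = nrow(x$ranking),
         best_gene = x$ranking$gene[1],
         best_mean_sd = x$ranking$mean_sd[1])
}

#' @rdname delta_ct
#' @export
autoplot.delta_ct <- function(object, ...) {
  d <- object$ranking |>
    dplyr::mutate(gene = factor(.data$gene, levels = .data$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$mean_sd)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean pairwise SD of delta-Ct (cycles)") +
    ggplot2::theme_minimal()
}
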