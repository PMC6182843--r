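#' Convert Cq values to relative quantities
#'
#' The stability statistics that work on the linear scale use relative
#' quantities `Q = E^(minCq - Cq)`, calibrated per gene so that the sample
#' with the lowest Cq (highest expression) has `Q = 1`.
#'
#' @param data A long Cq tibble (technical replicates are collapsed and
#'   incomplete samples dropped) or a genes-by-samples numeric matrix.
#' @param efficiencies Amplification base per gene: a single number
#'   (default 2, perfect doubling), a named numeric vector, or a data frame
#'   with columns `gene` and `efficiency_base` (e.g. from
#'   [fit_standard_curve()]).
#' @return A genes-by-samples matrix of relative quantities in (0, 1].
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' q <- cq_to_quantity(sim$cq)
#' apply(q, 1, max)   # 1 for every gene
#' @export
cq_to_quantity <- function(data, efficiencies = 2) {
  m <- if (is.matrix(data)) data else cq_matrix(data)
  e <- eff_vector(rownames(m), efficiencies)
  q <- e^(apply(m, 1, min) - m)
  dimnames(q) <- dimnames(m)
  q
}

# Resolve an efficiency spec into a named per-gene vector of bases
eff_vector <- function(genes, efficiencies) {
  if (is.data.frame(efficiencies)) {
    if (!all(c("gene", "efficiency_base") %in% names(efficiencies))) {
      abort("Efficiency table needs columns `gene` and `efficiency_base`.",
            class = "qpcrstab_config_error")
    }
    e <- setNames(efficiencies$efficiency_base, efficiencies$gene)
    missing <- setdiff(genes, names(e))
    if (length(missing) > 0) {
      abort(paste0("No efficiency for gene(s): ",
                   paste(missing, collapse = ", ")),
            class = "qpcrstab_config_error")
    }
    return(e[genes])
  }
  if (length(efficiencies) == 1 && is.null(names(efficiencies))) {
    return(setNames(rep(as.numeric(efficiencies), length(genes)), genes))
  }
  missing <- setdiff(genes, names(efficiencies))
  if (length(missing) > 0) {
    abort(paste0("No efficiency for gene(s): ",
                 paste(missing, collapse = ", ")),
          class = "qpcrstab_config_error")
  }
  efficiencies[genes]
}

#' Pairwise variation matrix of log-ratios
#'
#' For each gene pair (j, k), the sample standard deviation over samples of
#' `log2(Q_j / Q_k)`.  Two perfectly proportional genes have pairwise
#' variation 0; the statistic is invariant to per-gene multiplicative
#' scaling of the quantities (equivalently per-gene additive Cq shifts).
#'
#' @param q A genes-by-samples quantity matrix from [cq_to_quantity()]
#'   (strictly positive).
#' @return A symmetric genes-by-genes matrix with zero diagonal.
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' pairwise_variation_matrix(cq_to_quantity(sim$cq))
#' @export
pairwise_variation_matrix <- function(q) {
  if (nrow(q) < 2 || ncol(q) < 2) {
    abort("Need at least 2 genes and 2 samples.",
          class = "qpcrstab_size_error")
  }
  if (any(q <= 0)) {
    abort("Quantities must be strictly positive to take log-ratios.",
          class = "qpcrstab_domain_error")
  }
  lq <- log2(q)
  g <- nrow(lq)
  v <- matrix(0, g, g, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      v[j, k] <- v[k, j] <- sd(lq[j, ] - lq[k, ])
    }
  }
  v
}

#' geNorm stability ranking
#'
#' Computes the geNorm expression-stability value M for each candidate
#' reference gene (the mean pairwise variation of that gene against all
#' others), ranks genes by stepwise exclusion of the gene with the highest
#' M, and evaluates the pairwise-variation series `V_n/n+1` between
#' normalization factors built from the n and n+1 most stable genes to
#' decide how many reference genes are needed.
#'
#' The two last surviving genes form an unordered most-stable pair: the
#' method works on gene ratios and cannot separate them.  In rankings they
#' share rank 1.5.
#'
#' @inheritParams cq_to_quantity
#' @param cutoff Threshold on `V_n/n+1` below which adding an (n+1)-th
#'   reference gene is unnecessary (conventional value 0.15).
#' @return An object of class `"genorm"`: a list with `ranking` (tibble
#'   `gene`, `rank`, `m`: the gene's M value in the round it was excluded),
#'   `m_table` (M per remaining gene per round), `exclusion_order`,
#'   `final_pair`, `v_series` (tibble `n`, `v`), `optimal_n`,
#'   `cutoff_met`, `cutoff`.
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' gn <- genorm(sim$cq)
#' tidy(gn)
#' glance(gn)
#' @export
genorm <- function(data, efficiencies = 2, cutoff = 0.15) {
  q <- cq_to_quantity(data, efficiencies)
  genes <- rownames(q)
  g <- length(genes)
  if (g < 3) {
    abort("geNorm needs at least 3 candidate genes.",
          class = "qpcrstab_size_error")
  }
  v <- pairwise_variation_matrix(q)

  remaining <- genes
  exclusion_order <- character(0)
  m_rows <- list()
  m_at_exclusion <- numeric(0)
  round_i <- 1L
  while (length(remaining) > 2) {
    vr <- v[remaining, remaining, drop = FALSE]
    m <- rowSums(vr) / (length(remaining) - 1)
    m_rows[[round_i]] <- tibble(round = round_i, gene = remaining, m = m)
    worst <- which(m == max(m))
    if (length(worst) > 1) {
      warn(paste0("Tie in highest M; excluding the first in input order: ",
                  remaining[worst[1]]))
    }
    worst <- worst[1]
    exclusion_order <- c(exclusion_order, remaining[worst])
    m_at_exclusion <- c(m_at_exclusion, m[worst])
    remaining <- remaining[-worst]
    round_i <- round_i + 1L
  }
  vr <- v[remaining, remaining, drop = FALSE]
  m_final <- rowSums(vr) / (length(remaining) - 1)
  m_rows[[round_i]] <- tibble(round = round_i, gene = remaining, m = m_final)
  m_table <- dplyr::bind_rows(m_rows)

  # stability order, best first; the final pair in input-panel order
  stability_order <- c(remaining, rev(exclusion_order))
  ranks <- c(1.5, 1.5, seq(3, g, length.out = max(g - 2, 0)))
  ranking <- tibble(gene = stability_order,
                    rank = ranks[seq_len(g)],
                    m = c(m_final[remaining], rev(m_at_exclusion)))

  # V_n/n+1 along the stability ranking
  lq <- log2(q)
  v_series <- tibble(n = integer(0), v = numeric(0))
  for (n in 2:(g - 1)) {
    nf_n  <- colMeans(lq[stability_order[seq_len(n)], , drop = FALSE])
    nf_n1 <- colMeans(lq[stability_order[seq_len(n + 1)], , drop = FALSE])
    v_series <- dplyr::bind_rows(v_series,
                                 tibble(n = n, v = sd(nf_n - nf_n1)))
  }
  below <- which(v_series$v < cutoff)
  cutoff_met <- length(below) > 0
  optimal_n <- if (cutoff_met) v_series$n[below[1]] else g

  structure(list(ranking = ranking, m_table = m_table,
                 exclusion_order = exclusion_order,
                 final_pair = sort(remaining), v_series = v_series,
                 optimal_n = optimal_n, cutoff_met = cutoff_met,
                 cutoff = cutoff),
            class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability ranking (lower M = more stable)\n")
  cat("Most stable pair (unordered):",
      paste(x$final_pair, collapse = " / "), "\n")
  print(x$ranking)
  cat("Optimal number of reference genes:", x$optimal_n,
      if (x$cutoff_met) paste0("(V below cutoff ", x$cutoff, ")")
      else "(cutoff never met)", "\n")
  invisible(x)
}

#' @rdname genorm
#' @param x A `genorm` object.
#' @param ... Unused.
#' @export
tidy.genorm <- function(x, ...) x$ranking

#' @rdname genorm
#' @export
glance.genorm <- function(x, ...) {
  tibble(n_genes = nrow(x$ranking),
         final_pair = paste(x$final_pair, collapse = "/"),
         optimal_n = x$optimal_n, cutoff = x$cutoff,
         cutoff_met = x$cutoff_met,
         v_2_3 = x$v_series$v[x$v_series$n == 2])
}

#' @rdname genorm
#' @param object A `genorm` object.
#' @param type `"m"` for the average-stability (M) exclusion profile,
#'   `"v"` for the pairwise-variation bar chart.
#' @export
autoplot.genorm <- function(object, type = c("m", "v"), ...) {
  type <- match.arg(type)
  if (type == "m") {
    steps <- object$m_table |>
      dplyr::group_by(.data$round) |>
      dplyr::summarise(mean_m = mean(.data$m), .groups = "drop") |>
      dplyr::mutate(label = c(object$exclusion_order,
                              paste(object$final_pair, collapse = "\n")))
    ggplot2::ggplot(steps, ggplot2::aes(x = .data$round, y = .data$mean_m)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_continuous(breaks = steps$round,
                                  labels = steps$label) +
      ggplot2::labs(x = "least stable gene excluded at each step",
                    y = "average expression stability M") +
      ggplot2::theme_minimal()
  } else {
    vs <- object$v_series |>
      dplyr::mutate(label = factor(paste0("V", .data$n, "/", .data$n + 1),
                                   levels = paste0("V", .data$n, "/",
                                                   .data$n + 1)))
    ggplot2::ggplot(vs, ggplot2::aes(x = .data$label, y = .data$v)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
      ggplot2::labs(x = "normalization factors compared",
                    y = "pairwise variation V") +
      ggplot2::theme_minimal()
  }
}
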