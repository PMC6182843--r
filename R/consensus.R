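#' Cross-method consensus of stability rankings
#'
#' Compares the rankings produced by the four stability methods and
#' aggregates them into a single order by the geometric mean of per-method
#' ranks (lower = more stable).  geNorm's unordered most-stable pair enters
#' with shared rank 1.5.  The per-method top-k lists and their pairwise
#' overlaps are reported so that qualitative convergence between methods
#' (e.g. "at least 3 of the top 4 shared") can be read off directly.
#'
#' @param results Named list of fitted stability results — any mix of
#'   [genorm()], [normfinder()], [bestkeeper()], [delta_ct()] objects or
#'   plain data frames with `gene` and `rank` columns.  At least two, all
#'   over the same gene set.
#' @param k Size of the per-method top lists compared (default 4).
#' @param n_select Number of reference genes to select (default 3).
#' @param anchor Optional name of a method (usually `"genorm"`) whose two
#'   top-ranked genes are forced into the selected set before filling the
#'   remaining slots by aggregate rank.
#' @return An object of class `"consensus"`: list with `rank_table`
#'   (tibble gene x method ranks), `aggregate` (tibble `gene`,
#'   `aggregate_rank`, `rank`), `top_k` (per-method top-k gene lists),
#'   `top_k_overlap` (tibble `method1`, `method2`, `overlap`), and
#'   `selected` (character vector of `n_select` genes).
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' cs <- build_consensus(list(
#'   genorm = genorm(sim$cq), normfinder = normfinder(sim$cq),
#'   bestkeeper = bestkeeper(sim$cq), deltact = delta_ct(sim$cq)))
#' cs$selected
#' @export
build_consensus <- function(results, k = 4, n_select = 3, anchor = NULL) {
  if (length(results) < 2) {
    abort("Need results from at least 2 methods.",
          class = "qpcrstab_input_error")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a named list.", class = "qpcrstab_input_error")
  }
  ranks <- purrr::imap(results, function(res, nm) {
    r <- extract_ranking(res)
    tibble(method = nm, gene = r$gene, rank = r$rank)
  })
  gene_sets <- purrr::map(ranks, ~ sort(.x$gene))
  if (length(unique(gene_sets)) != 1) {
    abort("All methods must be fitted on the same gene set.",
          class = "qpcrstab_input_error")
  }
  long <- dplyr::bind_rows(ranks)
  rank_table <- long |>
    tidyr::pivot_wider(names_from = "method", values_from = "rank")

  aggregate <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(aggregate_rank = geomean(.data$rank),
                     .groups = "drop") |>
    dplyr::arrange(.data$aggregate_rank) |>
    dplyr::mutate(rank = dplyr::row_number())

  top_k <- purrr::map(ranks, function(r) {
    r$gene[order(r$rank)][seq_len(min(k, nrow(r)))]
  })
  pairs <- if (length(top_k) >= 2) combn(names(top_k), 2) else
    matrix(character(0), 2, 0)
  top_k_overlap <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble(method1 = a, method2 = b,
           overlap = length(intersect(top_k[[a]], top_k[[b]])))
  })

  selected <- character(0)
  if (!is.null(anchor)) {
    if (!anchor %in% names(results)) {
      abort(paste0("Unknown anchor method: ", anchor),
            class = "qpcrstab_input_error")
    }
    ar <- ranks[[anchor]]
    selected <- ar$gene[order(ar$rank)][seq_len(min(2, nrow(ar)))]
  }
  fill <- setdiff(aggregate$gene, selected)
  selected <- c(selected, fill)[seq_len(min(n_select, nrow(aggregate)))]

  structure(list(rank_table = rank_table, aggregate = aggregate,
                 top_k = top_k, top_k_overlap = top_k_overlap,
                 selected = selected, k = k, n_select = n_select),
            class = "consensus")
}

# Pull a gene/rank tibble out of any stability result
extract_ranking <- function(res) {
  r <- if (inherits(res, c("genorm", "normfinder", "delta_ct"))) {
    res$ranking
  } else if (inherits(res, "bestkeeper")) {
    res$ranking
  } else if (is.data.frame(res)) {
    res
  } else {
    abort("Unsupported result type in `results`.",
          class = "qpcrstab_input_error")
  }
  if (!all(c("gene", "rank") %in% names(r))) {
    abort("A ranking needs `gene` and `rank` columns.",
          class = "qpcrstab_input_error")
  }
  r[, c("gene", "rank")]
}

#' @export
print.consensus <- function(x, ...) {
  cat("Consensus of", ncol(x$rank_table) - 1, "stability methods\n")
  print(x$rank_table)
  cat("\nSelected reference set:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname build_consensus
#' @param x,object A `consensus` object.
#' @param ... Unused.
#' @export
tidy.consensus <- function(x, ...) {
  dplyr::left_join(x$rank_table, x$aggregate, by = "gene") |>
    dplyr::arrange(.data$aggregate_rank)
}

#' @rdname build_consensus
#' @export
glance.consensus <- function(x, ...) {
  tibble(n_methods = ncol(x$rank_table) - 1,
         n_genes = nrow(x$rank_table),
         min_top_k_overlap = min(x$top_k_overlap$overlap),
         selected = paste(x$selected, collapse = "/"))
}

#' @rdname build_consensus
#' @export
autoplot.consensus <- function(object, ...) {
  d <- object$rank_table |>
    tidyr::pivot_longer(-"gene", names_to = "method", values_to = "rank")
  gene_order <- object$aggregate$gene
  d$gene <- factor(d$gene, levels = gene_order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$rank,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "stability rank (1 = most stable)") +
    ggplot2::theme_minimal()
}
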