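#' Model-based (NormFinder-style) stability values
#'
#' Estimates a stability value per candidate reference gene by decomposing
#' its expression (on the log2-quantity scale) into intra-group variance
#' and inter-group deviation, following the model-based approach of
#' Andersen and colleagues.  Lower values indicate more stable expression.
#'
#' The algorithm: log2 quantities `x = (minCq - Cq) * log2(E)` are centred
#' per sample across genes (removing loading effects), then per gene and
#' group the mean and ddof-1 residual variance are computed.  The raw
#' within-group variances are bias-corrected for the centring step (with k
#' genes the centred residual variance is a mixture of all genes'
#' variances), floored at 0.  Inter-group deviations `d` (group mean minus
#' the gene's sample-size-weighted overall mean) are shrunk towards 0 by
#' the factor `tau^2 / (tau^2 + gamma^2_ig / n_g)`, where `tau^2` is the
#' across-gene ddof-1 variance of the raw deviations within the group.
#' The stability value is the mean over groups of
#' `|d_shrunk| + sqrt(gamma^2_ig / n_g)`.  With a single group it reduces
#' to `sqrt(gamma^2_i)`.
#'
#' @inheritParams cq_to_quantity
#' @param groups How to group samples: `"group"` (default; control versus
#'   treated), `"group_time"` (each group-by-time combination its own
#'   group), or a named character vector mapping `sample_id` to a group
#'   label.
#' @return An object of class `"normfinder"`: list with `ranking` (tibble
#'   `gene`, `stability`, `rank`, `tied`), `intergroup_d` and
#'   `intragroup_var` (tibbles gene x group) and `groups` (the mapping
#'   used).  Ties in stability keep input gene order and are flagged.
#' @examples
#' sim <- simulate_cq(cq_sim_config(seed = 1))
#' nf <- normfinder(sim$cq)
#' tidy(nf)
#' @export
normfinder <- function(data, groups = "group", efficiencies = 2) {
  m <- if (is.matrix(data)) data else cq_matrix(data)
  genes <- rownames(m)
  if (length(genes) < 3) {
    abort("NormFinder needs at least 3 genes.",
          class = "qpcrstab_size_error")
  }
  grp <- resolve_groups(data, colnames(m), groups)
  e <- eff_vector(genes, efficiencies)
  x <- (apply(m, 1, min) - m) * log2(e)   # log2 quantities
  z <- sweep(x, 2, colMeans(x))           # per-sample centring

  glabs <- unique(grp)
  n_groups <- length(glabs)
  k <- length(genes)
  n_g <- vapply(glabs, function(gl) sum(grp == gl), integer(1))
  if (n_groups > 1 && any(n_g < 2)) {
    abort("Every group needs at least 2 samples for intergroup analysis.",
          class = "qpcrstab_design_error")
  }

  zbar <- matrix(0, k, n_groups, dimnames = list(genes, glabs))
  s2 <- matrix(0, k, n_groups, dimnames = list(genes, glabs))
  for (gl in glabs) {
    zg <- z[, grp == gl, drop = FALSE]
    zbar[, gl] <- rowMeans(zg)
    s2[, gl] <- apply(zg, 1, function(r) sum((r - mean(r))^2) /
                        max(ncol(zg) - 1, 1))
  }
  # bias correction of centred residual variances:
  # E[s2_i] = gamma2_i (1 - 2/k) + sum_j gamma2_j / k^2
  gamma2 <- apply(s2, 2, function(a) {
    tot <- sum(a) / (1 - 1 / k)
    pmax((a - tot / k^2) / (1 - 2 / k), 0)
  })
  gamma2 <- matrix(gamma2, k, n_groups, dimnames = list(genes, glabs))

  if (n_groups == 1) {
    stability <- sqrt(gamma2[, 1])
    d_raw <- matrix(0, k, 1, dimnames = list(genes, glabs))
    d_shrunk <- d_raw
  } else {
    overall <- as.vector(zbar %*% n_g) / sum(n_g)   # weighted gene mean
    d_raw <- zbar - overall
    d_shrunk <- d_raw
    for (gl in glabs) {
      tau2 <- max(var(d_raw[, gl]), 0)
      denom <- tau2 + gamma2[, gl] / n_g[gl]
      shrink <- ifelse(denom > 0, tau2 / denom, 0)
      d_shrunk[, gl] <- d_raw[, gl] * shrink
    }
    stability <- rowMeans(abs(d_shrunk) + sqrt(sweep(gamma2, 2, n_g, "/")))
  }

  ord <- order(stability)   # stable sort: ties keep input order
  tied <- duplicated(round(stability[ord], 12)) |
    duplicated(round(stability[ord], 12), fromLast = TRUE)
  if (any(tied)) {
    warn("Tied stability values; tied genes keep input order.")
  }
  ranking <- tibble(gene = genes[ord],
                    stability = unname(stability[ord]),
                    rank = seq_along(ord), tied = tied)
  structure(list(
    ranking = ranking,
    intergroup_d = as_tibble(d_shrunk, rownames = "gene"),
    intragroup_var = as_tibble(gamma2, rownames = "gene"),
    groups = grp), class = "normfinder")
}

# Map samples to NormFinder groups
resolve_groups <- function(data, sample_ids, groups) {
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% c("group", "group_time")) {
    if (is.matrix(data)) {
      abort("With a matrix input, `groups` must be a named vector.",
            class = "qpcrstab_config_error")
    }
    meta <- cq_sample_meta(data)
    meta <- meta[match(sample_ids, meta$sample_id), ]
    if (groups == "group") return(setNames(meta$group, sample_ids))
    return(setNames(paste(meta$group, meta$time_min, sep = "_"),
                    sample_ids))
  }
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing) > 0) {
    abort(paste0("No group assigned for sample(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "qpcrstab_config_error")
  }
  groups[sample_ids]
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder stability values (lower = more stable)\n")
  print(x$ranking)
  invisible(x)
}

#' @rdname normfinder
#' @param x,object A `normfinder` object.
#' @param ... Unused.
#' @export
tidy.normfinder <- function(x, ...) x$ranking

#' @rdname normfinder
#' @export
glance.normfinder <- function(x, ...) {
  tibble(n_genes = nrow(x$ranking),
         n_groups = length(unique(x$groups)),
         best_gene = x$ranking$gene[1],
         best_stability = x$ranking$stability[1])
}

#' @rdname normfinder
#' @export
autoplot.normfinder <- function(object, ...) {
  d <- object$ranking |>
    dplyr::mutate(gene = factor(.data$gene, levels = .data$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$stability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "stability value") +
    ggplot2::theme_minimal()
}
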