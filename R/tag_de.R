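#' Tag integrity and singlet filtering
#'
#' Removes tags that cannot be tested: singlets (by default, tags seen
#' exactly once across the two libraries combined; a per-library reading
#' is available) and, when tag sequences are present, tags that are not
#' 26 bases long or do not start with the `CATG` anchor site.
#'
#' @param tags Tibble with integer count columns `x` (library 1) and `y`
#'   (library 2) and optionally `sequence`.
#' @param singlet `"total"` (default): a singlet has `x + y == 1`;
#'   `"per_library"`: a tag is removed when each library saw it at most
#'   once and at least one saw it exactly once.
#' @return A list with `kept` and `removed` tibbles; `removed` carries a
#'   `filtered_reason` column (`"singlet"`, `"bad_prefix"`,
#'   `"bad_length"`).
#' @examples
#' filter_tags(tibble::tibble(x = c(1, 1, 5), y = c(0, 1, 7)))
#' @export
filter_tags <- function(tags, singlet = c("total", "per_library")) {
  singlet <- match.arg(singlet)
  tags <- as_tibble(tags)
  if (any(tags$x < 0 | tags$y < 0)) {
    abort("Tag counts must be non-negative.", class = "qpcrstab_data_error")
  }
  reason <- rep(NA_character_, nrow(tags))
  if ("sequence" %in% names(tags)) {
    bad_len <- !is.na(tags$sequence) & nchar(tags$sequence) != 26
    bad_pre <- !bad_len & !is.na(tags$sequence) &
      substr(tags$sequence, 1, 4) != "CATG"
    reason[bad_len] <- "bad_length"
    reason[bad_pre] <- "bad_prefix"
  }
  is_singlet <- if (singlet == "total") {
    tags$x + tags$y == 1
  } else {
    tags$x <= 1 & tags$y <= 1 & (tags$x == 1 | tags$y == 1)
  }
  reason[is.na(reason) & is_singlet] <- "singlet"
  removed <- tags[!is.na(reason), ]
  if (nrow(removed) > 0) removed$filtered_reason <- reason[!is.na(reason)]
  list(kept = tags[is.na(reason), ], removed = removed)
}

#' Audic–Claverie test for a tag's counts in two libraries
#'
#' Conditional Poisson test: given `x` occurrences of a tag in a library
#' of `N1` total tags, the null distribution of its count `y` in a second
#' library of `N2` tags is
#' \deqn{p(y|x) = \left(\frac{N2}{N1}\right)^y
#'       \frac{(x+y)!}{x!\,y!\,(1 + N2/N1)^{x+y+1}}}
#' — a negative binomial with size `x + 1` and success probability
#' `N1/(N1+N2)`, evaluated in log-gamma space.  Each direction's tail is
#' computed by conditioning on the other library's count —
#' `P(Y <= y | x)` for depletion in library 2 and `P(X <= x | y)` for
#' enrichment — which makes the test exactly symmetric under exchanging
#' `(x, N1)` with `(y, N2)`.  The two-sided p-value doubles the smaller
#' tail, capped at 1.
#'
#' @param x,y Non-negative integer counts in libraries 1 and 2
#'   (vectorized).
#' @param n1,n2 Library totals.
#' @param alternative `"two.sided"` (default), `"less"` (`P(Y <= y | x)`)
#'   or `"greater"`.
#' @return p-value(s) in (0, 1].
#' @examples
#' ac_pvalue(0, 0, 1e6, 1e6)    # 1
#' ac_pvalue(0, 20, 1e6, 1e6)   # highly significant
#' @export
ac_pvalue <- function(x, y, n1, n2,
                      alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  p_lower <- pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
  p_upper <- pnbinom(x, size = y + 1, prob = n2 / (n1 + n2))
  switch(alternative,
         two.sided = pmin(1, 2 * pmin(p_lower, p_upper)),
         less = p_lower,
         greater = p_upper)
}

#' Normalized fold change for tag counts
#'
#' Frequencies are expressed in tags per million; a zero count is replaced
#' by one before normalization so the ratio is always defined.  The signed
#' fold change follows [fc_from_ratio()]: `R` when `R >= 1`, else `-1/R`,
#' with `R = tpm2 / tpm1` (library 2 relative to library 1).
#'
#' @inheritParams ac_pvalue
#' @return A tibble with `tpm1`, `tpm2`, `ratio`, `fold_change`.
#' @examples
#' tag_fold_change(0, 8, 1e6, 1e6)   # ratio 8, FC +8
#' @export
tag_fold_change <- function(x, y, n1, n2) {
  xs <- pmax(x, 1); ys <- pmax(y, 1)
  tpm1 <- xs / n1 * 1e6
  tpm2 <- ys / n2 * 1e6
  ratio <- tpm2 / tpm1
  tibble(tpm1 = tpm1, tpm2 = tpm2, ratio = ratio,
         fold_change = fc_from_ratio(ratio))
}

#' Tag-count differential expression between two libraries
#'
#' Full tag-level analysis: integrity/singlet filtering, the
#' Audic–Claverie test, tags-per-million fold changes, and regulation
#' calls (`UR`/`DR`/`ns`) at the given significance level.  No
#' multiple-testing correction is applied by default (per-tag testing at
#' `alpha`); Benjamini–Hochberg adjustment is available.
#'
#' @param tags Tibble with columns `tag` (or `sequence`), `x`, `y`.
#' @param n1,n2 Library totals (defaults: the column sums of `x` and `y`).
#' @param alpha Significance level.
#' @param singlet Singlet definition, see [filter_tags()].
#' @param adjust `"none"` (default) or `"BH"` for Benjamini–Hochberg
#'   adjusted p-values (the call then uses the adjusted values).
#' @param alternative Sidedness of the test, see [ac_pvalue()].
#' @return A tibble with one row per input tag: counts, `tpm1`, `tpm2`,
#'   `ratio`, `fold_change`, `p_value`, `call`, and `filtered_reason`
#'   (`NA` for tested tags; filtered tags have `NA` statistics and call).
#' @examples
#' sim <- simulate_tags(n_null = 50, n_de = 5, fold = 8, seed = 1)
#' tag_de(sim$tags, n1 = sim$N1, n2 = sim$N2)
#' @export
tag_de <- function(tags, n1 = sum(tags$x), n2 = sum(tags$y), alpha = 0.05,
                   singlet = "total", adjust = c("none", "BH"),
                   alternative = "two.sided") {
  adjust <- match.arg(adjust)
  tags <- as_tibble(tags)
  flt <- filter_tags(tags, singlet = singlet)
  kept <- flt$kept
  res <- kept |>
    dplyr::bind_cols(tag_fold_change(kept$x, kept$y, n1, n2)) |>
    dplyr::mutate(
      p_value = ac_pvalue(.data$x, .data$y, n1, n2,
                          alternative = alternative))
  if (adjust == "BH") res$p_value <- p.adjust(res$p_value, method = "BH")
  res <- res |>
    dplyr::mutate(
      call = dplyr::if_else(.data$ratio == 1, "ns",
                            regulation_call(.data$ratio, .data$p_value,
                                            alpha)),
      filtered_reason = NA_character_)
  if (nrow(flt$removed) > 0) {
    res <- dplyr::bind_rows(res, flt$removed)
  }
  # preserve input tag order where an id column exists
  if ("tag" %in% names(tags)) {
    res <- res[match(tags$tag, res$tag), ]
  }
  res
}
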