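# Independent brute-force oracles, written directly from the definitions
# with plain loops.  They deliberately share no code with the package
# internals they check.

# Mean over partner genes of the SD of per-sample log2 ratios
oracle_genorm_m <- function(q) {
  genes <- rownames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    sds <- c()
    for (k in setdiff(genes, j)) {
      ratios <- log2(q[j, ] / q[k, ])
      sds <- c(sds, sd(ratios))
    }
    m[j] <- mean(sds)
  }
  m
}

# Step-by-step model-based stability values: log quantities, per-sample
# centring, per-group means/variances with the centring bias correction,
# shrunken intergroup deviations, rho = mean_g(|d| + sqrt(var/n)).
oracle_normfinder <- function(cqm, groups, e_base = 2) {
  genes <- rownames(cqm)
  k <- length(genes)
  x <- matrix(NA_real_, k, ncol(cqm), dimnames = dimnames(cqm))
  for (g in genes) x[g, ] <- (min(cqm[g, ]) - cqm[g, ]) * log2(e_base)
  z <- x
  for (s in seq_len(ncol(x))) z[, s] <- x[, s] - mean(x[, s])

  glabs <- unique(groups)
  zbar <- s2 <- gam2 <- matrix(NA_real_, k, length(glabs),
                               dimnames = list(genes, glabs))
  ng <- integer(length(glabs)); names(ng) <- glabs
  for (gl in glabs) {
    cols <- which(groups == gl)
    ng[gl] <- length(cols)
    for (g in genes) {
      zg <- z[g, cols]
      zbar[g, gl] <- mean(zg)
      s2[g, gl] <- var(zg)
    }
    tot <- sum(s2[, gl]) / (1 - 1 / k)
    for (g in genes) {
      gam2[g, gl] <- max((s2[g, gl] - tot / k^2) / (1 - 2 / k), 0)
    }
  }
  if (length(glabs) == 1) return(sqrt(gam2[, 1]))
  rho <- numeric(k); names(rho) <- genes
  d_sh <- zbar
  for (g in genes) {
    overall <- sum(zbar[g, ] * ng) / sum(ng)
    for (gl in glabs) d_sh[g, gl] <- zbar[g, gl] - overall
  }
  for (gl in glabs) {
    tau2 <- max(var(d_sh[, gl]), 0)
    for (g in genes) {
      den <- tau2 + gam2[g, gl] / ng[gl]
      shrink <- if (den > 0) tau2 / den else 0
      d_sh[g, gl] <- d_sh[g, gl] * shrink
    }
  }
  for (g in genes) {
    terms <- abs(d_sh[g, ]) + sqrt(gam2[g, ] / ng)
    rho[g] <- mean(terms)
  }
  rho
}

# Direct summation of the conditional tag pmf (log-gamma terms summed
# explicitly, no distribution functions)
oracle_ac_pmf <- function(y, x, n1, n2) {
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log(1 + r))
}

oracle_ac_pvalue <- function(x, y, n1, n2) {
  lower <- sum(oracle_ac_pmf(0:y, x, n1, n2))
  upper <- sum(oracle_ac_pmf(0:x, y, n2, n1))
  min(1, 2 * min(lower, upper))
}

# Exhaustive reallocation test on per-sample normalized log quantities
oracle_perm_p <- function(lc, lt) {
  pooled <- c(lc, lt)
  n1 <- length(lc)
  obs <- abs(mean(lt) - mean(lc))
  allocs <- combn(length(pooled), n1)
  hits <- 0
  for (i in seq_len(ncol(allocs))) {
    idx <- allocs[, i]
    stat <- abs(mean(pooled[-idx]) - mean(pooled[idx]))
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(allocs)
}

# Small deterministic Cq fixture: g genes x s samples on a grid, strictly
# positive, no ties in interesting statistics
toy_cq_matrix <- function(g = 3, s = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(rnorm(g * s, mean = 20, sd = 1.5), g, s,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(s))))
  round(m, 3)
}

# Long-format tibble wrapper around a matrix, one assay, all control
toy_cq_long <- function(m, assay = "salt") {
  purrr::map_dfr(seq_len(ncol(m)), function(s) {
    tibble::tibble(
      sample_id = colnames(m)[s], assay = assay, accession = "acc1",
      group = "control", time_min = 0L, bio_rep = s, tech_rep = 1L,
      gene = rownames(m), cq = m[, s])
  })
}
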