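## Upper-quartile normalization, CPM filtering, exact negative-binomial
## two-group differential expression and z-score matrices for heatmaps.

#' Upper-quartile normalization
#'
#' Per sample j, `q_j` is the `quantile_p` quantile (linear interpolation,
#' type 7) of the nonzero counts divided by the library size; the
#' normalization factor is `q_j / geometric_mean(q)`, so factors have
#' geometric mean 1, and the effective library size is
#' `library_size * factor`.  CPM are counts per million of effective size.
#' The result is invariant to global library scaling and row permutation.
#'
#' @param m Count matrix (features x samples).
#' @param quantile_p Quantile used (default 0.75, the upper quartile).
#' @return List with `factors` (data.frame `sample`, `library_size`,
#'   `uq_factor`, `effective_size`) and `cpm` (matrix like `m`).  Rows that
#'   are zero across all samples are removed first.
#' @export
uq_normalize <- function(m, quantile_p = 0.75) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    stop("sample has no nonzero counts: ", colnames(m)[which(zero)[1]])
  }
  q <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    quantile(x[x > 0] / lib[j], probs = quantile_p, type = 7, names = FALSE)
  }, numeric(1))
  uq_factor <- q / exp(mean(log(q)))
  eff <- lib * uq_factor
  cpm <- sweep(m, 2, eff, "/") * 1e6
  factors <- data.frame(sample = colnames(m), library_size = as.numeric(lib),
                        uq_factor = uq_factor, effective_size = eff,
                        stringsAsFactors = FALSE)
  rownames(factors) <- NULL
  list(factors = factors, cpm = cpm)
}

#' CPM detection filter
#'
#' Keeps rows with CPM at or above `min_cpm` in every replicate of at least
#' one group.
#'
#' @param cpm CPM matrix (features x samples).
#' @param groups Factor/character of group labels per column.
#' @param min_cpm Threshold (default 1).
#' @return Character vector of retained row ids.
#' @export
filter_cpm <- function(cpm, groups, min_cpm = 1) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(cpm))
  keep <- rep(FALSE, nrow(cpm))
  for (g in unique(groups)) {
    sub <- cpm[, groups == g, drop = FALSE]
    keep <- keep | apply(sub >= min_cpm, 1, all)
  }
  rownames(cpm)[keep]
}

## two-sided exact test of a group-sum split conditioned on the total,
## under NB with common dispersion phi (binomial split when phi == 0)
.exact_split_pvalue <- function(y1, y2, n1, n2, phi) {
  T <- y1 + y2
  if (T == 0) return(1)
  ys <- 0:T
  if (phi <= 0) {
    logf <- dbinom(ys, size = T, prob = n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- T / (n1 + n2)
    logf <- dnbinom(ys, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(T - ys, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  logf <- logf - max(logf)
  f <- exp(logf)
  sum(f[f <= f[y1 + 1] * (1 + 1e-12)]) / sum(f)
}

#' Exact negative-binomial two-group differential expression
#'
#' Counts are scaled to a common effective library size (upper-quartile
#' effective sizes, or user-supplied) and rounded to pseudo-counts.  A
#' common dispersion is estimated by the method of moments across rows
#' (within-group moments, pooled over both groups, truncated at zero), and
#' each row's group-sum split is tested with a two-sided exact test
#' conditioned on the row total - a binomial split test in the Poisson
#' limit.  P-values are Benjamini-Hochberg adjusted; a row is flagged as
#' differentially expressed when `|log2FC| >= lfc_threshold` and
#' `FDR < fdr_threshold`.
#'
#' @param m Count matrix (features x samples), ideally pre-filtered with
#'   [filter_cpm()].
#' @param groups Two-level factor/character per column; each level needs at
#'   least 2 replicates.
#' @param pseudo_cpm Pseudocount (CPM units) used in the log2 fold change
#'   (default 0.5).
#' @param quantile_p Upper-quartile probability for internal normalization.
#' @param effective_sizes Optional per-sample effective sizes overriding the
#'   internal upper-quartile normalization.
#' @param lfc_threshold,fdr_threshold DEG thresholds (defaults 1 and 0.01).
#' @return data.frame with `row_id`, `mean_cpm_<group1>`,
#'   `mean_cpm_<group2>`, `log2fc` (group2 vs group1), `p_value`, `fdr`,
#'   `is_deg`.
#' @export
nb_exact_de <- function(m, groups, pseudo_cpm = 0.5, quantile_p = 0.75,
                        effective_sizes = NULL, lfc_threshold = 1,
                        fdr_threshold = 0.01) {
  m <- as.matrix(m)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 replicates")

  if (is.null(effective_sizes)) {
    norm <- uq_normalize(m, quantile_p)
    eff <- norm$factors$effective_size
    cpm <- norm$cpm
    m <- m[rownames(cpm), , drop = FALSE]
  } else {
    eff <- effective_sizes
    cpm <- sweep(m, 2, eff, "/") * 1e6
  }
  common <- exp(mean(log(eff)))
  scaled <- round(sweep(m, 2, common / eff, "*"))

  g1 <- groups == lv[1]
  g2 <- groups == lv[2]
  mom <- function(x) {
    xb <- mean(x)
    if (xb <= 0) return(NA_real_)
    (var(x) - xb) / xb^2
  }
  est1 <- apply(scaled[, g1, drop = FALSE], 1, mom)
  est2 <- apply(scaled[, g2, drop = FALSE], 1, mom)
  phi <- max(0, mean(c(est1, est2), na.rm = TRUE))

  y1 <- rowSums(scaled[, g1, drop = FALSE])
  y2 <- rowSums(scaled[, g2, drop = FALSE])
  p <- vapply(seq_along(y1),
              function(i) .exact_split_pvalue(y1[i], y2[i], n1, n2, phi),
              numeric(1))
  fdr <- p.adjust(p, method = "BH")
  mc1 <- rowMeans(cpm[, g1, drop = FALSE])
  mc2 <- rowMeans(cpm[, g2, drop = FALSE])
  log2fc <- log2((mc2 + pseudo_cpm) / (mc1 + pseudo_cpm))
  out <- data.frame(row_id = rownames(m), log2fc = log2fc, p_value = p,
                    fdr = fdr,
                    is_deg = abs(log2fc) >= lfc_threshold &
                      fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_cpm_", lv[1])]] <- mc1
  out[[paste0("mean_cpm_", lv[2])]] <- mc2
  rownames(out) <- NULL
  attr(out, "dispersion") <- phi
  attr(out, "groups") <- lv
  out
}

#' Row z-scores of log2(CPM + 1) with Ward clustering orders
#'
#' Rows with zero variance are dropped with a message.  Row and column
#' orderings come from hierarchical clustering (Euclidean distance, Ward
#' linkage), as conventionally used for expression heatmaps.
#'
#' @param cpm CPM matrix.
#' @param rows Optional row ids to subset.
#' @return List with `z` (matrix; each row mean 0, sd 1), `row_order`,
#'   `col_order` (integer permutations) and `dropped` (ids of zero-variance
#'   rows).
#' @export
zscore_matrix <- function(cpm, rows = NULL) {
  x <- log2(as.matrix(cpm) + 1)
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  if (ncol(x) < 2) stop("at least 2 samples are required")
  sds <- apply(x, 1, sd)
  dropped <- rownames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    message(length(dropped), " zero-variance row(s) dropped")
    x <- x[!(rownames(x) %in% dropped), , drop = FALSE]
  }
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  row_order <- if (nrow(z) > 2) hclust(dist(z), method = "ward.D2")$order
               else seq_len(nrow(z))
  col_order <- if (ncol(z) > 2) hclust(dist(t(z)), method = "ward.D2")$order
               else seq_len(ncol(z))
  list(z = z, row_order = row_order, col_order = col_order,
       dropped = dropped)
}
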