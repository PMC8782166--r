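## Repertoire inequality and heterogeneity statistics: N80, evenness factor,
## Gini coefficient and chi-squared heterogeneity of replicate compositions.

#' Minimum number of features reaching a cumulative abundance share (N80)
#'
#' The minimal k such that the k most abundant features jointly carry at
#' least `share` of the total.  Ties in abundance are handled by taking as
#' many elements as needed, so the result is deterministic and invariant to
#' feature order.  `n_top_share(v, 1)` equals the number of positive
#' entries.
#'
#' @param abundance Non-negative numeric vector.
#' @param share Target cumulative share (default 0.80).
#' @return Integer k.
#' @export
n_top_share <- function(abundance, share = 0.80) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  tot <- sum(abundance)
  if (tot <= 0) stop("abundance vector sums to zero")
  cum <- cumsum(sort(abundance, decreasing = TRUE)) / tot
  as.integer(which(cum >= share - 1e-12)[1])
}

#' Evenness factor e
#'
#' The value e such that e% of the RNA species account for (100 - e)% of
#' the total abundance: the crossing of the descending-sorted empirical
#' Lorenz curve L (piecewise linear, L(0) = 0, L(1) = 1, where L(p) is the
#' share held by the top p fraction of species) with the line 1 - p, found
#' by linear interpolation on the bracketing segment.  A uniform vector
#' gives e = 50 (the maximum); concentrating mass in few species drives e
#' towards 0.
#'
#' @param abundance Non-negative numeric vector with at least 2 positive
#'   entries; a single-species vector returns the limit convention 100/n
#'   with attribute `degenerate = TRUE`.
#' @return e in (0, 50].
#' @export
evenness_factor <- function(abundance) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  n <- length(abundance)
  tot <- sum(abundance)
  if (tot <= 0) stop("abundance vector sums to zero")
  if (sum(abundance > 0) < 2) {
    return(structure(100 / n, degenerate = TRUE))
  }
  x <- sort(abundance, decreasing = TRUE) / tot
  px <- seq_len(n) / n
  Lx <- cumsum(x)
  ## find the segment [p0, p1] on which L(p) - (1 - p) changes sign
  g <- Lx - (1 - px)
  i <- which(g >= 0)[1]
  p0 <- if (i == 1) 0 else px[i - 1]
  L0 <- if (i == 1) 0 else Lx[i - 1]
  slope <- (Lx[i] - L0) / (px[i] - p0)
  ## solve L0 + slope (p - p0) = 1 - p
  p_star <- (1 - L0 + slope * p0) / (slope + 1)
  100 * p_star
}

#' Gini coefficient
#'
#' Mean absolute pairwise difference normalized by twice the mean:
#' `G = sum_ij |x_i - x_j| / (2 n^2 mu)`.  Zero for a uniform vector,
#' approaching 1 as abundance concentrates in one species; invariant to
#' positive scaling and permutation.
#'
#' @param abundance Non-negative numeric vector, length >= 2, positive sum.
#' @return G in \[0, 1).
#' @export
gini_coefficient <- function(abundance) {
  n <- length(abundance)
  if (n < 2) stop("need at least 2 entries")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  mu <- mean(abundance)
  if (mu <= 0) stop("abundance vector sums to zero")
  x <- sort(abundance)
  ## O(n log n) form of the pairwise-difference sum
  g <- 2 * sum(seq_len(n) * x) / (n^2 * mu) - (n + 1) / n
  g
}

#' Chi-squared heterogeneity of replicate compositions
#'
#' For a features x replicates matrix of within-biotype fractional
#' compositions (columns sum to 1), the heterogeneity is the sum of squared
#' deviations from the per-feature replicate mean:
#' `chi2 = sum_f sum_r (p_fr - pbar_f)^2`.  When a reference group matrix
#' is supplied, the fold change `chi2(group) / chi2(reference)` is also
#' returned; values above 1 indicate a more heterogeneous repertoire than
#' the reference.
#'
#' @param fractions Numeric matrix, columns are replicate compositions.
#' @param ref_fractions Optional matrix for the reference group (same
#'   feature space, any replicate count).
#' @return List with `chi2` and `fold_change` (`NA` when no reference;
#'   `Inf` with a warning when the reference heterogeneity is zero and the
#'   group's is not).
#' @export
chi2_heterogeneity <- function(fractions, ref_fractions = NULL) {
  fractions <- as.matrix(fractions)
  cs <- colSums(fractions)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("column ", which(abs(cs - 1) > 1e-6)[1],
         " of fractions does not sum to 1")
  }
  chi2 <- sum((fractions - rowMeans(fractions))^2)
  fc <- NA_real_
  if (!is.null(ref_fractions)) {
    ref <- Recall(ref_fractions)$chi2
    if (ref == 0) {
      if (chi2 > 0) {
        warning("reference heterogeneity is zero; fold change is infinite")
        fc <- Inf
      } else {
        fc <- NaN
      }
    } else {
      fc <- chi2 / ref
    }
  }
  list(chi2 = chi2, fold_change = fc)
}

#' Per-biotype diversity statistics across sample groups
#'
#' Convenience wrapper computing, for each biotype and group, the N80,
#' evenness factor and Gini coefficient (mean of per-replicate values on
#' within-biotype CPM fractions) and the chi-squared heterogeneity with its
#' fold change against a reference group.
#'
#' @param cpm CPM matrix (features x samples).
#' @param feature_biotype Character vector of biotypes per row of `cpm`.
#' @param groups Group label per column.
#' @param ref_group Reference group for the heterogeneity fold change
#'   (default the first group).
#' @param min_features Biotypes with fewer features are skipped (default 2).
#' @return data.frame with one row per biotype x group: `biotype`, `group`,
#'   `n80`, `evenness_e`, `gini`, `chi2`, `chi2_fc_vs_ref`.
#' @export
diversity_stats <- function(cpm, feature_biotype, groups,
                            ref_group = NULL, min_features = 2L) {
  groups <- as.character(groups)
  if (is.null(ref_group)) ref_group <- groups[1]
  out <- list()
  for (b in unique(feature_biotype)) {
    sub <- cpm[feature_biotype == b, , drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (nrow(sub) < min_features) next
    frac <- sweep(sub, 2, colSums(sub), "/")
    ref_chi <- chi2_heterogeneity(
      frac[, groups == ref_group, drop = FALSE])$chi2
    for (g in unique(groups)) {
      gf <- frac[, groups == g, drop = FALSE]
      chi <- chi2_heterogeneity(gf)$chi2
      out[[length(out) + 1L]] <- data.frame(
        biotype = b, group = g,
        n80 = round(mean(apply(gf, 2, n_top_share))),
        evenness_e = mean(apply(gf, 2, evenness_factor)),
        gini = mean(apply(gf, 2, gini_coefficient)),
        chi2 = chi,
        chi2_fc_vs_ref = if (g == ref_group) 1
                         else if (ref_chi == 0) NA_real_
                         else chi / ref_chi,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
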