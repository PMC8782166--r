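## Per-feature base-coverage profiles with fragment/arm calling,
## cross-dataset miRNA signature intersection and sorting-motif scanning.

#' Base coverage of one feature
#'
#' `coverage[i]` is the number of assigned reads overlapping position i
#' (0-based) of the mature sequence (CCA included for tRNAs), so the sum of
#' the coverage vector equals the summed read lengths.
#'
#' @param assignments Assignment data.frame restricted to one feature.
#' @param feature One-row slice of `ReferenceSet$records` (or a list with
#'   `feature_id` and `sequence`).
#' @return Object of class `CoverageProfile`: list with `feature_id` and
#'   integer `coverage`.
#' @export
base_coverage <- function(assignments, feature) {
  if (nrow(assignments) &&
      any(assignments$feature_id != feature$feature_id)) {
    stop("assignments refer to a different feature")
  }
  L <- nchar(feature$sequence)
  d <- tabulate(assignments$start + 1L, nbins = L + 1L) -
    tabulate(assignments$end + 1L, nbins = L + 1L)
  structure(list(feature_id = feature$feature_id,
                 coverage = cumsum(d)[seq_len(L)]),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat("CoverageProfile for", x$feature_id, "-", length(x$coverage),
      "positions, max depth", max(x$coverage), "\n")
  invisible(x)
}

#' Call well-defined fragment peaks from a coverage profile
#'
#' Peaks are maximal runs of positions with coverage at or above
#' `threshold_frac` of the maximum, of length at least `min_len`.  Each
#' peak is labelled by arm: 5' when its midpoint lies in the first third of
#' the feature, 3' in the last third, internal otherwise.  When the
#' feature's assignments are supplied, `read_share` reports the fraction of
#' reads whose midpoint falls inside the peak.
#'
#' @param profile A `CoverageProfile`.
#' @param assignments Optional assignment data.frame for the same feature.
#' @param threshold_frac Fraction of the maximum coverage (default 0.5).
#' @param min_len Minimum peak length in nt (default 15).
#' @return data.frame of disjoint, sorted peaks: `feature_id`, `start`,
#'   `end` (0-based half-open), `arm`, `max_depth`, `read_share`.
#' @export
call_fragments <- function(profile, assignments = NULL,
                           threshold_frac = 0.5, min_len = 15L) {
  cov <- profile$coverage
  empty <- data.frame(feature_id = character(), start = integer(),
                      end = integer(), arm = character(),
                      max_depth = integer(), read_share = numeric(),
                      stringsAsFactors = FALSE)
  if (max(cov) == 0) return(empty)
  thr <- threshold_frac * max(cov)
  above <- cov >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- runs$values & runs$lengths >= min_len
  if (!any(sel)) return(empty)
  s0 <- starts[sel] - 1L            # back to 0-based
  e0 <- ends[sel]
  L <- length(cov)
  midpt <- (s0 + e0) / 2
  arm <- ifelse(midpt < L / 3, "five_prime",
                ifelse(midpt > 2 * L / 3, "three_prime", "internal"))
  share <- rep(NA_real_, length(s0))
  if (!is.null(assignments) && nrow(assignments)) {
    rm <- (assignments$start + assignments$end) / 2
    share <- vapply(seq_along(s0),
                    function(i) mean(rm >= s0[i] & rm < e0[i]), numeric(1))
  }
  data.frame(feature_id = profile$feature_id, start = s0, end = e0,
             arm = arm,
             max_depth = vapply(seq_along(s0),
                                function(i) max(cov[(s0[i] + 1):e0[i]]),
                                numeric(1)),
             read_share = share, stringsAsFactors = FALSE)
}

#' Collapse miRNA ids to a precursor base name
#'
#' Strips species prefixes (mmu-/rno-/xla-), arm suffixes (-5p/-3p) and
#' trailing locus indices (-1/-2/...), so e.g. "mmu-miR-10a-5p" and
#' "rno-miR-10a-5p" share the base "miR-10a".  Paralog letters are retained
#' unless `collapse_paralogs = TRUE` (miR-10a and miR-10b then both become
#' "miR-10").
#'
#' @param ids Character vector of miRNA ids.
#' @param collapse_paralogs Also strip paralog letters (default FALSE).
#' @return Character vector of base names.
#' @export
collapse_mirna_base <- function(ids, collapse_paralogs = FALSE) {
  x <- sub("^(mmu|rno|xla|hsa)-", "", ids, ignore.case = TRUE)
  x <- sub("-(5p|3p)$", "", x)
  x <- sub("-[0-9]+$", "", x)
  if (collapse_paralogs) x <- sub("(?<=[0-9])[a-z]+$", "", x, perl = TRUE)
  x
}

#' Cross-dataset miRNA signature intersection
#'
#' Each dataset's miRNA ids are collapsed to precursor bases
#' ([collapse_mirna_base()]); a base counts as detected in a dataset when
#' its summed counts reach that dataset's threshold on average across
#' replicates (`threshold_units` "reads" uses raw counts, "cpm" rescales
#' each sample to counts per million first).  The output reports per-base
#' membership and all Venn region cardinalities; the core count is the
#' number of bases detected in every dataset.  The result is symmetric in
#' dataset order.
#'
#' @param datasets List of lists with elements `name`, `counts` (miRNA
#'   count matrix, features x replicates), `min_threshold` and
#'   `threshold_units` ("reads" or "cpm").
#' @param collapse_paralogs Passed to [collapse_mirna_base()].
#' @return List with `membership` (data.frame, one row per base, one
#'   logical column per dataset), `venn` (data.frame `pattern`, `count` of
#'   exclusive Venn regions) and `core` (bases detected everywhere).
#' @export
signature_intersection <- function(datasets, collapse_paralogs = FALSE) {
  if (length(datasets) < 2) stop("at least 2 datasets are required")
  detected <- list()
  for (d in datasets) {
    units <- d$threshold_units
    if (!units %in% c("reads", "cpm")) {
      stop("unknown threshold_units '", units, "' for dataset ", d$name)
    }
    m <- as.matrix(d$counts)
    if (units == "cpm") {
      m <- sweep(m, 2, colSums(m), "/") * 1e6
    }
    base <- collapse_mirna_base(rownames(m), collapse_paralogs)
    agg <- rowsum(m, base)
    detected[[d$name]] <- rownames(agg)[rowMeans(agg) >= d$min_threshold]
  }
  all_bases <- sort(unique(unlist(detected)))
  membership <- data.frame(base = all_bases, stringsAsFactors = FALSE)
  for (nm in names(detected)) membership[[nm]] <- all_bases %in% detected[[nm]]
  memb <- as.matrix(membership[, -1, drop = FALSE])
  pattern <- apply(memb, 1, function(r) {
    paste(names(detected)[r], collapse = "&")
  })
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  core <- sum(rowSums(memb) == ncol(memb))
  list(membership = membership, venn = venn, core = core)
}

.IUPAC_OK <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Scan miRNA sequences for sorting motifs
#'
#' Motifs are IUPAC patterns (U accepted and treated as T) matched at every
#' position of every sequence.  The summary counts, among the `k` most and
#' least abundant miRNAs, how many carry at least one hit of any motif -
#' the comparison used to ask whether exported (EV-enriched) miRNAs
#' preferentially carry sorting motifs.
#'
#' @param sequences Named character vector (miRNA id -> sequence).
#' @param motifs Character vector of IUPAC motifs; the shipped default
#'   (GGAG, UGCA, CAUG, GUAG) covers motifs reported to direct miRNA
#'   loading into extracellular vesicles.
#' @param abundance Named numeric vector of miRNA abundances (same ids).
#' @param k Size of the top/bottom abundance sets (default 50).
#' @return List with `hits` (data.frame `mirna_id`, `motif`, `start`
#'   0-based), `per_mirna` (`mirna_id`, `abundance`, `n_hits`, `any_hit`)
#'   and `summary` (`set` top/bottom, `k`, `n_with_hit`).
#' @export
motif_scan <- function(sequences,
                       motifs = c("GGAG", "UGCA", "CAUG", "GUAG"),
                       abundance, k = 50L) {
  ids <- names(sequences)
  stopifnot(!is.null(ids), !is.null(names(abundance)))
  motifs_dna <- toupper(chartr("Uu", "Tt", motifs))
  bad <- vapply(strsplit(motifs_dna, ""),
                function(ch) any(!ch %in% .IUPAC_OK), logical(1))
  if (any(bad)) stop("invalid IUPAC symbol in motif '",
                     motifs[which(bad)[1]], "'")
  subj <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", sequences)))
  names(subj) <- ids
  hits <- list()
  for (mo in seq_along(motifs_dna)) {
    mt <- Biostrings::vmatchPattern(motifs_dna[mo], subj, fixed = FALSE)
    st <- Biostrings::startIndex(mt)
    for (i in seq_along(st)) {
      if (length(st[[i]])) {
        hits[[length(hits) + 1L]] <- data.frame(
          mirna_id = ids[i], motif = motifs[mo], start = st[[i]] - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE))
          else data.frame(mirna_id = character(), motif = character(),
                          start = integer(), stringsAsFactors = FALSE)
  n_hits <- table(factor(hits$mirna_id, levels = ids))
  per <- data.frame(mirna_id = ids,
                    abundance = as.numeric(abundance[ids]),
                    n_hits = as.integer(n_hits),
                    any_hit = as.integer(n_hits) > 0,
                    stringsAsFactors = FALSE)
  ord <- per[order(-per$abundance, per$mirna_id), ]
  k <- min(k, nrow(ord))
  top <- head(ord, k)
  bottom <- tail(ord, k)
  summary <- data.frame(set = c("top", "bottom"), k = k,
                        n_with_hit = c(sum(top$any_hit),
                                       sum(bottom$any_hit)),
                        stringsAsFactors = FALSE)
  list(hits = hits, per_mirna = per, summary = summary)
}
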