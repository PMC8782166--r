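## piRNA disambiguation: putative piRNAs whose full sequence also places
## inside another ncRNA biotype are discarded.  piRNA databases are known to
## duplicate substrings of structural ncRNAs (tRNAs, rRNAs, snoRNAs); only
## entries with no cross-biotype placement are kept as genuine piRNAs.

#' Filter piRNAs that cross-map to other ncRNA biotypes
#'
#' A piRNA is excluded when its full sequence has an ungapped, end-to-end
#' placement inside any other-biotype sequence with at most `max_mm`
#' substitutions AND the placement contains at least `seed_len` consecutive
#' exact matches (emulating a 0-mismatch seed of length 16 in an end-to-end
#' alignment screen).  The first qualifying hit, ordered by biotype
#' priority then lexicographic feature id, is reported.
#'
#' With `max_mm = 0` the filter reduces to plain substring containment, and
#' raising `max_mm` can only move piRNAs from kept to excluded.
#'
#' @param reference A `ReferenceSet` containing the piRNAs and the other
#'   biotypes to screen against.
#' @param seed_len Minimum run of consecutive exact matches (default 16).
#' @param max_mm Maximum substitutions over the full piRNA (default 2).
#' @return data.frame with one row per piRNA: `pirna_id`, `kept`,
#'   `hit_feature_id`, `hit_biotype`, `n_mismatch_at_hit` (hit fields `NA`
#'   when kept).
#' @export
filter_ambiguous_pirnas <- function(reference, seed_len = 16L, max_mm = 2L) {
  rec <- reference$records
  is_pi <- rec$biotype == "piRNA"
  pirnas <- rec[is_pi, , drop = FALSE]
  others <- rec[!is_pi, , drop = FALSE]
  empty <- data.frame(pirna_id = character(), kept = logical(),
                      hit_feature_id = character(), hit_biotype = character(),
                      n_mismatch_at_hit = integer(), stringsAsFactors = FALSE)
  if (nrow(pirnas) == 0) return(empty)
  if (any(nchar(pirnas$sequence) < seed_len)) {
    stop("seed_len exceeds the shortest piRNA length")
  }
  idx <- .build_seed_index(reference_set(others), k = seed_len)
  oth_prio <- .biotype_rank(others$biotype)
  oth_len <- nchar(others$sequence)

  out <- vector("list", nrow(pirnas))
  for (i in seq_len(nrow(pirnas))) {
    p <- pirnas$sequence[i]
    plen <- nchar(p)
    kms <- .kmers_of(p, seed_len)
    cand <- idx[data.table::data.table(kmer = kms, off = seq_along(kms) - 1L),
                on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    hit <- NULL
    if (nrow(cand)) {
      cand[, start0 := pos0 - off]
      cand <- unique(cand[, .(feature, start0)])
      cand <- cand[start0 >= 0L & start0 + plen <= oth_len[feature]]
      if (nrow(cand)) {
        praw <- charToRaw(p)
        keep_mm <- integer(nrow(cand))
        ok <- logical(nrow(cand))
        for (j in seq_len(nrow(cand))) {
          sub <- substr(others$sequence[cand$feature[j]],
                        cand$start0[j] + 1L, cand$start0[j] + plen)
          diff <- praw != charToRaw(sub)
          mm <- sum(diff)
          if (mm > max_mm) next
          ## longest run of consecutive exact matches
          runs <- rle(!diff)
          max_run <- if (any(runs$values)) max(runs$lengths[runs$values])
                     else 0L
          if (max_run >= seed_len) {
            ok[j] <- TRUE
            keep_mm[j] <- mm
          }
        }
        if (any(ok)) {
          cand <- cand[ok]
          cand[, mm := keep_mm[ok]]
          cand[, prio := oth_prio[feature]]
          cand[, feature_id := others$feature_id[feature]]
          data.table::setorder(cand, prio, feature_id)
          hit <- cand[1L]
        }
      }
    }
    out[[i]] <- if (is.null(hit)) {
      data.frame(pirna_id = pirnas$feature_id[i], kept = TRUE,
                 hit_feature_id = NA_character_, hit_biotype = NA_character_,
                 n_mismatch_at_hit = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(pirna_id = pirnas$feature_id[i], kept = FALSE,
                 hit_feature_id = hit$feature_id,
                 hit_biotype = others$biotype[hit$feature],
                 n_mismatch_at_hit = hit$mm, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
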