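## Read cleaning, read->feature assignment with mismatch tolerance, and
## count-matrix construction with the study's collapsing rules.

#' Clean a batch of reads (adapter, quality, length)
#'
#' Emulates a standard small RNA-seq cleaning stage: a 3' adapter is removed
#' when a prefix of at least 8 nt of the adapter matches the read's 3' end
#' exactly; trailing bases below `min_q` are then trimmed; finally reads
#' outside `[min_len, max_len]` are dropped.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (Phred+33).
#' @param adapter Optional 3' adapter sequence; `NULL` disables adapter
#'   trimming.
#' @param min_q Minimum Phred quality retained at the 3' end (default 20).
#' @param min_len,max_len Retained read length range (defaults 18 and 50).
#' @return List with `reads` (cleaned, same columns) and `tally`, a named
#'   integer vector of counts: `input`, `adapter_trimmed`,
#'   `quality_trimmed`, `too_short`, `too_long`, `passed`.
#' @export
preprocess_reads <- function(reads, adapter = NULL, min_q = 20L,
                             min_len = 18L, max_len = 50L) {
  seqs <- reads$sequence
  qual <- reads$quality
  n <- length(seqs)
  tally <- c(input = n, adapter_trimmed = 0L, quality_trimmed = 0L,
             too_short = 0L, too_long = 0L, passed = 0L)
  if (n == 0) return(list(reads = reads, tally = tally))

  rlen <- nchar(seqs)
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- toupper(chartr("Uu", "Tt", adapter))
    matched <- integer(n)  # matched prefix length, 0 = none
    for (k in seq(min(nchar(adapter), max(rlen)), 8L)) {
      todo <- matched == 0L & rlen >= k
      if (!any(todo)) next
      hit <- todo &
        substring(seqs, rlen - k + 1L, rlen) == substr(adapter, 1L, k)
      matched[hit] <- k
    }
    trim <- matched > 0L
    tally["adapter_trimmed"] <- sum(trim)
    rlen <- rlen - matched
    seqs[trim] <- substr(seqs[trim], 1L, rlen[trim])
    qual[trim] <- substr(qual[trim], 1L, rlen[trim])
  }

  if (min_q > 0L) {
    ## trailing run of bases with Phred < min_q (Phred+33 encoding)
    low_max <- 33L + as.integer(min_q) - 1L
    pat <- sprintf("[\\x21-\\x%02x]+$", low_max)
    m <- regexpr(pat, qual, perl = TRUE)
    has <- m > 0L
    tally["quality_trimmed"] <- sum(has)
    newlen <- ifelse(has, m - 1L, rlen)
    seqs[has] <- substr(seqs[has], 1L, newlen[has])
    qual[has] <- substr(qual[has], 1L, newlen[has])
    rlen <- as.integer(newlen)
  }

  short <- rlen < min_len
  long <- rlen > max_len
  tally["too_short"] <- sum(short)
  tally["too_long"] <- sum(long)
  keep <- !short & !long
  tally["passed"] <- sum(keep)
  out <- data.frame(read_id = reads$read_id[keep], sequence = seqs[keep],
                    quality = qual[keep], stringsAsFactors = FALSE)
  list(reads = out, tally = tally)
}

## seed index: every k-mer of every reference sequence -> (feature row, pos0)
.build_seed_index <- function(reference, k = 15L) {
  seqs <- reference$records$sequence
  lens <- nchar(seqs)
  n_k <- pmax(lens - k + 1L, 0L)
  fi <- rep.int(seq_along(seqs), n_k)
  pos0 <- sequence(n_k) - 1L
  dt <- data.table::data.table(
    kmer = substring(seqs[fi], pos0 + 1L, pos0 + k),
    feature = fi, pos0 = pos0)
  data.table::setkey(dt, kmer)
  dt
}

.count_mm_pairs <- function(a, b) {
  vapply(seq_along(a),
         function(i) sum(charToRaw(a[i]) != charToRaw(b[i])), integer(1))
}

#' Assign reads to reference features
#'
#' Finds, for each read, its best ungapped placement as a substring of any
#' reference feature with at most `max_mm` substitutions.  A placement
#' qualifies only when it contains a stretch of at least `seed_len`
#' consecutive exact matches (placements are located through an exact
#' `seed_len`-mer index and extended to the full read, so a read whose
#' mismatches break every `seed_len`-mer window is unassignable by
#' construction).  Ties are broken by fewest mismatches, then biotype
#' priority ([biotype_priority()]), then lexicographic feature id, then
#' smallest start.  The result does not depend on reference record order.
#'
#' @param reads data.frame with `read_id` and `sequence` (cleaned).
#' @param reference A `ReferenceSet`.
#' @param max_mm Maximum substitutions tolerated (default 2).
#' @param seed_len Exact seed length (default 15).
#' @return List with `assignments` (data.frame `read_id`, `feature_id`,
#'   `biotype`, `start`, `end` 0-based half-open, `n_mismatch`) and
#'   `unassigned` (data.frame `read_id`, `reason` in
#'   `{"no_placement", "too_short_for_seed"}`).
#' @export
assign_reads <- function(reads, reference, max_mm = 2L, seed_len = 15L) {
  rec <- reference$records
  empty_ass <- data.frame(read_id = character(), feature_id = character(),
                          biotype = character(), start = integer(),
                          end = integer(), n_mismatch = integer(),
                          stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    return(list(assignments = empty_ass,
                unassigned = data.frame(read_id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)))
  }
  useq <- unique(reads$sequence)
  ulen <- nchar(useq)
  too_short <- ulen < seed_len

  idx <- .build_seed_index(reference, seed_len)
  prio_by_feature <- .biotype_rank(rec$biotype)
  flen_by_feature <- nchar(rec$sequence)

  best <- NULL
  scan <- which(!too_short)
  if (length(scan)) {
    n_k <- ulen[scan] - seed_len + 1L
    rid <- rep.int(scan, n_k)
    off <- sequence(n_k) - 1L
    qdt <- data.table::data.table(
      kmer = substring(useq[rid], off + 1L, off + seed_len),
      read_idx = rid, off = off)
    cand <- idx[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(cand)) {
      cand[, start0 := pos0 - off]
      cand <- unique(cand[, .(read_idx, feature, start0)])
      cand[, rlen := ulen[read_idx]]
      cand <- cand[start0 >= 0L & start0 + rlen <= flen_by_feature[feature]]
      if (nrow(cand)) {
        ref_sub <- substr(rec$sequence[cand$feature], cand$start0 + 1L,
                          cand$start0 + cand$rlen)
        cand[, mm := .count_mm_pairs(useq[read_idx], ref_sub)]
        cand <- cand[mm <= max_mm]
        if (nrow(cand)) {
          cand[, prio := prio_by_feature[feature]]
          cand[, feature_id := rec$feature_id[feature]]
          data.table::setorder(cand, read_idx, mm, prio, feature_id, start0)
          best <- cand[, .SD[1L], by = read_idx]
        }
      }
    }
  }

  ass_u <- data.frame(read_idx = integer(), feature_id = character(),
                      biotype = character(), start = integer(),
                      end = integer(), n_mismatch = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(best) && nrow(best)) {
    ass_u <- data.frame(read_idx = best$read_idx,
                        feature_id = best$feature_id,
                        biotype = rec$biotype[best$feature],
                        start = best$start0,
                        end = best$start0 + best$rlen,
                        n_mismatch = best$mm, stringsAsFactors = FALSE)
  }

  ## expand unique-sequence results back to reads
  map <- match(reads$sequence, useq)
  hit <- match(map, ass_u$read_idx)
  assigned <- !is.na(hit)
  assignments <- data.frame(
    read_id = reads$read_id[assigned],
    feature_id = ass_u$feature_id[hit[assigned]],
    biotype = ass_u$biotype[hit[assigned]],
    start = ass_u$start[hit[assigned]],
    end = ass_u$end[hit[assigned]],
    n_mismatch = ass_u$n_mismatch[hit[assigned]],
    stringsAsFactors = FALSE)
  reason <- ifelse(too_short[map[!assigned]], "too_short_for_seed",
                   "no_placement")
  unassigned <- data.frame(read_id = reads$read_id[!assigned],
                           reason = reason, stringsAsFactors = FALSE)
  list(assignments = assignments, unassigned = unassigned)
}

#' Assign a single read
#'
#' Convenience wrapper around [assign_reads()] for one sequence.
#'
#' @param sequence Read sequence (character scalar).
#' @param reference A `ReferenceSet`.
#' @param max_mm,seed_len As in [assign_reads()].
#' @return A one-row assignment data.frame, or a zero-row one with
#'   attribute `reason` (`"no_placement"` or `"too_short_for_seed"`) when
#'   the read cannot be placed.
#' @export
assign_read <- function(sequence, reference, max_mm = 2L, seed_len = 15L) {
  res <- assign_reads(data.frame(read_id = "read1", sequence = sequence,
                                 stringsAsFactors = FALSE),
                      reference, max_mm = max_mm, seed_len = seed_len)
  if (nrow(res$assignments)) return(res$assignments)
  structure(res$assignments, reason = res$unassigned$reason[1])
}

#' Build a count matrix from per-sample assignments
#'
#' Collapsing rules mirror the study design: miRNA loci sharing an identical
#' mature sequence are merged (`mirna_sequence`), tRNA loci sharing an
#' anticodon are merged under the anticodon label (`trna_anticodon`), and
#' sno/sca/snRNAs are merged by RFAM-like family (`srna_family`).
#' Biotypes not targeted by the chosen mode pass through unchanged, so
#' column sums are preserved under every mode.
#'
#' @param assignments Named list of per-sample assignment data.frames (as
#'   returned by [assign_reads()]).
#' @param reference The `ReferenceSet` the assignments refer to.
#' @param collapse_mode One of "none", "mirna_sequence", "trna_anticodon",
#'   "srna_family".
#' @return Integer matrix (rows: feature or collapsed-group ids, columns:
#'   sample names) with attribute `collapse_mode`.
#' @export
build_count_matrix <- function(assignments, reference,
                               collapse_mode = c("none", "mirna_sequence",
                                                 "trna_anticodon",
                                                 "srna_family")) {
  collapse_mode <- match.arg(collapse_mode)
  rec <- reference$records
  row_key <- rec$feature_id
  if (collapse_mode == "mirna_sequence") {
    is_mi <- rec$biotype == "miRNA"
    grp <- rec$sequence[is_mi]
    reps <- vapply(split(rec$feature_id[is_mi], grp),
                   function(ids) sort(ids)[1], character(1))
    row_key[is_mi] <- reps[grp]
  } else if (collapse_mode == "trna_anticodon") {
    is_tr <- rec$biotype == "tRNA"
    if (any(is_tr & (is.na(rec$anticodon) | rec$anticodon == ""))) {
      bad <- rec$feature_id[is_tr & (is.na(rec$anticodon) |
                                       rec$anticodon == "")][1]
      stop("tRNA feature ", bad, " lacks an anticodon collapse key")
    }
    row_key[is_tr] <- rec$anticodon[is_tr]
  } else if (collapse_mode == "srna_family") {
    is_s <- rec$biotype %in% c("snoRNA", "scaRNA", "snRNA")
    if (any(is_s & (is.na(rec$family_id) | rec$family_id == ""))) {
      bad <- rec$feature_id[is_s & (is.na(rec$family_id) |
                                      rec$family_id == "")][1]
      stop("sRNA feature ", bad, " lacks a family_id collapse key")
    }
    row_key[is_s] <- rec$family_id[is_s]
  }
  key_by_feature <- setNames(row_key, rec$feature_id)
  row_ids <- unique(row_key)

  samples <- names(assignments)
  if (is.null(samples)) samples <- paste0("sample", seq_along(assignments))
  m <- matrix(0L, nrow = length(row_ids), ncol = length(assignments),
              dimnames = list(row_ids, samples))
  for (j in seq_along(assignments)) {
    a <- assignments[[j]]
    if (!nrow(a)) next
    keys <- key_by_feature[a$feature_id]
    if (anyNA(keys)) {
      stop("assignment refers to feature absent from the reference: ",
           a$feature_id[which(is.na(keys))[1]])
    }
    tab <- table(keys)
    m[names(tab), j] <- as.integer(tab)
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  attr(m, "collapse_mode") <- collapse_mode
  m
}

#' Biotype composition of assigned reads
#'
#' @param assignments Named list of per-sample assignment data.frames.
#' @return data.frame with one row per sample x biotype, columns `sample`,
#'   `biotype`, `n_reads`, `fraction`, `percent` (0.1% precision).
#'   Fractions sum to 1 within each sample.
#' @export
biotype_composition <- function(assignments) {
  samples <- names(assignments)
  out <- list()
  for (s in samples) {
    a <- assignments[[s]]
    if (nrow(a) == 0) stop("no assigned reads in sample ", s)
    tab <- table(factor(a$biotype, levels = .BIOTYPES))
    frac <- as.numeric(tab) / sum(tab)
    out[[s]] <- data.frame(sample = s, biotype = .BIOTYPES,
                           n_reads = as.integer(tab), fraction = frac,
                           percent = round(100 * frac, 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Read length histogram by biotype
#'
#' @param assignments Named list of per-sample assignment data.frames.
#' @return data.frame with columns `sample`, `biotype`, `length`, `count`.
#' @export
length_histogram <- function(assignments) {
  out <- list()
  for (s in names(assignments)) {
    a <- assignments[[s]]
    if (!nrow(a)) next
    len <- a$end - a$start
    agg <- aggregate(list(count = len),
                     by = list(biotype = a$biotype, length = len),
                     FUN = length)
    agg <- agg[order(agg$biotype, agg$length), ]
    out[[s]] <- data.frame(sample = s, biotype = agg$biotype,
                           length = agg$length, count = agg$count,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
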