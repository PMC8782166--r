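# Small in-code fixtures and independent oracle implementations.

# a tiny hand-built reference: one 22 nt miRNA and one 76 nt (pre-CCA) tRNA
mini_reference <- function() {
  set.seed(42)
  mir <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
  trna_body <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE),
                     collapse = "")
  reference_set(data.frame(
    feature_id = c("mir-test-5p", "tRNA-Gly-GCC"),
    biotype = c("miRNA", "tRNA"),
    sequence = c(mir, paste0(trna_body, "CCA")),
    anticodon = c(NA, "Gly-GCC"),
    anticodon_start = c(NA, 33L),
    has_cca = c(NA, TRUE),
    stringsAsFactors = FALSE))
}

reads_df <- function(seqs, qual = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  if (is.null(qual)) qual <- strrep("F", nchar(seqs))
  data.frame(read_id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

# brute-force oracles ---------------------------------------------------------

oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

oracle_n_top_share <- function(x, share = 0.8) {
  x <- sort(x, decreasing = TRUE)
  tot <- sum(x)
  acc <- 0
  for (k in seq_along(x)) {
    acc <- acc + x[k]
    if (acc / tot >= share - 1e-12) return(k)
  }
  length(x)
}

# numeric root of L(p) = 1 - p on the descending Lorenz polyline
oracle_evenness <- function(x) {
  x <- sort(x, decreasing = TRUE) / sum(x)
  n <- length(x)
  lorenz <- function(p) {
    if (p <= 0) return(0)
    k <- p * n
    i <- floor(k)
    base <- if (i >= 1) sum(x[seq_len(i)]) else 0
    frac <- k - i
    if (i < n) base + frac * x[i + 1] else base
  }
  f <- function(p) lorenz(p) - (1 - p)
  100 * uniroot(f, c(1e-12, 1), tol = 1e-13)$root
}

oracle_chi2 <- function(m) {
  s <- 0
  for (f in seq_len(nrow(m))) {
    mu <- mean(m[f, ])
    for (r in seq_len(ncol(m))) s <- s + (m[f, r] - mu)^2
  }
  s
}

# exhaustive ungapped placement scan over all features and offsets, using
# Biostrings as an independent alignment engine; same qualifying rule
# (<= max_mm substitutions containing >= seed_len consecutive exact
# matches) and tie-break order
oracle_assign <- function(sequence, reference, max_mm = 2L, seed_len = 15L,
                          subjects = NULL) {
  rec <- reference$records
  if (is.null(subjects)) subjects <- lapply(rec$sequence, Biostrings::DNAString)
  prio <- match(rec$biotype, biotype_priority())
  best <- NULL
  pat <- Biostrings::DNAString(sequence)
  praw <- charToRaw(sequence)
  rlen <- nchar(sequence)
  for (i in seq_len(nrow(rec))) {
    subj <- subjects[[i]]
    if (length(subj) < rlen) next
    starts <- seq_len(length(subj) - rlen + 1L)
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                      with.indels = FALSE)
    ok <- which(mm <= max_mm)
    for (s in ok) {
      sub <- substr(rec$sequence[i], s, s + rlen - 1L)
      same <- praw == charToRaw(sub)
      runs <- rle(same)
      max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
      if (max_run < seed_len) next
      cand <- list(feature_id = rec$feature_id[i], biotype = rec$biotype[i],
                   start = s - 1L, end = s - 1L + rlen,
                   n_mismatch = as.integer(mm[s]), prio = prio[i])
      if (is.null(best) ||
          cand$n_mismatch < best$n_mismatch ||
          (cand$n_mismatch == best$n_mismatch &&
           (cand$prio < best$prio ||
            (cand$prio == best$prio &&
             (cand$feature_id < best$feature_id ||
              (cand$feature_id == best$feature_id &&
               cand$start < best$start)))))) {
        best <- cand
      }
    }
  }
  best
}

# substring containment screen (the piRNA filter oracle at max_mm = 0)
oracle_pirna_substring <- function(reference) {
  rec <- reference$records
  pir <- rec[rec$biotype == "piRNA", ]
  oth <- rec[rec$biotype != "piRNA", ]
  vapply(pir$sequence,
         function(p) !any(grepl(p, oth$sequence, fixed = TRUE)),
         logical(1), USE.NAMES = FALSE)
}
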