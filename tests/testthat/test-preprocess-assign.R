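test_that("preprocess_reads applies adapter, quality and length rules", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"

  # clean 22 nt read passes unchanged
  r <- reads_df("ACGTACGTACGTACGTACGTAC")
  out <- preprocess_reads(r)
  expect_equal(out$reads$sequence, r$sequence)
  expect_equal(out$tally[["passed"]], 1L)

  # 30 nt insert + 10 nt adapter prefix -> adapter removed, insert kept
  insert <- strrep("ACGTG", 6)
  r <- reads_df(paste0(insert, substr(adapter, 1, 10)))
  out <- preprocess_reads(r, adapter = adapter)
  expect_equal(out$reads$sequence, insert)
  expect_equal(nchar(out$reads$sequence), 30L)
  expect_equal(out$tally[["adapter_trimmed"]], 1L)

  # adapter matches < 8 nt are left alone
  r <- reads_df(paste0(insert, substr(adapter, 1, 5)))
  out <- preprocess_reads(r, adapter = adapter)
  expect_equal(nchar(out$reads$sequence), 35L)

  # trailing low-quality bases trimmed ('#' = Q2), then length gate applies
  r <- reads_df(strrep("A", 25), qual = paste0(strrep("F", 20),
                                               strrep("#", 5)))
  out <- preprocess_reads(r)
  expect_equal(nchar(out$reads$sequence), 20L)

  # 17 nt after trimming -> dropped as too_short
  r <- reads_df(strrep("A", 20), qual = paste0(strrep("F", 17),
                                               strrep("#", 3)))
  out <- preprocess_reads(r)
  expect_equal(nrow(out$reads), 0)
  expect_equal(out$tally[["too_short"]], 1L)

  # > 50 nt dropped as too_long
  out <- preprocess_reads(reads_df(strrep("A", 51)))
  expect_equal(out$tally[["too_long"]], 1L)
})

test_that("assign_read recovers exact and mismatched placements", {
  ref <- mini_reference()
  mir <- ref$records$sequence[1]
  trna <- ref$records$sequence[2]

  # full miRNA mature sequence -> [0, 22), 0 mismatches
  a <- assign_read(mir, ref)
  expect_equal(a$feature_id, "mir-test-5p")
  expect_equal(c(a$start, a$end, a$n_mismatch), c(0L, 22L, 0L))

  # tRNA[0:33) with one substitution -> assigned with n_mismatch 1
  half <- substr(trna, 1, 33)
  pos <- 20
  sub <- setdiff(c("A", "C", "G", "T"), substr(half, pos, pos))[1]
  mut <- paste0(substr(half, 1, pos - 1), sub, substr(half, pos + 1, 33))
  a <- assign_read(mut, ref)
  expect_equal(a$feature_id, "tRNA-Gly-GCC")
  expect_equal(c(a$start, a$end, a$n_mismatch), c(0L, 33L, 1L))

  # too short for the seed
  a <- assign_read("ACGTACGTACGT", ref)
  expect_equal(nrow(a), 0)
  expect_equal(attr(a, "reason"), "too_short_for_seed")
})

test_that("ambiguous reads follow the biotype priority tie-break", {
  ref <- build_toy_reference(1)
  rec <- ref$records
  pir <- rec[rec$biotype == "piRNA", ]
  oth <- rec[rec$biotype != "piRNA", ]
  planted <- pir[vapply(pir$sequence,
                        function(p) any(grepl(p, oth$sequence, fixed = TRUE)),
                        logical(1)), ]
  # reads equal to planted piRNAs must be claimed by the host biotype
  res <- assign_reads(reads_df(planted$sequence), ref)
  expect_equal(nrow(res$assignments), nrow(planted))
  expect_true(all(res$assignments$biotype != "piRNA"))

  # a read equal to a free piRNA is assigned to that piRNA
  free <- pir[!pir$feature_id %in% planted$feature_id, ][1, ]
  a <- assign_read(free$sequence, ref)
  expect_equal(a$feature_id, free$feature_id)
})

test_that("assignment is invariant to reference record order", {
  ref <- build_toy_reference(1)
  set.seed(99)
  perm <- sample(nrow(ref$records))
  ref_perm <- reference_set(ref$records[perm, ], windows = ref$windows)
  pr <- default_profile("AX", ref, n_reads = 2000L, n_replicates = 1L,
                        seed = 3)
  rd <- simulate_library(pr, ref)$reads[[1]]
  a1 <- assign_reads(rd, ref)$assignments
  a2 <- assign_reads(rd, ref_perm)$assignments
  expect_equal(a1, a2)
})

test_that("assign_reads matches the exhaustive Biostrings oracle", {
  ref <- build_toy_reference(1)
  pr <- default_profile("WC", ref, n_reads = 1000L, n_replicates = 1L,
                        seed = 13, error_rate = 0.01)
  rd <- simulate_library(pr, ref)$reads[[1]]
  res <- assign_reads(rd, ref)
  got <- res$assignments
  found <- setNames(rep(FALSE, nrow(rd)), rd$read_id)
  found[got$read_id] <- TRUE
  subjects <- lapply(ref$records$sequence, Biostrings::DNAString)
  for (i in seq_len(nrow(rd))) {
    exp <- oracle_assign(rd$sequence[i], ref, subjects = subjects)
    if (is.null(exp)) {
      expect_false(found[[rd$read_id[i]]])
    } else {
      expect_true(found[[rd$read_id[i]]])
      row <- got[got$read_id == rd$read_id[i], ]
      expect_equal(row$feature_id, exp$feature_id)
      expect_equal(row$start, exp$start)
      expect_equal(row$n_mismatch, exp$n_mismatch)
    }
  }
})

test_that("error-free unique reads are recovered at the truth placement", {
  ref <- build_toy_reference(1)
  pr <- default_profile("AX", ref, n_reads = 20000L, n_replicates = 1L,
                        seed = 21)
  sim <- simulate_library(pr, ref)
  res <- assign_reads(sim$reads[[1]], ref)
  m <- merge(sim$truth, res$assignments, by = "read_id",
             suffixes = c(".truth", ".got"))
  ok <- m$n_errors == 0 & m$biotype.truth != "piRNA"
  rate <- mean(m$feature_id.truth[ok] == m$feature_id.got[ok] &
                 m$start.truth[ok] == m$start.got[ok] &
                 m$end.truth[ok] == m$end.got[ok])
  expect_gte(rate, 0.999)
})

test_that("count matrices respect collapsing rules and preserve totals", {
  # hand-built reference with collapsible groups
  seqs <- c(mirA = "ACGTTGCAACGGTACGATCGTA",
            mirB = "ACGTTGCAACGGTACGATCGTA",   # same mature sequence
            mirC = "TTTTGCAACGGTACGATCGTAC")
  set.seed(4)
  t1 <- paste(c(sample(c("A", "C", "G", "T"), 73, TRUE), "C", "C", "A"),
              collapse = "")
  t2 <- paste(c(sample(c("A", "C", "G", "T"), 73, TRUE), "C", "C", "A"),
              collapse = "")
  t3 <- paste(c(sample(c("A", "C", "G", "T"), 73, TRUE), "C", "C", "A"),
              collapse = "")
  sno <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  ref <- reference_set(data.frame(
    feature_id = c("mir-a", "mir-b", "mir-c", "trna-1", "trna-2", "trna-3",
                   "sno-1"),
    biotype = c("miRNA", "miRNA", "miRNA", "tRNA", "tRNA", "tRNA", "snoRNA"),
    sequence = c(seqs[["mirA"]], seqs[["mirB"]], seqs[["mirC"]],
                 t1, t2, t3, sno),
    family_id = c(NA, NA, NA, NA, NA, NA, "SNORD99"),
    anticodon = c(NA, NA, NA, "Gly-GCC", "Gly-GCC", "Gly-GCC", NA),
    anticodon_start = c(NA, NA, NA, 33L, 33L, 33L, NA),
    has_cca = c(NA, NA, NA, TRUE, TRUE, TRUE, NA),
    stringsAsFactors = FALSE))

  ass <- list(s1 = data.frame(
    read_id = sprintf("r%02d", 1:18),
    feature_id = c(rep("mir-a", 5), rep("mir-b", 7),
                   "trna-1", rep("trna-2", 2), rep("trna-3", 3)),
    biotype = c(rep("miRNA", 12), rep("tRNA", 6)),
    start = 0L, end = 22L, n_mismatch = 0L, stringsAsFactors = FALSE))

  m_none <- build_count_matrix(ass, ref, "none")
  expect_equal(sum(m_none[, "s1"]), 18)
  expect_equal(nrow(m_none), 5)  # features with >= 1 read

  # identical-sequence miRNA loci merge: 5 + 7 = 12
  m_mir <- build_count_matrix(ass, ref, "mirna_sequence")
  expect_equal(m_mir["mir-a", "s1"], 12L)
  expect_false("mir-b" %in% rownames(m_mir))

  # anticodon-sharing tRNA loci merge: 1 + 2 + 3 = 6
  m_tr <- build_count_matrix(ass, ref, "trna_anticodon")
  expect_equal(m_tr["Gly-GCC", "s1"], 6L)

  # column sums invariant under every collapse mode
  for (mode in c("none", "mirna_sequence", "trna_anticodon",
                 "srna_family")) {
    expect_equal(sum(build_count_matrix(ass, ref, mode)), 18)
  }

  # missing collapse key is a hard error naming the feature
  ref_bad <- ref
  ref_bad$records$anticodon[4] <- NA
  expect_error(build_count_matrix(ass, ref_bad, "trna_anticodon"), "trna-1")
})

test_that("biotype composition and length histograms are exact", {
  ass <- list(s1 = data.frame(
    read_id = sprintf("r%03d", 1:100),
    feature_id = c(rep("mir-x", 70), rep("trna-x", 30)),
    biotype = c(rep("miRNA", 70), rep("tRNA", 30)),
    start = 0L, end = c(rep(22L, 70), rep(33L, 30)),
    n_mismatch = 0L, stringsAsFactors = FALSE))
  comp <- biotype_composition(ass)
  expect_equal(comp$percent[comp$biotype == "miRNA"], 70)
  expect_equal(comp$percent[comp$biotype == "tRNA"], 30)
  expect_equal(sum(comp$fraction), 1)

  lh <- length_histogram(ass)
  expect_equal(lh$count[lh$biotype == "miRNA" & lh$length == 22], 70)
  expect_equal(lh$count[lh$biotype == "tRNA" & lh$length == 33], 30)
  expect_equal(sum(lh$count), 100)

  expect_error(
    biotype_composition(list(empty = ass$s1[0, ])), "empty")
})

test_that("compartment length profiles show the expected modal lengths", {
  ref <- build_toy_reference(1)
  modal <- function(cmp) {
    pr <- default_profile(cmp, ref, n_reads = 30000L, n_replicates = 1L,
                          seed = 17)
    rd <- simulate_library(pr, ref)$reads[[1]]
    ass <- assign_reads(preprocess_reads(rd)$reads, ref)$assignments
    lh <- length_histogram(list(x = ass))
    tot <- tapply(lh$count, lh$length, sum)
    as.integer(names(tot)[which.max(tot)])
  }
  expect_equal(modal("WC"), 22L)  # miRNA-dominated
  expect_equal(modal("AX"), 33L)  # 5'-tRNA-half-dominated
})
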