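test_that("toy reference construction is deterministic and as designed", {
  ref1 <- build_toy_reference(1)
  ref2 <- build_toy_reference(1)
  expect_identical(ref1$records, ref2$records)
  expect_identical(ref1$windows, ref2$windows)

  rec <- ref1$records
  tab <- table(rec$biotype)
  expect_gte(tab[["miRNA"]], 200)
  expect_equal(tab[["tRNA"]], 40)
  expect_equal(tab[["piRNA"]], 30)
  expect_true(all(c("mir-10a-5p", "mir-10b-5p", "let-7c-5p", "snord104",
                    "snord39", "U1", "U2", "U6", "RNY1", "RNY3") %in%
                    rec$feature_id))

  # every tRNA ends with the appended CCA tail
  trna <- rec[rec$biotype == "tRNA", ]
  expect_true(all(substr(trna$sequence, nchar(trna$sequence) - 2,
                         nchar(trna$sequence)) == "CCA"))
  expect_true(all(trna$has_cca))
  expect_true(all(nchar(trna$sequence) - 3 >= 73 &
                    nchar(trna$sequence) - 3 <= 76))

  # exactly 10 piRNAs are verbatim substrings of other-biotype records
  pir <- rec[rec$biotype == "piRNA", ]
  oth <- rec[rec$biotype != "piRNA", ]
  planted <- vapply(pir$sequence,
                    function(p) any(grepl(p, oth$sequence, fixed = TRUE)),
                    logical(1))
  expect_equal(sum(planted), 10)

  # no two non-piRNA features share a 16-mer
  kmers <- unlist(lapply(oth$sequence, function(s) {
    n <- nchar(s) - 15L
    substring(s, 1:n, 16:nchar(s))
  }))
  expect_false(anyDuplicated(kmers) > 0)
})

test_that("simulated libraries are deterministic with exact ground truth", {
  ref <- build_toy_reference(1)
  pr <- default_profile("WC", ref, n_reads = 5000L, n_replicates = 2L,
                        seed = 7)
  sim1 <- simulate_library(pr, ref)
  sim2 <- simulate_library(pr, ref)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$truth, sim2$truth)

  # written FASTQ is byte-identical between runs
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(sim1$reads[[1]], f1)
  write_fastq(sim2$reads[[1]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # n_reads = 0 -> empty library
  pr0 <- default_profile("WC", ref, n_reads = 0L, n_replicates = 1L)
  sim0 <- simulate_library(pr0, ref)
  expect_equal(nrow(sim0$reads[[1]]), 0)
  expect_equal(nrow(sim0$truth), 0)

  # every error-free read is an exact substring of its source feature
  tr <- sim1$truth[sim1$truth$replicate == 1, ]
  rd <- sim1$reads[[1]]
  ef <- tr$n_errors == 0
  src <- ref$records$sequence[match(tr$feature_id, ref$records$feature_id)]
  expect_true(all(substr(src[ef], tr$start[ef] + 1, tr$end[ef]) ==
                    rd$sequence[ef]))

  # truth coordinates stay inside the feature
  expect_true(all(tr$start >= 0 & tr$start < tr$end &
                    tr$end <= nchar(src)))
})

test_that("tsRNA truth classes respect the tRF/tRH length bands", {
  ref <- build_toy_reference(1)
  for (cmp in c("WC", "AXOPLASM")) {
    pr <- default_profile(cmp, ref, n_reads = 20000L, n_replicates = 1L,
                          seed = 5)
    tr <- simulate_library(pr, ref)$truth
    ts <- tr[tr$biotype == "tRNA", ]
    len <- ts$end - ts$start
    half <- ts$tsrna_class %in% c("tRH5", "tRH3")
    frag <- ts$tsrna_class %in% c("tRF5", "tRF3", "tRF3CCA", "tRFmisc")
    expect_true(all(len[half] >= 29 & len[half] <= 50))
    expect_true(all(len[frag] >= 14 & len[frag] <= 30))
  }
})

test_that("truth-table biotype tallies converge to the profile weights", {
  ref <- build_toy_reference(1)
  pr <- default_profile("WC", ref, n_reads = 200000L, n_replicates = 1L,
                        seed = 2)
  tr <- simulate_library(pr, ref)$truth
  emp <- table(tr$biotype) / nrow(tr)
  for (b in names(pr$biotype_weights)) {
    expect_lt(abs(emp[[b]] - pr$biotype_weights[[b]]), 0.01)
  }
})

test_that("a profile naming an unknown feature fails before sampling", {
  ref <- build_toy_reference(1)
  pr <- default_profile("WC", ref, n_reads = 10L, n_replicates = 1L)
  pr$feature_weights$miRNA <- c("not-a-feature" = 1)
  expect_error(simulate_library(pr, ref), "not-a-feature")
})

test_that("profile weight validation rejects malformed mixtures", {
  ref <- build_toy_reference(1)
  pr <- default_profile("WC", ref)
  expect_error(
    compartment_profile("x", biotype_weights = c(miRNA = 0.5, tRNA = 0.4),
                        feature_weights = pr$feature_weights),
    "sum to 1")
  expect_error(
    compartment_profile("x", biotype_weights = pr$biotype_weights,
                        feature_weights = pr$feature_weights,
                        error_rate = 0.5),
    "error_rate")
})
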