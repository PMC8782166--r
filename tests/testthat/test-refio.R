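test_that("load_reference handles the identity case and a toy fixture", {
  fa <- withr::local_tempfile(fileext = ".fa")
  ann <- withr::local_tempfile(fileext = ".tsv")

  # empty inputs -> empty ReferenceSet
  file.create(fa)
  writeLines(paste(c("feature_id", "biotype", "family_id", "anticodon",
                     "anticodon_start", "has_cca", "precursor_id",
                     "species_tag", "notes"), collapse = "\t"), ann)
  ref0 <- load_reference(fa, ann)
  expect_s3_class(ref0, "ReferenceSet")
  expect_equal(nrow(ref0$records), 0)

  # two-record toy: one miRNA, one tRNA (U in input converted to T)
  mini <- mini_reference()
  mir_seq <- chartr("T", "U", mini$records$sequence[1])
  writeLines(c(">mir-test-5p", mir_seq,
               ">tRNA-Gly-GCC", mini$records$sequence[2]), fa)
  rows <- c(paste(c("mir-test-5p", "miRNA", "", "", "", "", "pre-mir-test",
                    "mmu", ""), collapse = "\t"),
            paste(c("tRNA-Gly-GCC", "tRNA", "", "Gly-GCC", "33", "TRUE", "",
                    "mmu", ""), collapse = "\t"))
  writeLines(c(paste(c("feature_id", "biotype", "family_id", "anticodon",
                       "anticodon_start", "has_cca", "precursor_id",
                       "species_tag", "notes"), collapse = "\t"), rows), ann)
  ref <- load_reference(fa, ann)
  expect_equal(nrow(ref$records), 2)
  expect_equal(length(by_biotype(ref)$miRNA), 1)
  expect_equal(ref$records$sequence[1], mini$records$sequence[1])  # U -> T
  expect_true(ref$records$has_cca[2])
})

test_that("load_reference rejects invalid inputs naming the offender", {
  fa <- withr::local_tempfile(fileext = ".fa")
  ann <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("feature_id", "biotype", "family_id", "anticodon",
                 "anticodon_start", "has_cca", "precursor_id",
                 "species_tag", "notes"), collapse = "\t")

  # tRNA without anticodon_start
  writeLines(c(">tRNA-x", strrep("ACGT", 20)), fa)
  writeLines(c(hdr, paste(c("tRNA-x", "tRNA", "", "Gly-GCC", "", "TRUE", "",
                            "", ""), collapse = "\t")), ann)
  expect_error(load_reference(fa, ann), "tRNA-x")

  # unknown biotype string
  writeLines(c(hdr, paste(c("tRNA-x", "wrongtype", "", "", "", "", "", "",
                            ""), collapse = "\t")), ann)
  expect_error(load_reference(fa, ann), "wrongtype")

  # annotation row without sequence
  writeLines(c(hdr,
               paste(c("tRNA-x", "miRNA", "", "", "", "", "", "", ""),
                     collapse = "\t"),
               paste(c("ghost", "miRNA", "", "", "", "", "", "", ""),
                     collapse = "\t")), ann)
  expect_error(load_reference(fa, ann), "ghost")

  # duplicate ids
  writeLines(c(">dup", strrep("ACGT", 6), ">dup", strrep("GTCA", 6)), fa)
  writeLines(c(hdr, paste(c("dup", "miRNA", "", "", "", "", "", "", ""),
                          collapse = "\t")), ann)
  expect_error(load_reference(fa, ann), "dup")
})

test_that("reference FASTA/annotation round trip is lossless and stable", {
  ref <- build_toy_reference(3)
  fa <- withr::local_tempfile(fileext = ".fa")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_reference(ref, fa, ann)
  back <- load_reference(fa, ann)
  expect_equal(back$records$feature_id, ref$records$feature_id)
  expect_equal(back$records$sequence, ref$records$sequence)
  expect_equal(back$records$biotype, ref$records$biotype)
  expect_equal(back$records$anticodon_start, ref$records$anticodon_start)
  # loading twice gives identical objects (order-stable, deterministic)
  expect_identical(back$records, load_reference(fa, ann)$records)
})

test_that("FASTQ round trip preserves ids, sequences and qualities", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- reads_df(c(strrep("ACGT", 8), "ACGTACGTACGTACGTACGTAC"),
                    qual = c(strrep("I", 32), strrep("F", 22)))
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, reads)

  # single record, all 'I' -> Q40 across 22 bases
  one <- reads_df("ACGTACGTACGTACGTACGTAC", qual = strrep("I", 22))
  write_fastq(one, fq)
  got <- read_fastq(fq)
  expect_equal(nchar(got$quality), 22L)
  expect_true(all(utf8ToInt(got$quality) - 33L == 40L))

  # empty file -> empty frame
  file.create(fq2 <- withr::local_tempfile(fileext = ".fastq"))
  expect_equal(nrow(read_fastq(fq2)), 0)
})

test_that("count matrix TSV round trip preserves values", {
  m <- matrix(c(1, 5, 0, 7, 2, 9), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, p)
  expect_equal(read_count_matrix(p), m)
})
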