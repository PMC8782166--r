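test_that("base coverage obeys interval arithmetic and conservation", {
  feature <- list(feature_id = "RNY1", sequence = strrep("A", 100))
  a <- function(starts, ends) data.frame(
    read_id = sprintf("r%02d", seq_along(starts)), feature_id = "RNY1",
    biotype = "YRNA", start = starts, end = ends, n_mismatch = 0L,
    stringsAsFactors = FALSE)

  # one read [0, 22)
  cov <- base_coverage(a(0L, 22L), feature)
  expect_equal(cov$coverage[1:22], rep(1L, 22))
  expect_equal(sum(cov$coverage), 22)

  # two overlapping reads [0,30) and [10,40): depths 1 / 2 / 1
  cov <- base_coverage(a(c(0L, 10L), c(30L, 40L)), feature)
  expect_equal(unique(cov$coverage[1:10]), 1)
  expect_equal(unique(cov$coverage[11:30]), 2)
  expect_equal(unique(cov$coverage[31:40]), 1)
  expect_equal(sum(cov$coverage), 60)

  # conservation: sum of coverage equals summed read lengths
  set.seed(2)
  st <- sample(0:70, 50, replace = TRUE)
  en <- st + sample(18:30, 50, replace = TRUE)
  cov <- base_coverage(a(st, en), feature)
  expect_equal(sum(cov$coverage), sum(en - st))
})

test_that("fragment peaks are disjoint, sorted and arm-labelled", {
  feature <- list(feature_id = "RNY1", sequence = strrep("A", 99))
  mk <- function(starts, ends) data.frame(
    read_id = sprintf("r%03d", seq_along(starts)),
    feature_id = rep("RNY1", length(starts)),
    biotype = rep("YRNA", length(starts)), start = starts, end = ends,
    n_mismatch = rep(0L, length(starts)), stringsAsFactors = FALSE)

  # all 5'-anchored reads -> one five_prime peak
  a5 <- mk(rep(0L, 20), rep(30L, 20))
  pk <- call_fragments(base_coverage(a5, feature), a5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$arm, "five_prime")
  expect_equal(pk$read_share, 1)

  # equal 5'/3' mix -> two peaks, five_prime then three_prime
  mix <- mk(c(rep(0L, 10), rep(69L, 10)), c(rep(30L, 10), rep(99L, 10)))
  pk <- call_fragments(base_coverage(mix, feature), mix)
  expect_equal(pk$arm, c("five_prime", "three_prime"))
  expect_true(all(diff(pk$start) > 0))
  expect_true(all(pk$end[-nrow(pk)] <= pk$start[-1]))
  expect_equal(pk$read_share, c(0.5, 0.5))

  # zero coverage -> empty
  pk0 <- call_fragments(base_coverage(mk(integer(), integer()), feature))
  expect_equal(nrow(pk0), 0)
})

test_that("EV libraries prefer the RNY1 5' arm", {
  ref <- build_toy_reference(1)
  pr <- default_profile("EV", ref, n_reads = 50000L, n_replicates = 1L,
                        seed = 23)
  rd <- simulate_library(pr, ref)$reads[[1]]
  ass <- assign_reads(rd, ref)$assignments
  ay <- ass[ass$feature_id == "RNY1", ]
  frow <- ref$records[ref$records$feature_id == "RNY1", ]
  pk <- call_fragments(base_coverage(ay, frow), ay, threshold_frac = 0.1)
  s5 <- pk$read_share[pk$arm == "five_prime"]
  s3 <- pk$read_share[pk$arm == "three_prime"]
  expect_true(length(s5) == 1 && length(s3) == 1)
  expect_gt(s5, s3)
})

test_that("miRNA ids collapse to cross-species precursor bases", {
  expect_equal(collapse_mirna_base(c("mmu-miR-10a-5p", "rno-miR-10a-5p")),
               c("miR-10a", "miR-10a"))
  expect_equal(collapse_mirna_base("miR-26a-2-3p"), "miR-26a")
  expect_equal(collapse_mirna_base("xla-let-7c"), "let-7c")
  expect_equal(collapse_mirna_base("miR-10a", collapse_paralogs = TRUE),
               "miR-10")
})

test_that("signature intersection finds the planted core", {
  set.seed(31)
  mk_counts <- function(ids, reads) {
    m <- matrix(rep(reads, 3) + rpois(3 * length(reads), 1),
                ncol = 3, dimnames = list(ids, paste0("r", 1:3)))
    m
  }
  core_ids <- sprintf("miR-c%02d", 1:23)
  a_only <- sprintf("miR-a%02d", 1:5)
  b_only <- sprintf("miR-b%02d", 1:4)
  low <- sprintf("miR-lo%02d", 1:6)       # below threshold everywhere
  d <- function(name, extra) list(
    name = name,
    counts = mk_counts(c(paste0("mmu-", core_ids, "-5p"), extra, low),
                       c(rep(50, 23), rep(50, length(extra)),
                         rep(1, length(low)))),
    min_threshold = 10, threshold_units = "reads")
  datasets <- list(d("A", a_only), d("B", b_only),
                   list(name = "C",
                        counts = mk_counts(paste0("rno-", core_ids, "-3p"),
                                           rep(30, 23)),
                        min_threshold = 10, threshold_units = "reads"))
  sig <- signature_intersection(datasets)
  expect_equal(sig$core, 23)
  expect_equal(sig$venn$count[sig$venn$pattern == "A&B&C"], 23)
  expect_equal(sig$venn$count[sig$venn$pattern == "A"], 5)

  # symmetric in dataset order
  sig_rev <- signature_intersection(rev(datasets))
  expect_equal(sig_rev$core, 23)

  # two identical datasets: intersection equals union
  two <- signature_intersection(datasets[c(1, 1)])
  expect_equal(two$core, nrow(two$membership))

  expect_error(signature_intersection(
    list(list(name = "A", counts = mk_counts("miR-1", 5),
              min_threshold = 1, threshold_units = "bananas"),
         datasets[[2]])), "bananas")
})

test_that("motif scanning matches IUPAC classes and is monotone", {
  seqs <- c(m1 = "UUGGAGCC", m2 = "ACGTACGTACG", m3 = "CCCCCCCC")
  ab <- c(m1 = 100, m2 = 10, m3 = 1)

  res <- motif_scan(seqs, motifs = "GGAG", abundance = ab, k = 2)
  expect_equal(res$hits$mirna_id, "m1")
  expect_equal(res$hits$start, 2L)      # 0-based position

  # NNNN matches every sequence of length >= 4
  res_n <- motif_scan(seqs, motifs = "NNNN", abundance = ab, k = 3)
  expect_true(all(res_n$per_mirna$any_hit))

  # empty motif list -> zero hits
  res_0 <- motif_scan(seqs, motifs = character(), abundance = ab)
  expect_equal(nrow(res_0$hits), 0)
  expect_false(any(res_0$per_mirna$any_hit))

  # extending the motif list never loses hits
  r1 <- motif_scan(seqs, motifs = "GGAG", abundance = ab)
  r2 <- motif_scan(seqs, motifs = c("GGAG", "ACGT"), abundance = ab)
  expect_true(all(r2$per_mirna$n_hits >= r1$per_mirna$n_hits))

  # degenerate IUPAC classes: ACGT matches RYSW; invalid symbols error
  rr <- motif_scan(c(x = "AACGTT"), motifs = "RYSW", abundance = c(x = 1))
  expect_equal(rr$hits$start, 1L)
  expect_error(motif_scan(seqs, motifs = "GG#G", abundance = ab), "GG#G")
})
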