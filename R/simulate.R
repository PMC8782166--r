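## Synthetic-data generator: a toy multi-biotype ncRNA reference and
## compartment-specific small RNA-seq libraries with full ground truth.
##
## The default compartment profiles encode the compositions observed in the
## study system this package models: whole-cell (WC) libraries dominated by
## 22 nt miRNA reads, axonal (AX) and extracellular-vesicle (EV) libraries
## dominated by 5' tRNA halves with 33/30 nt length peaks, and adult
## axoplasm (AXOPLASM) libraries dominated by rRNA fragments and 3' tRNA
## halves.

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.kmers_of <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character())
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

.TRNA_ANTICODONS <- c(
  "Gly-GCC", "Val-CAC", "Val-AAC", "Glu-CTC", "Glu-TTC", "Lys-CTT",
  "Ser-GCT", "His-GTG", "Gly-CCC", "Gly-TCC", "Ala-AGC", "Ala-TGC",
  "Arg-ACG", "Arg-TCT", "Asn-GTT", "Asp-GTC", "Cys-GCA", "Gln-CTG",
  "Gln-TTG", "Ile-AAT", "Ile-TAT", "Leu-AAG", "Leu-CAG", "Leu-TAA",
  "Lys-TTT", "Met-CAT", "Phe-GAA", "Pro-AGG", "Pro-TGG", "Ser-AGA",
  "Ser-TGA", "Thr-AGT", "Thr-TGT", "Trp-CCA", "Tyr-GTA", "Val-TAC",
  "Arg-CCT", "Leu-CAA", "Pro-CGG", "Ser-CGA")

.SNRNA_NAMES <- c("U1", "U2", "U4", "U5", "U6", "U7", "U11", "U12",
                  "U4atac", "U6atac")

#' Build the deterministic toy ncRNA reference
#'
#' Constructs a small but structurally complete reference: 200 miRNAs
#' (22 nt; including mir-10a-5p, mir-10b-5p and let-7c-5p), 40 parental
#' tRNAs (73-76 nt mature sequence plus CCA, anticodon at offset 32, one
#' locus per anticodon), 20 snoRNAs (including snord104 and snord39), 10
#' snRNAs (U1, U2, U6, ...), 5 rRNA source segments, 2 Y RNAs (RNY1, RNY3),
#' 1 vault RNA, 5 protein-coding fragments and 30 piRNAs of which exactly 10
#' are verbatim 26-30 nt substrings of tRNA/rRNA/snoRNA records (planted
#' cross-mapping ambiguity for the piRNA filter).  No two non-piRNA features
#' share a 16-mer, so error-free reads of at least 18 nt place uniquely.
#'
#' Stable fragment windows (the processed fragments of sno/sca/snRNAs,
#' Y RNAs and the vault RNA) are fixed here and stored in the returned
#' object's `windows` table.
#'
#' @param seed Integer seed; the construction is fully deterministic given
#'   the seed.
#' @return A `ReferenceSet` with a `windows` table.
#' @export
build_toy_reference <- function(seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  registry <- new.env(hash = TRUE, parent = emptyenv())
  register16 <- function(seq) {
    for (km in .kmers_of(seq, 16L)) assign(km, TRUE, envir = registry)
  }
  clashes16 <- function(seq) {
    any(vapply(.kmers_of(seq, 16L), exists, logical(1), envir = registry))
  }
  fresh_seq <- function(n) {
    repeat {
      s <- .rand_seq(n)
      if (!clashes16(s)) return(s)
    }
  }

  rows <- list()
  add <- function(feature_id, biotype, sequence, family_id = NA,
                  anticodon = NA, anticodon_start = NA, has_cca = NA,
                  precursor_id = NA, species_tag = "mmu", notes = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = feature_id, biotype = biotype, sequence = sequence,
      family_id = as.character(family_id), anticodon = as.character(anticodon),
      anticodon_start = as.integer(anticodon_start),
      has_cca = as.logical(has_cca),
      precursor_id = as.character(precursor_id),
      species_tag = species_tag, notes = as.character(notes),
      stringsAsFactors = FALSE)
  }

  ## tRNAs: mature body 73-76 nt, anticodon at fixed offset 32, CCA appended
  for (ac in .TRNA_ANTICODONS) {
    body_len <- sample(73:76, 1L)
    seq <- paste0(fresh_seq(body_len), "CCA")
    register16(seq)
    add(paste0("tRNA-", ac), "tRNA", seq, anticodon = ac,
        anticodon_start = 32L, has_cca = TRUE)
  }

  ## miRNAs: 22 nt mature sequences
  mirna_names <- c("mir-10a-5p", "mir-10b-5p", "let-7c-5p",
                   sprintf("mir-sim%03d-5p", 4:200))
  for (nm in mirna_names) {
    seq <- fresh_seq(22L)
    register16(seq)
    add(nm, "miRNA", seq, precursor_id = sub("-5p$", "", nm))
  }

  ## snoRNAs (RFAM-like family = own name)
  sno_names <- c("snord104", "snord39", sprintf("snord-sim-%02d", 3:20))
  for (nm in sno_names) {
    seq <- fresh_seq(sample(65:90, 1L))
    register16(seq)
    add(nm, "snoRNA", seq, family_id = nm)
  }

  ## snRNAs
  for (nm in .SNRNA_NAMES) {
    seq <- fresh_seq(sample(100:160, 1L))
    register16(seq)
    add(nm, "snRNA", seq, family_id = nm)
  }

  ## rRNA source segments
  rrna_names <- c("rRNA-5S", "rRNA-5.8S", "rRNA-18S-seg1", "rRNA-18S-seg2",
                  "rRNA-28S-seg1")
  for (nm in rrna_names) {
    seq <- fresh_seq(sample(120:180, 1L))
    register16(seq)
    add(nm, "rRNA", seq)
  }

  ## Y RNAs and vault RNA
  for (nm in c("RNY1", "RNY3")) {
    seq <- fresh_seq(sample(95:105, 1L))
    register16(seq)
    add(nm, "YRNA", seq)
  }
  vt_seq <- fresh_seq(100L)
  register16(vt_seq)
  add("vtRNA-1", "vtRNA", vt_seq)

  ## protein-coding fragments
  for (i in 1:5) {
    seq <- fresh_seq(sample(140:180, 1L))
    register16(seq)
    add(sprintf("pc-sim-%d", i), "protein_coding", seq)
  }

  rec <- do.call(rbind, rows)

  ## piRNAs: 10 planted as verbatim substrings of tRNA/rRNA/snoRNA records,
  ## 20 free (sharing no 16-mer with any other feature)
  hosts <- rec[rec$biotype %in% c("tRNA", "rRNA", "snoRNA"), ]
  host_pick <- hosts[sample(nrow(hosts), 10L, replace = FALSE), ]
  pirna_rows <- list()
  for (i in 1:10) {
    plen <- sample(26:30, 1L)
    hseq <- host_pick$sequence[i]
    start <- sample(0:(nchar(hseq) - plen), 1L)
    pseq <- substr(hseq, start + 1L, start + plen)
    pirna_rows[[i]] <- data.frame(
      feature_id = sprintf("pirna-sim-%02d", i), biotype = "piRNA",
      sequence = pseq, family_id = NA_character_, anticodon = NA_character_,
      anticodon_start = NA_integer_, has_cca = NA, precursor_id = NA_character_,
      species_tag = "mmu", notes = paste0("planted:", host_pick$feature_id[i]),
      stringsAsFactors = FALSE)
  }
  for (i in 11:30) {
    pseq <- fresh_seq(sample(26:30, 1L))
    register16(pseq)
    pirna_rows[[i]] <- data.frame(
      feature_id = sprintf("pirna-sim-%02d", i), biotype = "piRNA",
      sequence = pseq, family_id = NA_character_, anticodon = NA_character_,
      anticodon_start = NA_integer_, has_cca = NA, precursor_id = NA_character_,
      species_tag = "mmu", notes = NA_character_, stringsAsFactors = FALSE)
  }
  rec <- rbind(rec, do.call(rbind, pirna_rows))

  ## designated fragment windows for the stable-fragment biotypes
  win <- list()
  add_win <- function(feature_id, window_id, start, end, weight) {
    win[[length(win) + 1L]] <<- data.frame(
      feature_id = feature_id, window_id = window_id,
      start = as.integer(start), end = as.integer(end), weight = weight,
      stringsAsFactors = FALSE)
  }
  for (i in which(rec$biotype == "snoRNA")) {
    L <- nchar(rec$sequence[i]); id <- rec$feature_id[i]
    add_win(id, paste0(id, ":5p"), 0L, 20L, 0.5)
    add_win(id, paste0(id, ":3p"), L - 22L, L, 0.5)
  }
  for (i in which(rec$biotype == "snRNA")) {
    L <- nchar(rec$sequence[i]); id <- rec$feature_id[i]
    ## two internal processed regions (Sm-site-like), 22 nt each
    add_win(id, paste0(id, ":frag1"), 8L, 30L, 0.6)
    add_win(id, paste0(id, ":frag2"), min(40L, L - 25L), min(62L, L - 3L), 0.4)
  }
  for (i in which(rec$biotype == "YRNA")) {
    L <- nchar(rec$sequence[i]); id <- rec$feature_id[i]
    add_win(id, paste0(id, ":5p"), 0L, 31L, 0.5)
    add_win(id, paste0(id, ":3p"), L - 30L, L, 0.5)
  }
  for (i in which(rec$biotype == "vtRNA")) {
    id <- rec$feature_id[i]
    add_win(id, paste0(id, ":frag1"), 3L, 33L, 1.0)
  }
  windows <- do.call(rbind, win)

  reference_set(rec, windows = windows)
}

## ---------------------------------------------------------------------------
## Compartment profiles

.pmf <- function(x) x / sum(x)

.tri_pmf <- function(lengths, peak) {
  w <- pmax(0, max(abs(lengths - peak)) + 1 - abs(lengths - peak))
  setNames(.pmf(w), lengths)
}

.default_length_models <- function() {
  list(
    tRF5    = .tri_pmf(18:26, 21),
    tRF3    = .tri_pmf(18:24, 20),
    tRF3CCA = .tri_pmf(18:24, 21),
    tRFmisc = setNames(.pmf(rep(1, 13)), 18:30),
    generic = .tri_pmf(20:34, 28),
    ## offset of the tRH5 3' cut (and tRH3 5' cut) relative to the anticodon
    ## middle; peaked at 0 so the modal tRNA-half length is 33 nt
    tRH_jitter = setNames(.pmf(c(.10, .20, .34, .22, .14)), -2:2)
  )
}

#' Construct a compartment profile for the read generator
#'
#' @param name Compartment label (e.g. "WC", "AX", "EV", "AXOPLASM").
#' @param biotype_weights Named numeric, fractions per biotype (sum 1).
#' @param feature_weights Named list: for each biotype, named fractions over
#'   feature ids (sum 1 within the biotype).
#' @param tsrna_class_mix Named fractions over the six tsRNA classes (sum 1).
#' @param length_models List of discrete pmfs: `tRF5`, `tRF3`, `tRF3CCA`,
#'   `tRFmisc` and `generic` over fragment lengths (nt), and `tRH_jitter`
#'   over the cut offset relative to the anticodon middle.
#' @param window_weights Optional named numeric overriding the reference's
#'   designated-window weights (names are `window_id`s; weights are
#'   renormalized within each feature).
#' @param error_rate Per-base substitution probability, in \[0, 0.1\].
#' @param n_reads Reads per replicate.
#' @param n_replicates Number of replicate libraries.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @return A `CompartmentProfile`.
#' @export
compartment_profile <- function(name, biotype_weights, feature_weights,
                                tsrna_class_mix = NULL,
                                length_models = .default_length_models(),
                                window_weights = NULL,
                                error_rate = 0.001, n_reads = 200000L,
                                n_replicates = 3L, seed = 1L) {
  chk_pmf <- function(w, what) {
    if (any(w < 0)) stop(what, " has negative weights")
    if (abs(sum(w) - 1) > 1e-9) stop(what, " weights do not sum to 1")
  }
  chk_pmf(biotype_weights, "biotype")
  for (b in names(feature_weights)) {
    chk_pmf(feature_weights[[b]], paste0("feature (", b, ")"))
  }
  if (!is.null(tsrna_class_mix)) {
    tsrna_class_mix <- tsrna_class_mix[.TSRNA_CLASSES]
    tsrna_class_mix[is.na(tsrna_class_mix)] <- 0
    names(tsrna_class_mix) <- .TSRNA_CLASSES
    chk_pmf(tsrna_class_mix, "tsRNA class")
  }
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]")
  }
  if (n_reads < 0) stop("n_reads must be non-negative")
  structure(list(name = name, biotype_weights = biotype_weights,
                 feature_weights = feature_weights,
                 tsrna_class_mix = tsrna_class_mix,
                 length_models = length_models,
                 window_weights = window_weights,
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "CompartmentProfile")
}

#' @export
print.CompartmentProfile <- function(x, ...) {
  cat("CompartmentProfile", x$name, "-", x$n_replicates, "replicate(s) x",
      x$n_reads, "reads, error rate", x$error_rate, "\n")
  bw <- sort(x$biotype_weights, decreasing = TRUE)
  cat("  biotypes:", paste0(names(bw), "=", signif(bw, 3), collapse = " "),
      "\n")
  invisible(x)
}

## feature-weight helpers -----------------------------------------------------

.weights_on <- function(ids, named_weights, rest_total) {
  w <- setNames(rep(0, length(ids)), ids)
  w[names(named_weights)] <- named_weights
  rest <- setdiff(ids, names(named_weights))
  if (length(rest)) w[rest] <- rest_total / length(rest)
  .pmf(w)
}

## miRNA weights designed so about 30 miRNAs carry 80% of miRNA reads:
## ranks 1-10 at .04, ranks 11-30 at .02, the remaining 170 share .20.
.mirna_weights_n80_30 <- function(mirna_ids) {
  ord <- c("let-7c-5p",
           setdiff(mirna_ids, c("let-7c-5p", "mir-10a-5p", "mir-10b-5p")),
           c("mir-10a-5p", "mir-10b-5p"))
  w <- c(rep(0.04, 10), rep(0.02, 20), rep(0.20 / 170, 170))
  setNames(w, ord)
}

## AX/EV parental tRNA weights designed so the N80 statistic is 15:
## top-14 cumulative share .79 < .80 <= top-15 share .81.
.trna_weights_n80_15 <- function() {
  heads <- c("Gly-GCC" = 0.30, "Val-CAC" = 0.15, "Val-AAC" = 0.12)
  mids <- setNames(rep(0.02, 12),
                   c("Glu-CTC", "Lys-CTT", "Ser-GCT", "His-GTG", "Gly-CCC",
                     "Ala-AGC", "Arg-ACG", "Asn-GTT", "Asp-GTC", "Cys-GCA",
                     "Gln-CTG", "Ile-AAT"))
  rest <- setdiff(.TRNA_ANTICODONS, c(names(heads), names(mids)))
  c(heads, mids, setNames(rep(0.19 / length(rest), length(rest)), rest))
}

.trna_feature_weights <- function(anticodon_weights) {
  setNames(as.numeric(anticodon_weights),
           paste0("tRNA-", names(anticodon_weights)))
}

#' Default compartment profiles
#'
#' Shipped generative parameters for the four compartments the package
#' models.  Whole-cell (WC): 68% miRNA / 15% tRNA with a 70% 5'-tRH tsRNA
#' mix; axon (AX): 70% tRNA with 90% 5'-tRHs and a 33 nt length peak;
#' extracellular vesicles (EV): 90% tRNA, 90% 5'-tRHs with 30/33 nt length
#' peaks and the snord104 5' fragment carrying 60% of the sRNA pool; adult
#' axoplasm (AXOPLASM): rRNA-dominated (55%) with a 3'-half-shifted tsRNA
#' mix (40% 3'-tRHs), miR-10a/b-5p at a combined 35% of miRNA reads, and an
#' sRNA pool at 95.5% snRNA (U2 68%, U1 12%, U6 6%).
#'
#' @param name One of "WC", "AX", "EV", "AXOPLASM".
#' @param reference The `ReferenceSet` the profile will be used with
#'   (feature weights are spread over its feature ids); defaults to the toy
#'   reference at seed 1.
#' @param n_reads Reads per replicate (default 200000).
#' @param n_replicates Replicates; defaults to 3 (2 for AXOPLASM, matching
#'   the paired motor/sensory nerve design).
#' @param seed Base seed for the generator.
#' @param error_rate Per-base substitution probability.
#' @return A `CompartmentProfile`.
#' @export
default_profile <- function(name = c("WC", "AX", "EV", "AXOPLASM"),
                            reference = NULL, n_reads = 200000L,
                            n_replicates = NULL, seed = 1L,
                            error_rate = 0.001) {
  name <- match.arg(name)
  if (is.null(reference)) reference <- build_toy_reference(1L)
  ids <- by_biotype(reference)
  mirna_w <- .mirna_weights_n80_30(ids$miRNA)
  lm <- .default_length_models()

  if (name == "WC") {
    bw <- c(miRNA = .68, tRNA = .15, rRNA = .08, snoRNA = .025, snRNA = .015,
            YRNA = .02, vtRNA = .005, piRNA = .005, protein_coding = .02)
    trna_w <- .weights_on(
      .TRNA_ANTICODONS,
      c("Gly-GCC" = .08, "Val-CAC" = .06, "Val-AAC" = .05, "Glu-CTC" = .06,
        "Glu-TTC" = .05), rest_total = .70)
    mix <- c(tRF5 = .05, tRH5 = .70, tRH3 = .05, tRF3 = .10, tRF3CCA = .05,
             tRFmisc = .05)
    sno_w <- .weights_on(ids$snoRNA, c(snord104 = .25, snord39 = .15), .60)
    snrna_w <- .weights_on(ids$snRNA, c(U1 = .35, U2 = .35, U6 = .05), .25)
    ww <- NULL
  } else if (name == "AX") {
    bw <- c(tRNA = .70, miRNA = .08, rRNA = .10, snRNA = .06, snoRNA = .02,
            YRNA = .02, vtRNA = .005, piRNA = .005, protein_coding = .01)
    trna_w <- .trna_weights_n80_15()
    mix <- c(tRF5 = .03, tRH5 = .90, tRH3 = .02, tRF3 = .02, tRF3CCA = .01,
             tRFmisc = .02)
    sno_w <- .weights_on(ids$snoRNA, c(snord104 = .20, snord39 = .15), .65)
    snrna_w <- .weights_on(ids$snRNA, c(U1 = .25, U2 = .51, U6 = .06), .18)
    ww <- NULL
  } else if (name == "EV") {
    bw <- c(tRNA = .90, miRNA = .04, rRNA = .01, snoRNA = .02, snRNA = .01,
            YRNA = .015, vtRNA = .002, piRNA = .002, protein_coding = .001)
    trna_w <- .trna_weights_n80_15()
    mix <- c(tRF5 = .04, tRH5 = .90, tRH3 = .01, tRF3 = .02, tRF3CCA = .01,
             tRFmisc = .02)
    ## snord104 5' fragment accumulates ~60% of the combined sno+snRNA pool:
    ## snoRNA biotype carries 2/3 of that pool, snord104 carries .9 of it.
    sno_w <- .weights_on(ids$snoRNA, c(snord104 = .90), .10)
    snrna_w <- .weights_on(ids$snRNA, c(U1 = .25, U2 = .40, U6 = .05), .30)
    ## EV tRNA halves show a secondary 30 nt peak; EVs prefer the RNY1 5' arm
    lm$tRH_jitter <- setNames(.pmf(c(.34, .06, .10, .28, .14, .08)), -3:2)
    ww <- c("RNY1:5p" = .85, "RNY1:3p" = .15, "snord104:5p" = .95,
            "snord104:3p" = .05)
  } else { # AXOPLASM
    ## printed biotype shares 55 / 41 / 4.2 plus a small sRNA pool,
    ## renormalized to 1
    bw <- .pmf(c(rRNA = .55, tRNA = .41, miRNA = .042,
                 snRNA = .008 * .955, snoRNA = .008 * .045, YRNA = .002))
    trna_w <- .weights_on(
      .TRNA_ANTICODONS,
      c("Lys-CTT" = .36, "Ser-GCT" = .11, "His-GTG" = .10), rest_total = .43)
    mix <- c(tRF5 = .03, tRH5 = .15, tRH3 = .40, tRF3 = .25, tRF3CCA = .12,
             tRFmisc = .05)
    mirna_w <- .weights_on(ids$miRNA,
                           c("mir-10a-5p" = .20, "mir-10b-5p" = .15), .65)
    sno_w <- .weights_on(ids$snoRNA, c(snord39 = .30), .70)
    ## U2 68%, U1 12%, U6 6% of sRNA reads; snRNA carries .955 of the pool
    snrna_w <- .pmf(.weights_on(ids$snRNA,
                                c(U2 = .68, U1 = .12, U6 = .06), .095))
    ww <- NULL
    if (is.null(n_replicates)) n_replicates <- 2L
  }
  if (is.null(n_replicates)) n_replicates <- 3L

  fw <- list(
    miRNA = mirna_w,
    tRNA = .trna_feature_weights(trna_w),
    rRNA = if (length(ids$rRNA)) setNames(.pmf(c(3, 2, 2, 2, 1)), ids$rRNA),
    snoRNA = sno_w,
    snRNA = snrna_w,
    YRNA = if (length(ids$YRNA)) setNames(c(.6, .4), c("RNY1", "RNY3")),
    vtRNA = if (length(ids$vtRNA)) setNames(1, ids$vtRNA),
    piRNA = if (length(ids$piRNA))
      setNames(rep(1 / length(ids$piRNA), length(ids$piRNA)), ids$piRNA),
    protein_coding = if (length(ids$protein_coding))
      setNames(rep(1 / length(ids$protein_coding),
                   length(ids$protein_coding)), ids$protein_coding)
  )
  fw <- fw[names(fw) %in% names(bw)]

  compartment_profile(name = name, biotype_weights = bw,
                      feature_weights = fw, tsrna_class_mix = mix,
                      length_models = lm, window_weights = ww,
                      error_rate = error_rate, n_reads = n_reads,
                      n_replicates = n_replicates, seed = seed)
}

## ---------------------------------------------------------------------------
## Library simulation

.sample_pmf <- function(pmf, n) {
  as.integer(sample(as.integer(names(pmf)), n, replace = TRUE, prob = pmf))
}

#' Simulate compartment-specific small RNA-seq libraries
#'
#' Draws reads per replicate according to the profile: biotype, then feature
#' within biotype; tRNA reads additionally draw a tsRNA class and are cut by
#' the class rule (halves at the anticodon loop with a small jitter,
#' fragments anchored at the 5'/3' termini, optionally through the CCA
#' tail); stable-fragment biotypes emit their designated windows; remaining
#' biotypes emit internal windows with lengths from the `generic` model.
#' Substitution errors are injected at `error_rate`; all bases carry
#' constant quality Q37.  Replicate r is seeded with `seed + r - 1`, so a
#' given profile always yields byte-identical libraries.
#'
#' @param profile A `CompartmentProfile`.
#' @param reference A `ReferenceSet` containing every feature the profile
#'   references (checked before any sampling).
#' @return List with `reads` (one data.frame of `read_id`, `sequence`,
#'   `quality` per replicate, named `<name>_rep<k>`) and `truth` (data.frame
#'   with `read_id`, `replicate`, `feature_id`, `biotype`, `tsrna_class`,
#'   `start`, `end` (0-based half-open on the mature feature, CCA included
#'   where applicable) and `n_errors`).
#' @export
simulate_library <- function(profile, reference) {
  stopifnot(inherits(profile, "CompartmentProfile"),
            inherits(reference, "ReferenceSet"))
  rec <- reference$records
  all_ids <- unlist(lapply(profile$feature_weights, names), use.names = FALSE)
  unknown <- setdiff(all_ids, rec$feature_id)
  if (length(unknown)) {
    stop("profile references unknown feature(s): ",
         paste(head(unknown, 3), collapse = ", "))
  }
  fid2row <- setNames(seq_len(nrow(rec)), rec$feature_id)
  seq_full <- rec$sequence
  len_full <- nchar(seq_full)
  pre_cca <- len_full - ifelse(isTRUE_vec(rec$has_cca), 3L, 0L)

  win <- reference$windows
  win_w <- NULL
  if (!is.null(win)) {
    win_w <- win$weight
    if (!is.null(profile$window_weights)) {
      idx <- match(names(profile$window_weights), win$window_id)
      win_w[idx[!is.na(idx)]] <- profile$window_weights[!is.na(idx)]
    }
  }
  lm <- profile$length_models
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  reads <- list()
  truth <- list()
  for (r in seq_len(profile$n_replicates)) {
    set.seed(profile$seed + r - 1L)
    n <- profile$n_reads
    if (n == 0L) {
      nm <- sprintf("%s_rep%d", profile$name, r)
      reads[[nm]] <- data.frame(read_id = character(), sequence = character(),
                                quality = character(),
                                stringsAsFactors = FALSE)
      next
    }
    bw <- profile$biotype_weights
    bio <- sample(names(bw), n, replace = TRUE, prob = bw)
    feat <- character(n)
    for (b in unique(bio)) {
      sel <- bio == b
      fwb <- profile$feature_weights[[b]]
      if (is.null(fwb)) stop("profile has no feature weights for biotype ", b)
      feat[sel] <- sample(names(fwb), sum(sel), replace = TRUE, prob = fwb)
    }
    row <- fid2row[feat]
    L <- pre_cca[row]           # pre-CCA mature length
    full <- len_full[row]
    start <- integer(n)
    end <- integer(n)
    cls <- rep(NA_character_, n)

    is_tr <- bio == "tRNA"
    if (any(is_tr)) {
      k <- sum(is_tr)
      cls[is_tr] <- sample(names(profile$tsrna_class_mix), k, replace = TRUE,
                           prob = profile$tsrna_class_mix)
      a0 <- rec$anticodon_start[row][is_tr]
      mid <- a0 + 1L
      cl <- cls[is_tr]
      s <- integer(k); e <- integer(k)
      Lt <- L[is_tr]; fullt <- full[is_tr]
      for (cc in unique(cl)) {
        j <- cl == cc
        m <- sum(j)
        if (cc == "tRH5") {
          s[j] <- 0L
          e[j] <- mid[j] + .sample_pmf(lm$tRH_jitter, m)
        } else if (cc == "tRF5") {
          s[j] <- 0L
          ln <- .sample_pmf(lm$tRF5, m)
          ln <- pmin(ln, a0[j] - 5L)   # end stays below the anticodon loop
          e[j] <- ln
        } else if (cc == "tRH3") {
          thru <- sample(c(0L, 3L), m, replace = TRUE)
          e[j] <- Lt[j] + thru
          s[j] <- mid[j] + .sample_pmf(lm$tRH_jitter, m)
        } else if (cc == "tRF3") {
          e[j] <- Lt[j]
          s[j] <- Lt[j] - .sample_pmf(lm$tRF3, m)
        } else if (cc == "tRF3CCA") {
          e[j] <- fullt[j]
          s[j] <- fullt[j] - .sample_pmf(lm$tRF3CCA, m)
        } else { # tRFmisc: internal window away from both termini
          ln <- .sample_pmf(lm$tRFmisc, m)
          lo <- 3L
          hi <- Lt[j] - ln - 3L
          s[j] <- lo + floor(runif(m) * (hi - lo + 1L))
          e[j] <- s[j] + ln
        }
      }
      start[is_tr] <- s; end[is_tr] <- e
    }

    is_full <- bio %in% c("miRNA", "piRNA")
    start[is_full] <- 0L
    end[is_full] <- full[is_full]

    is_win <- bio %in% .WINDOWED_BIOTYPES
    if (any(is_win)) {
      if (is.null(win)) stop("reference has no designated fragment windows")
      for (f in unique(feat[is_win])) {
        j <- which(is_win & feat == f)
        wrows <- which(win$feature_id == f)
        if (!length(wrows)) stop("no fragment window for feature ", f)
        pick <- wrows[sample.int(length(wrows), length(j), replace = TRUE,
                                 prob = win_w[wrows])]
        start[j] <- win$start[pick]
        end[j] <- win$end[pick]
      }
    }

    is_gen <- !(is_tr | is_full | is_win)
    if (any(is_gen)) {
      m <- sum(is_gen)
      ln <- .sample_pmf(lm$generic, m)
      ln <- pmin(ln, full[is_gen])
      s <- floor(runif(m) * (full[is_gen] - ln + 1L))
      start[is_gen] <- as.integer(s)
      end[is_gen] <- as.integer(s) + ln
    }

    seqs <- substr(seq_full[row], start + 1L, end)
    rl <- end - start
    n_err <- rbinom(n, size = rl, prob = profile$error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(rl[i], n_err[i])
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    ids <- sprintf("%s_rep%d_%07d", profile$name, r, seq_len(n))
    nm <- sprintf("%s_rep%d", profile$name, r)
    reads[[nm]] <- data.frame(read_id = ids, sequence = seqs,
                              quality = strrep("F", rl),
                              stringsAsFactors = FALSE)
    truth[[nm]] <- data.frame(read_id = ids, replicate = r,
                              feature_id = feat, biotype = bio,
                              tsrna_class = cls, start = start, end = end,
                              n_errors = n_err, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
           else data.frame(read_id = character(), replicate = integer(),
                           feature_id = character(), biotype = character(),
                           tsrna_class = character(), start = integer(),
                           end = integer(), n_errors = integer(),
                           stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}
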