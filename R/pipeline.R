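## End-to-end orchestration: simulate (or load) libraries, clean, assign,
## count, classify, filter, normalize, and emit the full table bundle under
## a run directory.  All outputs are plain TSV and re-derivable from the
## assignments alone; reruns with the same configuration are byte-identical.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory for the run.
#' @param profiles List of `CompartmentProfile`s to simulate, or `NULL`
#'   when supplying `fastq_paths`.
#' @param fastq_paths Optional named list: sample name -> FASTQ path (used
#'   instead of simulation).
#' @param reference A `ReferenceSet`; defaults to [build_toy_reference()]
#'   at `seed`.
#' @param seed Global seed recorded in the manifest and used for the
#'   default reference.
#' @param adapter Optional 3' adapter for [preprocess_reads()].
#' @param min_q,min_len,max_len Read-cleaning parameters.
#' @param max_mm,seed_len Assignment parameters.
#' @param tol5,tol3,loop_halfwidth tsRNA-classifier parameters.
#' @param pirna_seed_len,pirna_max_mm piRNA-filter parameters.
#' @param quantile_p,min_cpm Normalization/filter parameters.
#' @param motifs Sorting motifs for [motif_scan()].
#' @param coverage_features Feature ids to profile with [base_coverage()].
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir, profiles = NULL, fastq_paths = NULL,
                            reference = NULL, seed = 1L, adapter = NULL,
                            min_q = 20L, min_len = 18L, max_len = 50L,
                            max_mm = 2L, seed_len = 15L, tol5 = 1L,
                            tol3 = 1L, loop_halfwidth = 4L,
                            pirna_seed_len = 16L, pirna_max_mm = 2L,
                            quantile_p = 0.75, min_cpm = 1,
                            motifs = c("GGAG", "UGCA", "CAUG", "GUAG"),
                            coverage_features = c("RNY1", "U2")) {
  if (is.null(profiles) && is.null(fastq_paths)) {
    stop("either profiles (simulate) or fastq_paths must be given")
  }
  structure(list(out_dir = out_dir, profiles = profiles,
                 fastq_paths = fastq_paths, reference = reference,
                 seed = as.integer(seed), adapter = adapter, min_q = min_q,
                 min_len = min_len, max_len = max_len, max_mm = max_mm,
                 seed_len = seed_len, tol5 = tol5, tol3 = tol3,
                 loop_halfwidth = loop_halfwidth,
                 pirna_seed_len = pirna_seed_len,
                 pirna_max_mm = pirna_max_mm, quantile_p = quantile_p,
                 min_cpm = min_cpm, motifs = motifs,
                 coverage_features = coverage_features),
            class = "PipelineConfig")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Replicate similarity: Pearson correlation and principal components
#'
#' @param counts Count matrix (features x samples).
#' @return List with `correlation` (Pearson correlation of
#'   `log2(counts + 1)` between samples) and `pca` (sample coordinates on
#'   the principal components of the same transform, via singular value
#'   decomposition).
#' @export
replicate_similarity <- function(counts) {
  x <- log2(as.matrix(counts) + 1)
  keep <- apply(x, 1, function(r) sd(r) > 0)
  pc <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  list(correlation = cor(x, method = "pearson"),
       pca = pc$x)
}

#' Run the full sncRNA landscape pipeline
#'
#' Simulates (or reads) the configured libraries, then runs cleaning,
#' assignment, count-matrix construction at every collapse mode, biotype
#' composition, length histograms, tsRNA classification tables, the piRNA
#' cross-mapping filter, upper-quartile normalization with CPM output,
#' pairwise differential expression between sample groups, per-biotype
#' diversity statistics, coverage profiles with fragment peaks for the
#' configured features, a cross-group miRNA signature intersection,
#' a sorting-motif summary and a replicate-similarity block
#' (correlations + principal components).  All tables are written as TSV
#' under `out_dir`, plus a `manifest.txt` echoing the seed and parameters.
#'
#' @param config A `PipelineConfig`.
#' @return Invisibly, a list with the main in-memory results (assignments,
#'   count matrices, tables, file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- config$reference
  if (is.null(ref)) ref <- build_toy_reference(config$seed)

  stage <- "simulate"
  res <- tryCatch({
    ## ---- acquire reads
    reads_by_sample <- list()
    groups <- character()
    if (!is.null(config$profiles)) {
      for (pr in config$profiles) {
        sim <- simulate_library(pr, ref)
        for (nm in names(sim$reads)) {
          reads_by_sample[[nm]] <- sim$reads[[nm]]
          groups[nm] <- pr$name
        }
      }
    } else {
      for (nm in names(config$fastq_paths)) {
        reads_by_sample[[nm]] <- read_fastq(config$fastq_paths[[nm]])
        groups[nm] <- sub("_rep[0-9]+$", "", nm)
      }
    }

    ## ---- clean + assign
    stage <- "preprocess_assign"
    assignments <- list()
    tallies <- list()
    for (nm in names(reads_by_sample)) {
      pp <- preprocess_reads(reads_by_sample[[nm]], adapter = config$adapter,
                             min_q = config$min_q, min_len = config$min_len,
                             max_len = config$max_len)
      tallies[[nm]] <- data.frame(sample = nm, t(pp$tally),
                                  stringsAsFactors = FALSE)
      ass <- assign_reads(pp$reads, ref, max_mm = config$max_mm,
                          seed_len = config$seed_len)
      assignments[[nm]] <- ass$assignments
      .write_tsv(ass$assignments,
                 file.path(out_dir, paste0("assignments_", nm, ".tsv")))
    }
    .write_tsv(do.call(rbind, c(tallies, make.row.names = FALSE)),
               file.path(out_dir, "preprocess_tally.tsv"))

    ## ---- counts, composition, lengths
    stage <- "count"
    counts <- list()
    for (mode in c("none", "mirna_sequence", "trna_anticodon",
                   "srna_family")) {
      counts[[mode]] <- build_count_matrix(assignments, ref,
                                           collapse_mode = mode)
      write_count_matrix(counts[[mode]],
                         file.path(out_dir, paste0("counts_", mode, ".tsv")))
    }
    comp <- biotype_composition(assignments)
    .write_tsv(comp, file.path(out_dir, "biotype_composition.tsv"))
    lh <- length_histogram(assignments)
    .write_tsv(lh, file.path(out_dir, "length_histogram.tsv"))

    ## ---- tsRNA classification
    stage <- "tsrna"
    calls <- lapply(assignments, classify_tsrna_reads, reference = ref,
                    tol5 = config$tol5, tol3 = config$tol3,
                    loop_halfwidth = config$loop_halfwidth)
    has_tsrna <- vapply(calls, nrow, integer(1)) > 0
    tsrna_tabs <- NULL
    if (any(has_tsrna)) {
      tsrna_tabs <- tsrna_class_table(calls[has_tsrna])
      .write_tsv(tsrna_tabs$classes,
                 file.path(out_dir, "tsrna_classes.tsv"))
      .write_tsv(tsrna_tabs$parental,
                 file.path(out_dir, "tsrna_parental.tsv"))
    }

    ## ---- piRNA filter
    stage <- "pirna_filter"
    verdicts <- filter_ambiguous_pirnas(ref,
                                        seed_len = config$pirna_seed_len,
                                        max_mm = config$pirna_max_mm)
    .write_tsv(verdicts, file.path(out_dir, "pirna_verdicts.tsv"))

    ## ---- normalization + DE + diversity
    stage <- "normalize_de"
    norm <- uq_normalize(counts$none, quantile_p = config$quantile_p)
    .write_tsv(norm$factors, file.path(out_dir, "norm_factors.tsv"))
    write_count_matrix(round(norm$cpm, 4), file.path(out_dir, "cpm.tsv"))
    de_tables <- list()
    glv <- unique(groups)
    if (length(glv) >= 2 &&
        all(table(groups)[glv] >= 2)) {
      keep <- filter_cpm(norm$cpm, groups[colnames(norm$cpm)],
                         min_cpm = config$min_cpm)
      for (i in seq_along(glv)) for (j in seq_along(glv)) {
        if (j <= i) next
        sel <- groups[colnames(norm$cpm)] %in% glv[c(i, j)]
        de <- nb_exact_de(counts$none[keep, sel, drop = FALSE],
                          groups[colnames(norm$cpm)][sel])
        nm <- paste0(glv[i], "_vs_", glv[j])
        de_tables[[nm]] <- de
        .write_tsv(de, file.path(out_dir, paste0("de_", nm, ".tsv")))
      }
    }
    stage <- "diversity"
    feat_bio <- ref$records$biotype[match(rownames(norm$cpm),
                                          ref$records$feature_id)]
    div <- diversity_stats(norm$cpm, feat_bio,
                           groups[colnames(norm$cpm)])
    .write_tsv(div, file.path(out_dir, "diversity_stats.tsv"))

    ## ---- coverage + peaks
    stage <- "coverage"
    cov_rows <- list()
    peak_rows <- list()
    for (f in config$coverage_features) {
      frow <- ref$records[ref$records$feature_id == f, , drop = FALSE]
      if (!nrow(frow)) next
      for (nm in names(assignments)) {
        a <- assignments[[nm]]
        a <- a[a$feature_id == f, , drop = FALSE]
        prof <- base_coverage(a, frow)
        cov_rows[[paste(f, nm)]] <- data.frame(
          sample = nm, feature_id = f,
          position = seq_along(prof$coverage) - 1L,
          depth = prof$coverage, stringsAsFactors = FALSE)
        if (max(prof$coverage) > 0) {
          pk <- call_fragments(prof, a)
          if (nrow(pk)) {
            peak_rows[[paste(f, nm)]] <- data.frame(sample = nm, pk,
                                                    stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(cov_rows)) {
      .write_tsv(do.call(rbind, c(cov_rows, make.row.names = FALSE)),
                 file.path(out_dir, "coverage.tsv"))
    }
    if (length(peak_rows)) {
      .write_tsv(do.call(rbind, c(peak_rows, make.row.names = FALSE)),
                 file.path(out_dir, "fragment_peaks.tsv"))
    }

    ## ---- miRNA signature across groups + motif summary
    stage <- "signature"
    signature <- NULL
    mir_counts <- counts$mirna_sequence
    mir_ids <- intersect(rownames(mir_counts),
                         ref$records$feature_id[ref$records$biotype ==
                                                  "miRNA"])
    if (length(glv) >= 2 && length(mir_ids)) {
      datasets <- lapply(glv, function(g) {
        list(name = g,
             counts = mir_counts[mir_ids, groups[colnames(mir_counts)] == g,
                                 drop = FALSE],
             min_threshold = 5, threshold_units = "reads")
      })
      signature <- signature_intersection(datasets)
      .write_tsv(signature$membership,
                 file.path(out_dir, "signature_membership.tsv"))
      .write_tsv(signature$venn, file.path(out_dir, "signature_venn.tsv"))
    }
    motif <- NULL
    if (length(mir_ids)) {
      mseq <- setNames(
        ref$records$sequence[match(mir_ids, ref$records$feature_id)],
        mir_ids)
      ab <- rowMeans(mir_counts[mir_ids, , drop = FALSE])
      motif <- motif_scan(mseq, config$motifs, ab)
      .write_tsv(motif$summary, file.path(out_dir, "motif_summary.tsv"))
    }

    ## ---- replicate similarity
    stage <- "similarity"
    sim <- replicate_similarity(counts$none)
    .write_tsv(data.frame(sample = rownames(sim$correlation),
                          round(sim$correlation, 6), check.names = FALSE),
               file.path(out_dir, "replicate_correlation.tsv"))
    .write_tsv(data.frame(sample = rownames(sim$pca),
                          round(sim$pca, 6), check.names = FALSE),
               file.path(out_dir, "pca_coordinates.tsv"))

    ## ---- manifest
    stage <- "manifest"
    par_names <- c("seed", "min_q", "min_len", "max_len", "max_mm",
                   "seed_len", "tol5", "tol3", "loop_halfwidth",
                   "pirna_seed_len", "pirna_max_mm", "quantile_p",
                   "min_cpm")
    manifest <- c(
      paste0("sncscape_version\t", as.character(packageVersion("sncscape"))),
      paste0(par_names, "\t",
             vapply(config[par_names], function(v) paste(v, collapse = ","),
                    character(1))),
      paste0("samples\t", paste(names(assignments), collapse = ",")),
      paste0("groups\t", paste(unique(groups), collapse = ",")))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))

    list(reference = ref, groups = groups, assignments = assignments,
         counts = counts, composition = comp, length_histogram = lh,
         tsrna = tsrna_tabs, pirna_verdicts = verdicts, norm = norm,
         de = de_tables, diversity = div, signature = signature,
         motif = motif, similarity = sim, out_dir = out_dir)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage ", stage, ": ",
                      conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
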