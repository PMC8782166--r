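## Reference data model and standard-format I/O (FASTA, FASTQ, TSV).
##
## A ReferenceSet holds mature ncRNA sequences together with the annotation
## fields the downstream modules need: biotype, RFAM-like family, tRNA
## anticodon and its offset, CCA status, miRNA precursor and species tag.
## All feature-internal coordinates are 0-based, half-open; sequences are
## stored uppercase in the DNA (T) alphabet, with U converted on read.

.ANNOT_COLUMNS <- c("feature_id", "biotype", "family_id", "anticodon",
                    "anticodon_start", "has_cca", "precursor_id",
                    "species_tag", "notes")

#' Construct a ReferenceSet
#'
#' @param records data.frame with columns `feature_id`, `biotype`,
#'   `sequence` and optionally `family_id`, `anticodon`, `anticodon_start`
#'   (0-based), `has_cca`, `precursor_id`, `species_tag`, `notes`.
#' @param windows Optional data.frame of designated fragment windows
#'   (`feature_id`, `window_id`, `start`, `end`, `weight`), 0-based
#'   half-open, used by the synthetic read generator for biotypes that shed
#'   stable processed fragments (sno/sca/snRNA, Y RNA, vault RNA).
#' @return An object of class `ReferenceSet`.
#' @export
reference_set <- function(records, windows = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("feature_id", "biotype", "sequence"),
                          names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.ANNOT_COLUMNS, names(records))) {
    records[[col]] <- rep(if (col == "has_cca") NA else NA_character_,
                          nrow(records))
  }
  records$sequence <- toupper(chartr("Uu", "Tt", records$sequence))
  records$anticodon_start <- suppressWarnings(
    as.integer(records$anticodon_start))
  records$has_cca <- as.logical(records$has_cca)
  rownames(records) <- NULL
  ref <- structure(list(records = records, windows = windows),
                   class = "ReferenceSet")
  validate_reference(ref)
  ref
}

#' Validate ReferenceSet invariants
#'
#' Checks sequence alphabet and minimum length, feature id uniqueness, known
#' biotypes, and the tRNA-specific requirements (anticodon metadata present
#' and within the pre-CCA mature sequence).
#'
#' @param ref A `ReferenceSet`.
#' @return `ref`, invisibly; errors name the offending feature.
#' @export
validate_reference <- function(ref) {
  rec <- ref$records
  dup <- rec$feature_id[duplicated(rec$feature_id)]
  if (length(dup)) {
    stop("duplicate feature_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_bio <- !rec$biotype %in% .BIOTYPES
  if (any(bad_bio)) {
    stop("unknown biotype '", rec$biotype[which(bad_bio)[1]],
         "' for feature ", rec$feature_id[which(bad_bio)[1]])
  }
  bad_alpha <- grepl("[^ACGT]", rec$sequence)
  if (any(bad_alpha)) {
    stop("sequence of feature ", rec$feature_id[which(bad_alpha)[1]],
         " contains characters outside {A,C,G,T}")
  }
  too_short <- nchar(rec$sequence) < 15L
  if (any(too_short)) {
    stop("sequence of feature ", rec$feature_id[which(too_short)[1]],
         " is shorter than 15 nt")
  }
  is_trna <- rec$biotype == "tRNA"
  if (any(is_trna)) {
    tr <- rec[is_trna, ]
    no_ac <- is.na(tr$anticodon_start) | is.na(tr$anticodon) |
      tr$anticodon == ""
    if (any(no_ac)) {
      stop("tRNA feature ", tr$feature_id[which(no_ac)[1]],
           " lacks anticodon/anticodon_start annotation")
    }
    pre_cca <- nchar(tr$sequence) - ifelse(isTRUE_vec(tr$has_cca), 3L, 0L)
    off <- tr$anticodon_start + 3L > pre_cca
    if (any(off)) {
      stop("tRNA feature ", tr$feature_id[which(off)[1]],
           ": anticodon does not fit within the pre-CCA mature sequence")
    }
  }
  invisible(ref)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.ReferenceSet <- function(x, ...) {
  tab <- table(factor(x$records$biotype, levels = .BIOTYPES))
  cat("ReferenceSet with", nrow(x$records), "features\n")
  tab <- tab[tab > 0]
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  if (!is.null(x$windows)) {
    cat("  designated fragment windows:", nrow(x$windows), "\n")
  }
  invisible(x)
}

#' Index feature ids by biotype
#'
#' @param ref A `ReferenceSet`.
#' @return Named list mapping each biotype present to its feature ids, in
#'   record order.
#' @export
by_biotype <- function(ref) {
  split(ref$records$feature_id, ref$records$biotype)
}

#' Load a reference from FASTA plus annotation table
#'
#' The annotation is a 9-column tab-separated table with header
#' (`feature_id`, `biotype`, `family_id`, `anticodon`, `anticodon_start`,
#' `has_cca`, `precursor_id`, `species_tag`, `notes`).  FASTA ids must match
#' the `feature_id` column one-to-one.
#'
#' @param fasta_path Path to a FASTA file (wrapped or single-line).
#' @param annotation_path Path to the annotation TSV.
#' @return A `ReferenceSet`.
#' @export
load_reference <- function(fasta_path, annotation_path) {
  ann <- read.delim(annotation_path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
  if (nrow(ann) == 0 && file.size(fasta_path) == 0) {
    return(reference_set(data.frame(feature_id = character(),
                                    biotype = character(),
                                    sequence = character())))
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  if (anyDuplicated(ann$feature_id)) {
    stop("duplicate annotation feature_id: ",
         ann$feature_id[duplicated(ann$feature_id)][1])
  }
  missing_seq <- setdiff(ann$feature_id, ids)
  if (length(missing_seq)) {
    stop("annotation row without sequence: ", missing_seq[1])
  }
  missing_ann <- setdiff(ids, ann$feature_id)
  if (length(missing_ann)) {
    stop("FASTA record without annotation row: ", missing_ann[1])
  }
  ann <- ann[match(ids, ann$feature_id), , drop = FALSE]
  ann$sequence <- as.character(seqs)
  ann$has_cca <- toupper(ann$has_cca) %in% c("TRUE", "T", "1", "YES")
  ann$anticodon_start <- suppressWarnings(as.integer(ann$anticodon_start))
  for (col in c("family_id", "anticodon", "precursor_id", "species_tag",
                "notes")) {
    if (!is.null(ann[[col]])) ann[[col]][ann[[col]] == ""] <- NA_character_
  }
  reference_set(ann)
}

#' Write a ReferenceSet to FASTA plus annotation table
#'
#' Inverse of [load_reference()]; the round trip is lossless for ids,
#' sequences and annotation fields.
#'
#' @param ref A `ReferenceSet`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `ref`.
#' @export
write_reference <- function(ref, fasta_path, annotation_path) {
  rec <- ref$records
  seqs <- Biostrings::DNAStringSet(rec$sequence)
  names(seqs) <- rec$feature_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  out <- rec[, .ANNOT_COLUMNS]
  out$has_cca <- ifelse(is.na(out$has_cca), "", ifelse(out$has_cca, "TRUE",
                                                       "FALSE"))
  out$anticodon_start <- ifelse(is.na(out$anticodon_start), "",
                                as.character(out$anticodon_start))
  for (col in c("family_id", "anticodon", "precursor_id", "species_tag",
                "notes")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  write.table(out, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ref)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return data.frame with columns `read_id`, `sequence` (uppercase,
#'   T-alphabet) and `quality` (Phred+33 string), in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  qual <- as.character(S4Vectors::mcols(seqs)$qualities)
  out <- data.frame(read_id = sub("\\s.*$", "", names(seqs)),
                    sequence = toupper(chartr("Uu", "Tt",
                                              as.character(seqs))),
                    quality = qual,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  bad <- nchar(out$quality) != nchar(out$sequence)
  if (any(bad)) {
    stop("quality/sequence length mismatch for read ",
         out$read_id[which(bad)[1]])
  }
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a count matrix TSV
#'
#' First column `feature_id`, one column per sample.
#'
#' @param path Path to the TSV.
#' @return Integer matrix with feature ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix TSV
#'
#' @param m Matrix with feature ids as rownames and sample names as colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
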