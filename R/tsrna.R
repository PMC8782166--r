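## Positional classification of tRNA-mapped reads into tsRNA classes.
##
## tRNA halves (tRH5/tRH3, 29-50 nt) arise from cleavage at the anticodon
## loop; tRNA fragments (tRF5/tRF3, 14-30 nt) are shorter 5'- or 3'-anchored
## products, with 3' fragments retaining the CCA tail tracked separately
## (tRF3CCA).  The classifier is a pure function of the read placement and
## the tRNA geometry, so every call can be re-derived from
## (start, end, anticodon_start, mature length) alone.

#' Classify a tRNA-mapped read placement into a tsRNA class
#'
#' Rules, applied in order (`L` = pre-CCA mature length, anticodon occupies
#' `[anticodon_start, anticodon_start + 3)`, loop window
#' `W = [anticodon_start - loop_halfwidth, anticodon_start + 3 +
#' loop_halfwidth]`):
#' 1. 5'-anchored (`start <= tol5`), end inside `W`, length 29-50: `tRH5`;
#' 2. 5'-anchored, end below `W`, length 14-30: `tRF5`;
#' 3. 3'-anchored (`end >= L - tol3`, possibly through the CCA tail), start
#'    inside `W`, length 29-50: `tRH3`;
#' 4. 3'-anchored, start beyond `W`, length 14-30: `tRF3CCA` when the read
#'    covers at least one CCA base, else `tRF3`;
#' 5. otherwise `tRFmisc`.
#'
#' Because the tRH and tRF length bands overlap at 29-30 nt, the anchored
#' end/loop condition, not length alone, discriminates halves from
#' fragments; the rule order resolves ties in favour of halves.
#'
#' @param start,end Read placement, 0-based half-open on the mature
#'   sequence (CCA included when present).  Vectorized.
#' @param anticodon_start 0-based anticodon offset(s).
#' @param mature_len Pre-CCA mature length(s) `L`.
#' @param tol5,tol3 Terminal anchoring tolerances in nt (defaults 1).
#' @param loop_halfwidth Half-width of the anticodon-loop window in nt
#'   (default 4, approximating a 7-11 nt loop).
#' @return Character vector of class labels (see [tsrna_classes()]).
#' @export
classify_tsrna <- function(start, end, anticodon_start, mature_len,
                           tol5 = 1L, tol3 = 1L, loop_halfwidth = 4L) {
  len <- end - start
  w_lo <- anticodon_start - loop_halfwidth
  w_hi <- anticodon_start + 3L + loop_halfwidth
  anchored5 <- start <= tol5
  anchored3 <- end >= mature_len - tol3
  is_half <- len >= 29L & len <= 50L
  is_frag <- len >= 14L & len <= 30L

  cls <- rep("tRFmisc", length(len))
  r1 <- anchored5 & end >= w_lo & end <= w_hi & is_half
  r2 <- !r1 & anchored5 & end < w_lo & is_frag
  r3 <- !r1 & !r2 & anchored3 & start >= w_lo & start <= w_hi & is_half
  r4 <- !r1 & !r2 & !r3 & anchored3 & start > w_hi & is_frag
  cls[r1] <- "tRH5"
  cls[r2] <- "tRF5"
  cls[r3] <- "tRH3"
  cls[r4] <- ifelse(end[r4] > mature_len[r4], "tRF3CCA", "tRF3")
  cls
}

#' Classify all tRNA assignments of a sample
#'
#' @param assignments Assignment data.frame (from [assign_reads()]); only
#'   tRNA rows are used.
#' @param reference The `ReferenceSet`.
#' @param tol5,tol3,loop_halfwidth Passed to [classify_tsrna()].
#' @return data.frame with `read_id`, `feature_id`, `parental_anticodon`,
#'   `tsrna_class`, `start`, `end`.
#' @export
classify_tsrna_reads <- function(assignments, reference, tol5 = 1L,
                                 tol3 = 1L, loop_halfwidth = 4L) {
  rec <- reference$records
  a <- assignments[assignments$biotype == "tRNA", , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(read_id = character(), feature_id = character(),
                      parental_anticodon = character(),
                      tsrna_class = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  row <- match(a$feature_id, rec$feature_id)
  if (any(rec$biotype[row] != "tRNA")) {
    stop("classify_tsrna_reads applied to a non-tRNA feature")
  }
  L <- nchar(rec$sequence[row]) - ifelse(isTRUE_vec(rec$has_cca[row]), 3L, 0L)
  data.frame(read_id = a$read_id, feature_id = a$feature_id,
             parental_anticodon = rec$anticodon[row],
             tsrna_class = classify_tsrna(a$start, a$end,
                                          rec$anticodon_start[row], L,
                                          tol5, tol3, loop_halfwidth),
             start = a$start, end = a$end, stringsAsFactors = FALSE)
}

#' Per-sample tsRNA class and parental-anticodon tables
#'
#' @param calls Named list of per-sample call data.frames (from
#'   [classify_tsrna_reads()]).
#' @return List of two data.frames: `classes` (`sample`, `tsrna_class`,
#'   `n_reads`, `fraction`, `percent`) and `parental` (`sample`,
#'   `parental_anticodon`, `n_reads`, `fraction`, `percent`).  Fractions
#'   sum to 1 within each sample.
#' @export
tsrna_class_table <- function(calls) {
  cls_out <- list()
  par_out <- list()
  for (s in names(calls)) {
    cc <- calls[[s]]
    if (nrow(cc) == 0) stop("no tsRNA calls in sample ", s)
    tab <- table(factor(cc$tsrna_class, levels = .TSRNA_CLASSES))
    frac <- as.numeric(tab) / sum(tab)
    cls_out[[s]] <- data.frame(sample = s, tsrna_class = .TSRNA_CLASSES,
                               n_reads = as.integer(tab), fraction = frac,
                               percent = round(100 * frac, 1),
                               stringsAsFactors = FALSE)
    ptab <- table(cc$parental_anticodon)
    pfrac <- as.numeric(ptab) / sum(ptab)
    par_out[[s]] <- data.frame(sample = s,
                               parental_anticodon = names(ptab),
                               n_reads = as.integer(ptab), fraction = pfrac,
                               percent = round(100 * pfrac, 1),
                               stringsAsFactors = FALSE)
  }
  list(classes = do.call(rbind, c(cls_out, make.row.names = FALSE)),
       parental = do.call(rbind, c(par_out, make.row.names = FALSE)))
}
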