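## Controlled vocabularies shared across the pipeline.

.BIOTYPES <- c("miRNA", "tRNA", "rRNA", "snoRNA", "scaRNA", "snRNA", "YRNA",
               "vtRNA", "piRNA", "protein_coding", "lincRNA", "misc")

## Assignment priority: a read matching several biotypes equally well is
## attributed to the highest-priority one.  piRNA is deliberately last so
## that sequences shared with structural ncRNAs are claimed by their host
## biotype and the piRNA disambiguation filter sees genuinely ambiguous
## entries.
.BIOTYPE_PRIORITY <- c("miRNA", "tRNA", "rRNA", "snoRNA", "scaRNA", "snRNA",
                       "YRNA", "vtRNA", "misc", "lincRNA", "protein_coding",
                       "piRNA")

.TSRNA_CLASSES <- c("tRF5", "tRH5", "tRH3", "tRF3", "tRF3CCA", "tRFmisc")

## Biotypes whose reads are drawn from designated fragment windows fixed at
## reference construction (stable processed fragments rather than arbitrary
## degradation products).
.WINDOWED_BIOTYPES <- c("snoRNA", "scaRNA", "snRNA", "YRNA", "vtRNA")

#' Recognized sncRNA biotypes
#'
#' @return Character vector of the biotype vocabulary used throughout the
#'   package.
#' @export
sncrna_biotypes <- function() .BIOTYPES

#' Biotype priority order used for ambiguous read assignment
#'
#' Reads that place equally well (same mismatch count) on features of several
#' biotypes are attributed to the first biotype in this order.  piRNA is last
#' on purpose: piRNA database entries frequently duplicate substrings of
#' tRNAs, rRNAs and snoRNAs, and those reads belong to the host biotype.
#'
#' @return Character vector, highest priority first.
#' @export
biotype_priority <- function() .BIOTYPE_PRIORITY

#' tRNA-derived small RNA classes
#'
#' 5'/3' tRNA halves (tRH5/tRH3, cleavage at the anticodon loop, 29-50 nt),
#' 5'/3' tRNA fragments (tRF5/tRF3, 14-30 nt), 3' fragments retaining the
#' post-transcriptional CCA tail (tRF3CCA), and a miscellaneous internal
#' class (tRFmisc).
#'
#' @return Character vector of class labels.
#' @export
tsrna_classes <- function() .TSRNA_CLASSES

.biotype_rank <- function(biotype) match(biotype, .BIOTYPE_PRIORITY)
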