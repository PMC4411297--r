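#' Read exon/intron gene intervals
#'
#' Reads a BED-derived TSV of RefSeq-style exon and intron intervals with
#' columns `chrom`, `start` (0-based), `end` (half-open), `gene`, `strand`
#' (`+`/`-`) and `feature` (`exon`/`intron`). Internally all interval
#' arithmetic is 0-based half-open; site positions reported by the pipeline
#' stay 1-based as in the pileup dialect.
#'
#' @param file Path to the interval TSV (with header).
#' @return Data frame of intervals.
#' @export
read_gene_intervals <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "strand", "feature")
  if (!all(need %in% names(x)))
    stop("gene interval file must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(x$start < x$end), all(x$strand %in% c("+", "-")),
            all(x$feature %in% c("exon", "intron")))
  x[, need]
}

# GRanges over the interval table, for overlap queries
.intervals_as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = intervals$strand,
    gene = intervals$gene,
    feature = intervals$feature)
}

#' Read a polymorphism table
#'
#' TSV with columns `chrom`, `pos` (1-based), `ref`, `alt` and `max_freq`
#' (maximum known population allele frequency, in `[0,1]`). Candidate sites
#' matching a record with `max_freq` above the configured cutoff are
#' excluded as likely genomic polymorphisms rather than RNA edits.
#'
#' @param file Path to the TSV (with header).
#' @return Data frame of polymorphism records.
#' @export
read_polymorphisms <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "max_freq")
  if (!all(need %in% names(x)))
    stop("polymorphism file must have columns: ", paste(need, collapse = ", "))
  if (any(x$max_freq < 0 | x$max_freq > 1))
    stop("max_freq must be in [0, 1]")
  x[, need]
}

#' Load the packaged validation-site table
#'
#' The package ships a transcription of the 33 non-synonymous C>U editing
#' sites chosen for experimental validation, with their editing levels (%)
#' in monocyte-enriched PBMCs (normoxia/hypoxia) and macrophages (M2/M1);
#' levels not determined for a tissue are `NA`.
#'
#' @param file Path to the fixture TSV; defaults to the packaged copy.
#' @return Data frame with columns `gene`, `position`, `change`,
#'   `mep_normoxia`, `mep_hypoxia`, `m2`, `m1`.
#' @export
load_validation_table <- function(file = system.file("extdata",
                                                     "table1_validation.tsv",
                                                     package = "cuedit")) {
  x <- read.delim(file, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("gene", "position", "change",
            "mep_normoxia", "mep_hypoxia", "m2", "m1")
  if (!all(need %in% names(x)))
    stop("validation table must have columns: ", paste(need, collapse = ", "))
  lv <- as.matrix(x[, need[4:7]])
  if (any(lv < 0 | lv > 100, na.rm = TRUE))
    stop("editing levels must be percentages in [0, 100]")
  x[, need]
}

#' Classify validation sites by the tissue they were identified in
#'
#' A site with both macrophage levels missing was identified only in MEPs;
#' both MEP levels missing, only in macrophages; all four levels present, in
#' both. A record with exactly one member of a tissue's pair missing is
#' counted as present for that tissue, with a warning.
#'
#' @param records Data frame from [load_validation_table()].
#' @return Named list `mep_only`, `macrophage_only`, `both`, `total`.
#' @export
classify_validation_sites <- function(records) {
  if (nrow(records) == 0L)
    return(list(mep_only = 0L, macrophage_only = 0L, both = 0L, total = 0L))
  mep_na <- is.na(records$mep_normoxia) + is.na(records$mep_hypoxia)
  mac_na <- is.na(records$m2) + is.na(records$m1)
  if (any(mep_na == 1L | mac_na == 1L))
    warning("record(s) with a half-missing level pair counted as present")
  mep_present <- mep_na < 2L
  mac_present <- mac_na < 2L
  list(mep_only = sum(mep_present & !mac_present),
       macrophage_only = sum(!mep_present & mac_present),
       both = sum(mep_present & mac_present),
       total = nrow(records))
}
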