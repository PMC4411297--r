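#' Editing level from Sanger chromatogram peak heights
#'
#' The editing level at a chromatogram position is the minor peak height as
#' a fraction of the summed major and minor heights, in percent. Peak-calling
#' software only reports a minor peak when its height exceeds 5% of the
#' major peak's, so when no minor peak is detected a relative minor height
#' of 4% is assumed, assigning a level of 3.8% (one decimal).
#'
#' @param major Major peak height (> 0).
#' @param minor Minor peak height, or `NA`/`NULL` when no minor peak was
#'   detected.
#' @param assumed_minor_frac Relative minor height assumed when the minor
#'   peak is absent (default 0.04).
#' @return List with `level` (percent) and `assigned` (`TRUE` when the level
#'   is the assumed-absent convention rather than a detected peak).
#' @examples
#' sanger_level(100, 10)$level   # 9.1
#' sanger_level(100)$level       # 3.8
#' @export
sanger_level <- function(major, minor = NA, assumed_minor_frac = 0.04) {
  stopifnot(major > 0)
  if (is.null(minor) || is.na(minor)) {
    level <- round(100 * assumed_minor_frac / (1 + assumed_minor_frac), 1)
    return(list(level = level, assigned = TRUE))
  }
  stopifnot(minor > 0)
  if (minor > major) {
    warning("minor peak taller than major; swapping (major is the larger)")
    tmp <- major; major <- minor; minor <- tmp
  }
  list(level = round(100 * minor / (major + minor), 1), assigned = FALSE)
}

#' Targeted editing level from pileup base counts at one position
#'
#' Estimates the C>U editing level at a known site from A/C/G/T call counts
#' at its plus-strand position, with the indeterminability rules used for
#' per-ORF tumour RNA-seq scans: a sample is indeterminable if fewer than
#' `purity` of its calls are for the reference or variant base, if it has
#' fewer than `min_total` calls with none for the variant, or fewer than
#' `min_total_single_variant` calls with exactly one for the variant.
#' Otherwise the level is variant / (variant + reference). For a
#' minus-strand gene (such as *SDHB*) the plus-strand reference reads G and
#' the edited reads A, which are the defaults.
#'
#' @param counts Named counts for `A`, `C`, `G`, `T`.
#' @param ref_base,variant_base Plus-strand reference and variant bases
#'   (defaults `G` and `A`: a C>U edit in a minus-strand gene).
#' @param min_total Minimum calls when no variant call is seen (default
#'   200).
#' @param min_total_single_variant Minimum calls when exactly one variant
#'   call is seen (default 100).
#' @param purity Minimum fraction of reference-or-variant calls (default
#'   0.99).
#' @return List with `level` (or `NA`), `indeterminable`, `reason`.
#' @examples
#' targeted_editing(c(A = 20, C = 0, G = 180, T = 0))$level   # 0.1
#' @export
targeted_editing <- function(counts, ref_base = "G", variant_base = "A",
                             min_total = 200, min_total_single_variant = 100,
                             purity = 0.99) {
  stopifnot(all(c(ref_base, variant_base) %in% names(counts)))
  total <- sum(counts)
  v <- counts[[variant_base]]
  r <- counts[[ref_base]]
  if (total == 0)
    return(list(level = NA_real_, indeterminable = TRUE, reason = "no_calls"))
  if ((v + r) / total < purity)
    return(list(level = NA_real_, indeterminable = TRUE, reason = "impure"))
  if (total < min_total && v == 0)
    return(list(level = NA_real_, indeterminable = TRUE,
                reason = "low_coverage_no_variant"))
  if (total < min_total_single_variant && v == 1)
    return(list(level = NA_real_, indeterminable = TRUE,
                reason = "low_coverage_single_variant"))
  list(level = v / (v + r), indeterminable = FALSE, reason = "")
}

#' Count C-bearing positions of an ORF sequence
#'
#' @param orf_sequence Coding-sense DNA or RNA string.
#' @return Number of positions whose base is C.
#' @examples
#' count_c_positions("ATGCC")   # 2
#' @export
count_c_positions <- function(orf_sequence) {
  if (nchar(orf_sequence) == 0L) return(0L)
  ch <- strsplit(.as_rna(orf_sequence), "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("A", "C", "G", "U")))
    stop("sequence must contain only A, C, G, T/U")
  sum(ch == "C")
}

#' Length of a cDNA coordinate range
#'
#' cDNA (c.) coordinates number the coding sequence with the A of the ATG
#' start codon as position 1; the range c.start-c.end spans
#' `end - start + 1` bases.
#'
#' @param start,end c.-coordinates with `1 <= start <= end`.
#' @return Integer length.
#' @examples
#' cdna_range_length(37, 156)   # 120
#' @export
cdna_range_length <- function(start, end) {
  stopifnot(start >= 1)
  if (start > end) stop("start must not exceed end")
  end - start + 1
}

#' In-silico PCR amplicon lengths
#'
#' Finds products delimited by an exact forward-primer match and an exact
#' reverse-complemented reverse-primer match downstream of it on a template.
#'
#' @param template Template sequence (DNA).
#' @param fwd_primer,rev_primer Primer sequences (>= 15 nt); the reverse
#'   primer is given 5'->3' on the opposite strand, as ordered.
#' @return Integer vector of product lengths (empty if no product); if more
#'   than one, attribute `multiple` is set.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer) {
  stopifnot(nchar(fwd_primer) >= 15, nchar(rev_primer) >= 15)
  tpl <- Biostrings::DNAString(toupper(template))
  f <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(toupper(fwd_primer)), tpl))
  rc <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev_primer))),
    tpl)
  r_end <- Biostrings::end(rc)
  r_start <- Biostrings::start(rc)
  if (length(f) == 0L || length(r_end) == 0L) return(integer())
  lens <- integer()
  for (fs in f) {
    ok <- r_start >= fs + nchar(fwd_primer)
    lens <- c(lens, r_end[ok] - fs + 1L)
  }
  lens <- sort(unique(lens))
  if (length(lens) > 1L) attr(lens, "multiple") <- TRUE
  lens
}
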