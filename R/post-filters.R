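#' Flanking-sequence uniqueness filter
#'
#' Rebuilds the four 30-base queries around a site (5' flank plus site base,
#' and site base plus 3' flank, each with the reference and with the variant
#' base at the site) and drops the site if any query aligns perfectly --
#' exact string match, forward or reverse-complement -- anywhere in the
#' genome other than the site's own location. Sites within flank distance of
#' a contig end are evaluated on the available bases and flagged.
#'
#' @param chrom,pos Site location (1-based).
#' @param ref,variant Site bases.
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes).
#' @param flank Flank length in bases (default 29, giving 30-mers).
#' @return List with `keep` (logical) and `truncated` flag.
#' @export
flank_uniqueness_filter <- function(chrom, pos, ref, variant, genome,
                                    flank = 29) {
  stopifnot(chrom %in% names(genome))
  chr_seq <- genome[[chrom]]
  L <- length(chr_seq)
  lo <- max(1L, pos - flank)
  hi <- min(L, pos + flank)
  truncated <- lo > pos - flank || hi < pos + flank
  left_flank <- as.character(Biostrings::subseq(chr_seq, lo, pos - 1L))
  right_flank <- if (pos < L)
    as.character(Biostrings::subseq(chr_seq, pos + 1L, hi)) else ""

  queries <- list(
    list(q = paste0(left_flank, ref), own_start = lo),
    list(q = paste0(left_flank, variant), own_start = lo),
    list(q = paste0(ref, right_flank), own_start = pos),
    list(q = paste0(variant, right_flank), own_start = pos))

  for (qr in queries) {
    pat <- Biostrings::DNAString(qr$q)
    w <- length(pat)
    if (w < 2L) next
    for (cn in names(genome)) {
      fwd <- Biostrings::start(Biostrings::matchPattern(pat, genome[[cn]]))
      other <- fwd[!(cn == chrom & fwd == qr$own_start)]
      if (length(other) > 0L)
        return(list(keep = FALSE, truncated = truncated))
      rc <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(pat), genome[[cn]]))
      # a reverse-complement hit coinciding with the site's own interval is
      # the locus itself being palindromic, not a second location
      other_rc <- rc[!(cn == chrom & rc == qr$own_start)]
      if (length(other_rc) > 0L)
        return(list(keep = FALSE, truncated = truncated))
    }
  }
  list(keep = TRUE, truncated = truncated)
}

#' Sequencing-read strand-bias filter
#'
#' Drops a site if (a) across all samples the variant base was called from
#' more than `abs_threshold` forward reads but no reverse read, or vice
#' versa; or (b) the variant-call forward fraction differs from the
#' reference-call forward fraction (paired beta-binomial test across the
#' samples of the test group, or of the control group) with p < 0.05. A site
#' with no variant calls at all is kept and flagged.
#'
#' @param v_fwd,v Per-sample forward-strand and total variant calls.
#' @param r_fwd,r Per-sample forward-strand and total reference calls.
#' @param is_test Logical vector marking test samples.
#' @param abs_threshold One-strand-only trigger (default 9: more than nine
#'   reads on one strand, none on the other).
#' @param test_bias Run the paired significance sub-rule (b)? Default TRUE.
#' @return List with `keep`, `reason` (`one_strand`, `bias_test`, or `""`)
#'   and `no_variant` flag.
#' @export
strand_bias_filter <- function(v_fwd, v, r_fwd, r, is_test,
                               abs_threshold = 9, test_bias = TRUE) {
  if (sum(v) == 0)
    return(list(keep = TRUE, reason = "", no_variant = TRUE))
  V_fwd <- sum(v_fwd)
  V_rev <- sum(v) - V_fwd
  if ((V_fwd > abs_threshold && V_rev == 0) ||
      (V_rev > abs_threshold && V_fwd == 0))
    return(list(keep = FALSE, reason = "one_strand", no_variant = FALSE))
  if (test_bias) {
    for (grp in list(is_test, !is_test)) {
      # a group whose variant calls do not exceed the one-strand trigger
      # cannot evidence strand bias either way; testing such counts only
      # produces spurious rejections
      if (sum(v[grp]) <= abs_threshold) next
      d <- data.frame(v_test = v_fwd[grp], n_test = v[grp],
                      v_control = r_fwd[grp], n_control = r[grp])
      if (sum(d$n_test > 0 & d$n_control > 0) < 2) next
      p <- .strand_bias_p(d)
      if (!is.na(p) && p < 0.05)
        return(list(keep = FALSE, reason = "bias_test", no_variant = FALSE))
    }
  }
  list(keep = TRUE, reason = "", no_variant = FALSE)
}

# paired test of variant vs reference forward-read fraction for one group.
# Read strands are assigned independently per read, so under the null the
# two fractions share each sample's forward rate with no extra-binomial
# dispersion; the paired LRT (dispersion fixed at 0) is therefore referred
# to its exact parametric Monte Carlo null given the totals, rather than to
# the asymptotic chi-square, which is liberal at the small variant counts
# this filter routinely sees. The Monte Carlo draw is seeded from the
# counts, so results are reproducible and independent of filter order.
.strand_bias_p <- function(d, B = 199) {
  lrt_of <- function(dd) {
    f <- tryCatch(fit_paired_bb(dd, rho = 0), error = function(e) NULL)
    if (is.null(f) || is.na(f$loglik_alt)) return(NA_real_)
    max(0, 2 * (f$loglik_alt - f$loglik_null))
  }
  obs <- lrt_of(d)
  if (is.na(obs)) return(NA_real_)
  pis <- (d$v_test + d$v_control + 0.5) / (d$n_test + d$n_control + 1)
  seed <- as.integer((sum(d) * 31 + nrow(d)) %% 2147483629)
  .with_preserved_rng(seed, {
    ge <- 0L
    for (b in seq_len(B)) {
      db <- data.frame(v_test = rbinom(nrow(d), d$n_test, pis),
                       n_test = d$n_test,
                       v_control = rbinom(nrow(d), d$n_control, pis),
                       n_control = d$n_control)
      lb <- lrt_of(db)
      if (!is.na(lb) && lb >= obs) ge <- ge + 1L
    }
    (1 + ge) / (B + 1)
  })
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Deduce the RNA-level change from the DNA change and gene strand
#'
#' On the plus strand the RNA change is the DNA change with T relabeled U;
#' on the minus strand both bases are complemented first. A>G changes are
#' labeled `"A>I (A>G)"` since inosine is read as G.
#'
#' @param dna_ref,dna_variant Plus-strand DNA bases.
#' @param gene_strand `"+"` or `"-"`.
#' @return RNA change label, e.g. `"C>U"`.
#' @examples
#' deduce_rna_change("G", "A", "-")   # "C>U"
#' @export
deduce_rna_change <- function(dna_ref, dna_variant, gene_strand) {
  stopifnot(dna_ref %in% .BASES, dna_variant %in% .BASES,
            gene_strand %in% c("+", "-"))
  if (gene_strand == "-") {
    dna_ref <- .COMPLEMENT[[dna_ref]]
    dna_variant <- .COMPLEMENT[[dna_variant]]
  }
  to_rna <- function(b) if (b == "T") "U" else b
  if (dna_ref == "A" && dna_variant == "G") return("A>I (A>G)")
  paste0(to_rna(dna_ref), ">", to_rna(dna_variant))
}
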