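#' Editing level from variant and reference call counts
#'
#' The editing (variation) level of a site in a sample is the ratio of
#' variant calls to the sum of variant and reference calls. When a sample has
#' neither, the level is 0 and flagged degenerate.
#'
#' @param variant_count,reference_count Non-negative call counts
#'   (vectorized).
#' @return Numeric vector of levels in `[0,1]`, with attribute `degenerate`
#'   marking samples with zero variant+reference calls.
#' @examples
#' editing_level(10, 90)   # 0.10
#' @export
editing_level <- function(variant_count, reference_count) {
  if (any(variant_count < 0) || any(reference_count < 0))
    stop("counts must be non-negative")
  denom <- variant_count + reference_count
  lev <- ifelse(denom == 0, 0, variant_count / denom)
  attr(lev, "degenerate") <- denom == 0
  lev
}

#' Default screening thresholds
#'
#' All constants of the candidacy and level-filter cascade, overridable per
#' call or through the pipeline configuration.
#'
#' @return Named list of thresholds: `min_calls_pair` (>=20 calls in both
#'   samples of at least one pair), `min_calls_all` (>=5 calls in every
#'   sample), `min_ref_frac` (reference base >=50% of calls in all test or
#'   all control samples), `min_var_calls`/`min_var_samples` (>=2 identical
#'   variant calls in >=2 samples of a group), `max_other_variant` (<=5 calls
#'   for any different variant in every sample), `min_purity` (>=95%
#'   reference-or-variant calls in every sample), `level_min` (2.5%),
#'   `level_min_samples`, `group_mean_min` (5%), `range_mean_min` (2),
#'   `popfreq_max` (0.20).
#' @export
screen_thresholds <- function() {
  list(min_calls_pair = 20, min_calls_all = 5,
       min_ref_frac = 0.5,
       min_var_calls = 2, min_var_samples = 2,
       max_other_variant = 5, min_purity = 0.95,
       level_min = 0.025, level_min_samples = 2,
       group_mean_min = 0.05, range_mean_min = 2,
       popfreq_max = 0.20)
}

# Candidacy criteria for one site.
# calls: 4 x S matrix (rows A,C,G,T) of strand-summed quality-passing calls;
# is_test: logical length S; pair: integer length S.
# Returns variant choice, per-criterion verdicts and reason codes.
.screen_one <- function(calls, ref, is_test, pair, th) {
  total <- colSums(calls)
  ref_row <- match(ref, .BASES)
  ref_count <- if (is.na(ref_row)) rep(0, length(total)) else calls[ref_row, ]

  # (1) coverage: >=20 calls in both samples of >=1 pair, >=5 in all samples
  pair_ok <- any(tapply(total >= th$min_calls_pair, pair, all))
  c1 <- pair_ok && all(total >= th$min_calls_all)

  # (2) reference majority in all test or all control samples
  ref_major <- ref_count >= th$min_ref_frac * total
  c2 <- all(ref_major[is_test]) || all(ref_major[!is_test])

  # (3) variant support, evaluated per non-reference base
  nonref <- setdiff(seq_len(4L), ref_row)
  ok3 <- logical(4L)
  for (b in nonref) {
    vb <- calls[b, ]
    ge2 <- vb >= th$min_var_calls
    a <- sum(ge2[is_test]) >= th$min_var_samples ||
         sum(ge2[!is_test]) >= th$min_var_samples
    bb <- all(vb[is_test] >= 1) || all(vb[!is_test] >= 1)
    others <- setdiff(nonref, b)
    cc <- all(calls[others, , drop = FALSE] <= th$max_other_variant)
    ok3[b] <- a && bb && cc
  }
  cand <- which(ok3)
  tied <- FALSE
  if (length(cand) > 0L) {
    tot_b <- rowSums(calls)[cand]
    best <- cand[tot_b == max(tot_b)]
    tied <- length(best) > 1L
    variant_row <- min(best)          # lexicographic tie-break (A<C<G<T)
    c3 <- TRUE
  } else {
    tot_b <- rowSums(calls)[nonref]
    best <- nonref[tot_b == max(tot_b)]
    variant_row <- min(best)
    c3 <- FALSE
  }
  var_count <- calls[variant_row, ]

  # (4) purity: >=95% reference-or-variant calls in every sample
  c4 <- all(ref_count + var_count >= th$min_purity * total)

  reasons <- c("calls", "ref_majority", "variant_support", "purity")[
    !c(c1, c2, c3, c4)]
  list(variant = .BASES[variant_row], pass = c1 && c2 && c3 && c4,
       reasons = reasons, ref_count = ref_count, var_count = var_count,
       variant_tied = tied)
}

#' Screen one pileup site for editing candidacy
#'
#' Applies the four candidacy criteria to a single site: (1) >=20 A/T/G/C
#' calls in both samples of at least one pair and >=5 calls in every sample;
#' (2) the reference base makes up >=50% of calls in all test or all control
#' samples; (3) >=2 identical variant-base calls in >=2 test or >=2 control
#' samples, >=1 such call in all test or all control samples, and <=5 calls
#' for any different variant in every sample; (4) >=95% of calls are for the
#' reference or chosen variant base in every sample. The chosen variant is
#' the non-reference base satisfying (3) (highest total count, ties broken
#' alphabetically); a rejected site lists every violated criterion.
#'
#' @param calls 4 x n_samples matrix of A/C/G/T calls (rows in that order),
#'   strands summed.
#' @param ref Reference base, one of `A`, `C`, `G`, `T`.
#' @param pairing Pairing data frame (see [pair_design()]); columns of
#'   `calls` follow its sample order.
#' @param thresholds See [screen_thresholds()].
#' @return List with `variant`, `pass`, `reasons` (codes `calls`,
#'   `ref_majority`, `variant_support`, `purity`), per-sample `ref_count` and
#'   `var_count`.
#' @export
screen_site <- function(calls, ref, pairing = pair_design(ncol(calls) / 2),
                        thresholds = screen_thresholds()) {
  stopifnot(nrow(calls) == 4L, ncol(calls) == nrow(pairing))
  .screen_one(calls, ref, pairing$condition == "test", pairing$pair,
              thresholds)
}

#' Screen all sites of a merged pileup
#'
#' Vectorized application of [screen_site()] over a `cu_pileup`, retaining
#' per-sample reference/variant counts (strand-split) for downstream testing
#' and artifact filters.
#'
#' @param pileup A `cu_pileup` from [merge_samples()].
#' @param thresholds See [screen_thresholds()].
#' @param keep_all Keep rejected sites (with reason codes) in the result?
#'   Default drops them.
#' @return An object of class `cu_candidates`: list with `table` (site
#'   descriptions, variant, pass flag, reason codes), count matrices `r`,
#'   `v` (site x sample), strand-split `v_fwd`, `r_fwd`, editing `levels`,
#'   and the `pairing`.
#' @export
screen_sites <- function(pileup, thresholds = screen_thresholds(),
                         keep_all = FALSE) {
  stopifnot(inherits(pileup, "cu_pileup"))
  th <- thresholds
  calls <- .base_calls(pileup)
  n <- nrow(pileup$sites)
  S <- dim(calls)[3L]
  is_test <- pileup$pairing$condition == "test"
  pair <- pileup$pairing$pair

  variant <- character(n); pass <- logical(n); reasons <- character(n)
  r <- v <- matrix(0, n, S)
  for (i in seq_len(n)) {
    res <- .screen_one(matrix(calls[i, , ], 4L, S), pileup$sites$ref[i],
                       is_test, pair, th)
    variant[i] <- res$variant; pass[i] <- res$pass
    reasons[i] <- paste(res$reasons, collapse = ";")
    r[i, ] <- res$ref_count; v[i, ] <- res$var_count
  }
  tab <- cbind(pileup$sites,
               data.frame(variant = variant, screen_pass = pass,
                          screen_reasons = reasons,
                          stringsAsFactors = FALSE))
  ridx <- match(tab$ref, .BASES); vidx <- match(tab$variant, .BASES)
  pick <- function(idx) {
    out <- matrix(0L, n, S)
    for (s in seq_len(S)) out[, s] <- pileup$counts[cbind(seq_len(n), idx, s)]
    out
  }
  v_fwd <- pick(vidx); r_fwd <- pick(ridx)
  keep <- if (keep_all) rep(TRUE, n) else pass
  lev <- editing_level(v[keep, , drop = FALSE], r[keep, , drop = FALSE])
  structure(list(table = tab[keep, , drop = FALSE],
                 r = r[keep, , drop = FALSE], v = v[keep, , drop = FALSE],
                 v_fwd = v_fwd[keep, , drop = FALSE],
                 r_fwd = r_fwd[keep, , drop = FALSE],
                 levels = matrix(lev, sum(keep), S),
                 pairing = pileup$pairing,
                 n_screened = n),
            class = "cu_candidates")
}

#' @export
print.cu_candidates <- function(x, ...) {
  cat("cu_candidates: ", nrow(x$table), " candidate sites (of ",
      x$n_screened, " screened)\n", sep = "")
  invisible(x)
}

#' Editing-level filters for a candidate site
#'
#' A candidate passes iff (1) its level is >=2.5% in >=2 test or >=2 control
#' samples, (2) the mean level of the test or of the control group is >=5%,
#' and (3) range/mean of the levels across all samples is >=2 (range =
#' max - min; mean over all samples pooled). A site whose pooled mean is 0
#' fails (3) with a degenerate flag.
#'
#' @param levels Numeric vector of per-sample editing levels.
#' @param is_test Logical vector marking test samples.
#' @param thresholds See [screen_thresholds()].
#' @return List with `pass`, `reasons` (codes `level`, `group_mean`,
#'   `range_mean`), and `degenerate`.
#' @export
level_filter <- function(levels, is_test, thresholds = screen_thresholds()) {
  th <- thresholds
  c1 <- sum(levels[is_test] >= th$level_min) >= th$level_min_samples ||
        sum(levels[!is_test] >= th$level_min) >= th$level_min_samples
  c2 <- mean(levels[is_test]) >= th$group_mean_min ||
        mean(levels[!is_test]) >= th$group_mean_min
  m <- mean(levels)
  degenerate <- m == 0
  c3 <- !degenerate && (max(levels) - min(levels)) / m >= th$range_mean_min
  reasons <- c("level", "group_mean", "range_mean")[!c(c1, c2, c3)]
  list(pass = c1 && c2 && c3, reasons = reasons, degenerate = degenerate)
}

# apply level_filter to every row of a cu_candidates object
.level_filter_all <- function(candidates, thresholds = screen_thresholds()) {
  is_test <- candidates$pairing$condition == "test"
  t(vapply(seq_len(nrow(candidates$table)), function(i) {
    lf <- level_filter(candidates$levels[i, ], is_test, thresholds)
    c(pass = lf$pass,
      reasons = paste(lf$reasons, collapse = ";"))
  }, c(pass = "", reasons = "")))
}

#' Annotation-based exclusions and gene assignment
#'
#' Drops candidate sites that (a) match a known polymorphism with maximum
#' population frequency above `prevalence_cutoff`, (b) overlap no gene,
#' (c) fall in exons of more than one gene with those genes on both strands,
#' or (d) fall only in introns of more than one gene on both strands.
#' Surviving sites are assigned a gene, strand and feature; a site that is
#' exonic in one gene and intronic in another on the opposite strand gets
#' the exon-bearing gene.
#'
#' @param candidates A `cu_candidates` object (or any data frame with
#'   `chrom`, `pos`, `ref`, `variant` in its `table`).
#' @param intervals Gene intervals from [read_gene_intervals()].
#' @param polymorphisms Optional table from [read_polymorphisms()].
#' @param prevalence_cutoff Maximum tolerated population frequency
#'   (default 0.20).
#' @return Data frame (one row per candidate) with `keep`, `reason`, `gene`,
#'   `strand`, `feature`.
#' @export
annotation_exclusions <- function(candidates, intervals,
                                  polymorphisms = NULL,
                                  prevalence_cutoff = 0.20) {
  tab <- if (inherits(candidates, "cu_candidates")) candidates$table
         else candidates
  n <- nrow(tab)
  out <- data.frame(keep = rep(TRUE, n), reason = character(n),
                    gene = rep(NA_character_, n),
                    strand = rep(NA_character_, n),
                    feature = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  if (!is.null(polymorphisms) && nrow(polymorphisms) > 0L) {
    key <- paste(tab$chrom, tab$pos, tab$ref, tab$variant)
    pk <- paste(polymorphisms$chrom, polymorphisms$pos,
                polymorphisms$ref, polymorphisms$alt)
    hit <- match(key, pk)
    poly <- !is.na(hit) & polymorphisms$max_freq[ifelse(is.na(hit), 1L, hit)] >
      prevalence_cutoff
    out$keep[poly] <- FALSE
    out$reason[poly] <- "polymorphism"
  }

  gr <- .intervals_as_granges(intervals)
  sites <- GenomicRanges::GRanges(tab$chrom,
                                  IRanges::IRanges(tab$pos, tab$pos))
  ov <- GenomicRanges::findOverlaps(sites, gr, ignore.strand = TRUE)
  hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))

  for (i in which(out$keep)) {
    h <- hits[[as.character(i)]]
    if (is.null(h)) {
      out$keep[i] <- FALSE; out$reason[i] <- "no_gene"; next
    }
    gene <- S4Vectors::mcols(gr)$gene[h]
    feature <- S4Vectors::mcols(gr)$feature[h]
    strand <- as.character(GenomicRanges::strand(gr))[h]
    ex <- feature == "exon"
    if (any(ex)) {
      genes_e <- unique(gene[ex])
      strands_e <- unique(strand[ex])
      if (length(genes_e) > 1L && length(strands_e) > 1L) {
        out$keep[i] <- FALSE; out$reason[i] <- "ambiguous_exon"; next
      }
      g <- sort(genes_e)[1L]
      out$gene[i] <- g
      out$strand[i] <- strand[ex][gene[ex] == g][1L]
      out$feature[i] <- "exon"
    } else {
      genes_i <- unique(gene)
      strands_i <- unique(strand)
      if (length(genes_i) > 1L && length(strands_i) > 1L) {
        out$keep[i] <- FALSE; out$reason[i] <- "ambiguous_intron"; next
      }
      g <- sort(genes_i)[1L]
      out$gene[i] <- g
      out$strand[i] <- strand[gene == g][1L]
      out$feature[i] <- "intron"
    }
  }
  out
}
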