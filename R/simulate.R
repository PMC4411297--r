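#' Parameters for the synthetic paired-pileup generator
#'
#' Defaults emulate a paired test/control bulk RNA-seq editing experiment:
#' three donor pairs, per-site coverage around 100x (negative binomial),
#' a 0.2% per-call sequencing error rate, planted C>U sites whose control
#' editing is drawn around 1% and test editing around 20%, beta-binomial
#' overdispersion 0.01 shared across samples, and an even read-strand split.
#' Half of the planted sites are written into a CAUC-motif context with
#' palindromic flanks so the context-analysis stage has signal to find.
#'
#' @param seed Mandatory RNG seed.
#' @param n_pairs Test/control pairs (default 3).
#' @param genome_length Synthetic genome length in bp (default 20000).
#' @param n_genes Genes tiled across the genome (default 10).
#' @param coverage_mean,coverage_size Negative-binomial per-site coverage
#'   (mean 100, size 10).
#' @param error_rate Per-call sequencing error probability (default 0.002).
#' @param n_sites Planted differentially edited sites (default 50).
#' @param control_shape,test_shape Beta parameters for the per-pair baseline
#'   editing proportion in controls (mean 0.01) and tests (mean 0.20).
#' @param rho Beta-binomial overdispersion of realized counts (default
#'   0.01).
#' @param strand_p Probability a call is on the forward strand (default
#'   0.5).
#' @param motif_fraction Fraction of planted sites written into a
#'   CAUC-motif, palindrome-flanked context (default 0.5).
#' @return Named parameter list.
#' @export
simulation_params <- function(seed, n_pairs = 3, genome_length = 20000,
                              n_genes = 10, coverage_mean = 100,
                              coverage_size = 10, error_rate = 0.002,
                              n_sites = 50, control_shape = c(1, 99),
                              test_shape = c(4, 16), rho = 0.01,
                              strand_p = 0.5, motif_fraction = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(error_rate >= 0, error_rate <= 1, rho >= 0, rho < 1,
            strand_p >= 0, strand_p <= 1,
            motif_fraction >= 0, motif_fraction <= 1)
  as.list(environment())
}

# overwrite genome (plus strand) with coding-sense string s at coding
# offsets off relative to site pos on the given strand
.write_coding <- function(genome_chars, pos, strand, off, s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  stopifnot(length(ch) == length(off))
  if (strand == "+") {
    genome_chars[pos + off] <- ch
  } else {
    genome_chars[pos - off] <- unname(.COMPLEMENT[ch])
  }
  genome_chars
}

# one beta-binomial draw per element; pi may vary, shared rho
.rbetabinom <- function(n, size, pi, rho) {
  if (rho < 1e-12) return(rbinom(n, size, pi))
  s <- (1 - rho) / rho
  p <- rbeta(n, pi * s, (1 - pi) * s)
  rbinom(n, size, p)
}

#' Simulate a paired-pileup editing dataset
#'
#' Generates a synthetic genome, exon/intron gene annotation, per-sample
#' mpileup files for a paired test/control design with planted
#' differentially edited sites, and the ground-truth table. All draws are
#' deterministic given `params$seed`. Non-planted positions carry only
#' sequencing-error mismatches; planted sites draw a per-pair baseline from
#' the condition's level distribution and realize counts beta-binomially.
#'
#' @param params From [simulation_params()].
#' @param dir Output directory (created if needed).
#' @return List with file paths (`genome`, `intervals`, `pileups`, `truth`),
#'   the `truth` data frame, the `pairing`, and the interval table.
#' @export
simulate_dataset <- function(params, dir = tempfile("cuedit_sim_")) {
  p <- params
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(p$seed)
  chrom <- "synth1"
  L <- p$genome_length
  genome_chars <- sample(.BASES, L, replace = TRUE)

  # tile genes with intergenic gaps; exon-intron-exon structure
  gap <- 200L
  span <- (L - (p$n_genes + 1L) * gap) %/% p$n_genes
  if (span < 300L) stop("genome too short for the requested gene count")
  intervals <- do.call(rbind, lapply(seq_len(p$n_genes), function(g) {
    s0 <- gap + (g - 1L) * (span + gap)          # 0-based gene start
    e1 <- floor(span * 0.4); ilen <- floor(span * 0.2)
    strand <- sample(c("+", "-"), 1L)
    gene <- sprintf("GENE%02d", g)
    data.frame(chrom = chrom,
               start = c(s0, s0 + e1, s0 + e1 + ilen),
               end = c(s0 + e1, s0 + e1 + ilen, s0 + span),
               gene = gene, strand = strand,
               feature = c("exon", "intron", "exon"),
               stringsAsFactors = FALSE)
  }))

  # candidate exon positions (1-based), clear of contig ends and each other
  exons <- intervals[intervals$feature == "exon", ]
  exon_pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    (exons$start[i] + 1L):exons$end[i]))
  exon_pos <- exon_pos[exon_pos > 80L & exon_pos < L - 80L]
  sites <- integer(0)
  if (p$n_sites > 0L) {
    for (cand in sample(exon_pos)) {
      if (all(abs(cand - sites) > 80L)) sites <- c(sites, cand)
      if (length(sites) == p$n_sites) break
    }
    if (length(sites) < p$n_sites)
      stop("planted sites exceed genome capacity")
    sites <- sort(sites)
  }

  n_motif <- round(p$motif_fraction * p$n_sites)
  motif <- rep(FALSE, p$n_sites)
  if (n_motif > 0L) motif[sample.int(p$n_sites, n_motif)] <- TRUE

  site_gene <- character(p$n_sites); site_strand <- character(p$n_sites)
  for (i in seq_len(p$n_sites)) {
    hit <- which(exons$start < sites[i] & sites[i] <= exons$end)[1L]
    site_gene[i] <- exons$gene[hit]
    site_strand[i] <- exons$strand[hit]
    if (motif[i]) {
      # coding-sense CCAUCG hexamer (edited C at offset 0) plus a 5-bp
      # palindromic stem directly outside it
      up <- sample(.BASES, 5L, replace = TRUE)
      dn <- rev(unname(.COMPLEMENT[up]))
      s <- c(up, "C", "C", "A", "T", "C", "G", dn)
      genome_chars <- .write_coding(genome_chars, sites[i], site_strand[i],
                                    -9:6, paste(s, collapse = ""))
    } else {
      genome_chars <- .write_coding(genome_chars, sites[i], site_strand[i],
                                    0L, "C")
    }
  }
  site_ref <- genome_chars[sites]                        # plus-strand base
  site_var <- ifelse(site_strand == "+", "T", "A")       # C>T on coding

  pairing <- pair_design(p$n_pairs)
  S <- nrow(pairing)

  # per-pair baselines per site and condition
  ctrl_base <- matrix(rbeta(p$n_sites * p$n_pairs,
                            p$control_shape[1], p$control_shape[2]),
                      p$n_sites, p$n_pairs)
  test_base <- matrix(rbeta(p$n_sites * p$n_pairs,
                            p$test_shape[1], p$test_shape[2]),
                      p$n_sites, p$n_pairs)

  base_idx <- match(genome_chars, .BASES)
  pileup_files <- character(S)
  v_real <- n_real <- matrix(0L, p$n_sites, S)

  for (s in seq_len(S)) {
    depth <- rnbinom(L, size = p$coverage_size, mu = p$coverage_mean)
    vcount <- integer(L)
    if (p$n_sites > 0L) {
      pi_s <- if (pairing$condition[s] == "test")
        test_base[cbind(seq_len(p$n_sites), pairing$pair[s])]
      else ctrl_base[cbind(seq_len(p$n_sites), pairing$pair[s])]
      vcount[sites] <- .rbetabinom(p$n_sites, depth[sites], pi_s, p$rho)
    }
    rest <- depth - vcount
    err <- rbinom(L, rest, p$error_rate)
    e1 <- rbinom(L, err, 1 / 3)
    e2 <- rbinom(L, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    refcount <- rest - err

    counts <- matrix(0L, L, 4L)
    counts[cbind(seq_len(L), base_idx)] <- refcount
    err_split <- cbind(e1, e2, e3)   # errors over the three non-ref bases
    for (b in seq_len(4L)) {
      slot <- b - (base_idx < b)     # this base's column among the non-refs
      is_ref_b <- base_idx == b
      slot[is_ref_b] <- 1L           # placeholder, zeroed below
      add <- err_split[cbind(seq_len(L), slot)]
      add[is_ref_b] <- 0L
      counts[, b] <- counts[, b] + add
    }
    vrow <- match(site_var, .BASES)
    counts[cbind(sites, vrow)] <- counts[cbind(sites, vrow)] + vcount[sites]

    fwd <- matrix(rbinom(4L * L, counts, p$strand_p), L, 4L)
    cm <- cbind(fwd, counts - fwd)
    colnames(cm) <- .COUNT_COLS
    df <- data.frame(chrom = chrom, pos = seq_len(L), ref = genome_chars,
                     cm, stringsAsFactors = FALSE)
    df <- df[rowSums(cm) > 0L, , drop = FALSE]
    class(df) <- c("pileup_sample", "data.frame")
    fn <- file.path(dir, sprintf("pair%d_%s.pileup",
                                 pairing$pair[s], pairing$condition[s]))
    write_pileup(df, fn)
    pileup_files[s] <- fn

    v_real[, s] <- vcount[sites]
    rcol <- match(site_ref, .BASES)
    n_real[, s] <- vcount[sites] + counts[cbind(sites, rcol)]
  }

  genome_file <- file.path(dir, "genome.fa")
  gseq <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(gseq) <- chrom
  Biostrings::writeXStringSet(gseq, genome_file)

  intervals_file <- file.path(dir, "genes.tsv")
  write.table(intervals, intervals_file, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth <- data.frame(chrom = rep(chrom, length(sites)),
                      pos = sites, gene = site_gene,
                      strand = site_strand, ref = site_ref,
                      variant = site_var, motif = motif,
                      rho = rep(p$rho, length(sites)),
                      stringsAsFactors = FALSE)
  for (j in seq_len(p$n_pairs)) {
    truth[[paste0("control_", j)]] <- ctrl_base[, j]
    truth[[paste0("test_", j)]] <- test_base[, j]
  }
  for (s in seq_len(S)) {
    truth[[paste0("v_s", s)]] <- v_real[, s]
    truth[[paste0("n_s", s)]] <- n_real[, s]
  }
  truth_file <- file.path(dir, "truth.tsv")
  write.table(truth, truth_file, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(dir = dir, genome = genome_file, intervals = intervals_file,
       pileups = pileup_files, truth_file = truth_file, truth = truth,
       pairing = pairing, interval_table = intervals)
}

#' Evaluate recovery of planted sites
#'
#' @param calls Data frame of called sites (`chrom`, `pos`; if a `called`
#'   column is present only `TRUE` rows are used).
#' @param truth Truth table from [simulate_dataset()].
#' @param position_tolerance Match slack in bp (default 0).
#' @return List `sensitivity`, `precision`, `fdr`, `n_called`, `n_planted`.
#' @export
evaluate_recovery <- function(calls, truth, position_tolerance = 0) {
  if (!is.null(calls$called)) calls <- calls[calls$called, , drop = FALSE]
  n_called <- nrow(calls)
  n_planted <- nrow(truth)
  match_one <- function(chrom, pos) {
    any(truth$chrom == chrom & abs(truth$pos - pos) <= position_tolerance)
  }
  hit <- if (n_called > 0L)
    mapply(match_one, calls$chrom, calls$pos) else logical(0)
  recovered <- if (n_planted > 0L) {
    sum(vapply(seq_len(n_planted), function(i)
      any(calls$chrom == truth$chrom[i] &
            abs(calls$pos - truth$pos[i]) <= position_tolerance), TRUE))
  } else 0L
  sens <- if (n_planted > 0L) recovered / n_planted else NA_real_
  prec <- if (n_called > 0L) sum(hit) / n_called else NA_real_
  list(sensitivity = sens, precision = prec,
       fdr = if (is.na(prec)) NA_real_ else 1 - prec,
       n_called = n_called, n_planted = n_planted)
}
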