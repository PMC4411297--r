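#' Pipeline configuration
#'
#' All thresholds of the detection cascade in one structure, defaulting to
#' the standard values: candidacy 20/5 calls, 50% reference majority,
#' 2 variant calls in 2 samples, 5-call other-variant cap, 95% purity;
#' level filters 2.5%, 5% group mean, range/mean 2; polymorphism frequency
#' cutoff 0.20; q < 0.05 with > 2-fold change and >= 5% higher-group mean;
#' fold cap 1e4; 29-base flank uniqueness; strand-bias trigger 9.
#'
#' @param seed RNG seed for the run (q-value bootstrap).
#' @param min_base_quality Parser base-quality cutoff (Phred, default 20).
#' @param thresholds Screening thresholds, see [screen_thresholds()].
#' @param q_cut,fold_cut,mean_cut Differential-call thresholds.
#' @param cap Fold-change cap (default 1e4).
#' @param lambda Q-value tuning grid.
#' @param flank Flank-uniqueness query flank length (default 29).
#' @param strand_bias_threshold One-strand-only trigger (default 9).
#' @param strand_bias_test Run the paired strand-bias significance rule?
#' @param secondary_concordance Require concordance in a second-aligner
#'   pileup set (default off; the pipeline consumes pileups regardless of
#'   aligner)?
#' @param structure_engine `"maxpair"` or a folding function.
#' @param context_flank Context window half-width (default 30 nt).
#' @return Named configuration list of class `cu_config`.
#' @export
cu_config <- function(seed = 1, min_base_quality = 20,
                      thresholds = screen_thresholds(), q_cut = 0.05,
                      fold_cut = 2, mean_cut = 0.05, cap = 1e4,
                      lambda = seq(0.05, 0.95, by = 0.05), flank = 29,
                      strand_bias_threshold = 9, strand_bias_test = TRUE,
                      secondary_concordance = FALSE,
                      structure_engine = "maxpair", context_flank = 30) {
  structure(as.list(environment()), class = "cu_config")
}

#' Write / read a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config A `cu_config` list.
#' @param file Path to the YAML file.
#' @return `read_config` returns the `cu_config`; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  if (is.function(x$structure_engine)) x$structure_engine <- "maxpair"
  yaml::write_yaml(x, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  base <- cu_config()
  base[names(x)] <- x
  class(base) <- "cu_config"
  base
}

#' Run the full differential-editing pipeline
#'
#' Stages, in order: parse and merge per-sample pileups; candidacy
#' screening; editing-level filters; polymorphism/gene-annotation
#' exclusions; paired beta-binomial test per site; Storey bootstrap
#' q-values; differential calls (q, fold, group mean; optional
#' second-aligner concordance); flank-uniqueness and strand-bias artifact
#' filters; RNA-change deduction from the coding strand; sequence-context
#' annotation of the final calls. A manifest records thresholds, the seed
#' and per-stage site counts.
#'
#' @param pileup_files Character vector of per-sample mpileup paths, ordered
#'   pair1-test, pair1-control, pair2-test, ...
#' @param genome_file Reference FASTA.
#' @param intervals_file Exon/intron interval TSV (see
#'   [read_gene_intervals()]).
#' @param polymorphisms_file Optional polymorphism TSV.
#' @param secondary_files Optional second-aligner pileup set (same sample
#'   order); used only when `config$secondary_concordance` is on.
#' @param config A [cu_config()].
#' @param output_dir If given, writes `calls.tsv`, `context.tsv` and
#'   `manifest.yaml` there.
#' @return List of class `cu_run`: `calls` (per-tested-site results with
#'   `final_call`), `context` (per final call), `manifest`.
#' @export
run_pipeline <- function(pileup_files, genome_file, intervals_file,
                         polymorphisms_file = NULL, secondary_files = NULL,
                         config = cu_config(), output_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  th <- cfg$thresholds

  samples <- lapply(pileup_files, read_pileup,
                    min_base_quality = cfg$min_base_quality)
  pileup <- merge_samples(samples)
  is_test <- pileup$pairing$condition == "test"

  cand <- screen_sites(pileup, thresholds = th)
  n_screened <- cand$n_screened
  n_pass_screen <- nrow(cand$table)

  lf <- .level_filter_all(cand, th)
  keep_lvl <- lf[, "pass"] == "TRUE"
  cand <- .subset_candidates(cand, keep_lvl)
  n_pass_level <- nrow(cand$table)

  intervals <- read_gene_intervals(intervals_file)
  poly <- if (!is.null(polymorphisms_file))
    read_polymorphisms(polymorphisms_file) else NULL
  ann <- annotation_exclusions(cand, intervals, poly,
                               prevalence_cutoff = th$popfreq_max)
  cand <- .subset_candidates(cand, ann$keep)
  ann <- ann[ann$keep, , drop = FALSE]
  n_pass_annot <- nrow(cand$table)

  res <- cand$table
  res$gene <- ann$gene; res$strand <- ann$strand; res$feature <- ann$feature
  res$mean_test <- rowMeans(cand$levels[, is_test, drop = FALSE])
  res$mean_control <- rowMeans(cand$levels[, !is_test, drop = FALSE])

  # dispersion shared by all sites of the experiment, then per-site tests
  # with it held fixed
  pc <- .paired_count_matrices(cand, is_test)
  rho_pooled <- if (nrow(res) >= 5L)
    as.numeric(estimate_dispersion(pc$v_test, pc$n_test,
                                   pc$v_control, pc$n_control)) else NULL
  fits <- lapply(seq_len(nrow(res)), function(i)
    .fit_site(cand, i, is_test, cfg$cap, rho_pooled))
  res$beta <- vapply(fits, `[[`, 0, "beta")
  res$fold <- vapply(fits, `[[`, 0, "fold")
  res$p <- vapply(fits, `[[`, 0, "p")
  res$rho <- vapply(fits, `[[`, 0, "rho")
  res$q <- if (nrow(res) > 0L) qvalues(res$p, lambda = cfg$lambda)$qvalues
           else numeric(0)

  secondary <- NULL
  if (cfg$secondary_concordance && !is.null(secondary_files)) {
    secondary <- .secondary_results(secondary_files, res, cfg)
  }
  res <- call_differential(res, secondary, q_cut = cfg$q_cut,
                           fold_cut = cfg$fold_cut, mean_cut = cfg$mean_cut)
  n_called <- sum(res$called)

  genome <- Biostrings::readDNAStringSet(genome_file)
  names(genome) <- sub("\\s.*$", "", names(genome))

  res$flank_keep <- rep(TRUE, nrow(res))
  res$strand_keep <- rep(TRUE, nrow(res))
  for (i in which(res$called)) {
    res$flank_keep[i] <- flank_uniqueness_filter(
      res$chrom[i], res$pos[i], res$ref[i], res$variant[i], genome,
      flank = cfg$flank)$keep
    res$strand_keep[i] <- strand_bias_filter(
      cand$v_fwd[i, ], cand$v[i, ], cand$r_fwd[i, ], cand$r[i, ], is_test,
      abs_threshold = cfg$strand_bias_threshold,
      test_bias = cfg$strand_bias_test)$keep
  }
  n_pass_flank <- sum(res$called & res$flank_keep)
  res$final_call <- res$called & res$flank_keep & res$strand_keep
  n_final <- sum(res$final_call)

  res$rna_change <- rep(NA_character_, nrow(res))
  for (i in which(res$final_call)) {
    res$rna_change[i] <- deduce_rna_change(res$ref[i], res$variant[i],
                                           res$strand[i])
  }

  context <- .context_report(res[res$final_call, , drop = FALSE], genome,
                             cfg)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cuedit")),
    seed = cfg$seed,
    thresholds = th,
    q_cut = cfg$q_cut, fold_cut = cfg$fold_cut, mean_cut = cfg$mean_cut,
    cap = cfg$cap, flank = cfg$flank,
    rho_pooled = if (is.null(rho_pooled)) NA_real_ else rho_pooled,
    strand_bias_threshold = cfg$strand_bias_threshold,
    secondary_concordance = cfg$secondary_concordance,
    stage_counts = list(screened = n_screened,
                        candidacy = n_pass_screen,
                        level_filter = n_pass_level,
                        annotation = n_pass_annot,
                        tested = n_pass_annot,
                        differential_call = n_called,
                        flank_filter = n_pass_flank,
                        strand_bias_filter = n_final))

  out <- structure(list(calls = res, context = context, manifest = manifest),
                   class = "cu_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    lev <- cand$levels
    colnames(lev) <- paste0("level_s", seq_len(ncol(lev)))
    write.table(cbind(res, lev), file.path(output_dir, "calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(context, file.path(output_dir, "context.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.cu_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("cu_run: ", sc$screened, " sites screened -> ", sc$tested,
      " tested -> ", sc$strand_bias_filter, " final calls\n", sep = "")
  invisible(x)
}

.subset_candidates <- function(cand, keep) {
  for (nm in c("r", "v", "v_fwd", "r_fwd", "levels"))
    cand[[nm]] <- cand[[nm]][keep, , drop = FALSE]
  cand$table <- cand$table[keep, , drop = FALSE]
  rownames(cand$table) <- NULL
  cand
}

.fit_site <- function(cand, i, is_test, cap, rho = NULL) {
  v <- cand$v[i, ]; r <- cand$r[i, ]
  pair <- cand$pairing$pair
  d <- data.frame(
    v_test = v[is_test][order(pair[is_test])],
    n_test = (v + r)[is_test][order(pair[is_test])],
    v_control = v[!is_test][order(pair[!is_test])],
    n_control = (v + r)[!is_test][order(pair[!is_test])])
  tryCatch(fit_paired_bb(d, cap = cap, rho = rho),
           error = function(e) list(beta = 1, fold = 1, p = 1,
                                    rho = NA_real_))
}

# sites x pairs matrices of paired counts for dispersion pooling
.paired_count_matrices <- function(cand, is_test) {
  pair <- cand$pairing$pair
  ot <- order(pair[is_test]); oc <- order(pair[!is_test])
  v <- cand$v; n <- cand$v + cand$r
  list(v_test = v[, is_test, drop = FALSE][, ot, drop = FALSE],
       n_test = n[, is_test, drop = FALSE][, ot, drop = FALSE],
       v_control = v[, !is_test, drop = FALSE][, oc, drop = FALSE],
       n_control = n[, !is_test, drop = FALSE][, oc, drop = FALSE])
}

.secondary_results <- function(secondary_files, res, cfg) {
  samples <- lapply(secondary_files, read_pileup,
                    min_base_quality = cfg$min_base_quality)
  pileup <- merge_samples(samples)
  is_test <- pileup$pairing$condition == "test"
  calls <- .base_calls(pileup)
  key <- paste(pileup$sites$chrom, pileup$sites$pos)
  idx <- match(paste(res$chrom, res$pos), key)
  out <- res[, c("chrom", "pos")]
  out$beta <- 1; out$p <- 1
  for (i in seq_len(nrow(res))) {
    if (is.na(idx[i])) next
    cm <- matrix(calls[idx[i], , ], 4L, dim(calls)[3L])
    v <- cm[match(res$variant[i], .BASES), ]
    r <- cm[match(res$ref[i], .BASES), ]
    pair <- pileup$pairing$pair
    d <- data.frame(
      v_test = v[is_test][order(pair[is_test])],
      n_test = (v + r)[is_test][order(pair[is_test])],
      v_control = v[!is_test][order(pair[!is_test])],
      n_control = (v + r)[!is_test][order(pair[!is_test])])
    f <- tryCatch(fit_paired_bb(d, cap = cfg$cap), error = function(e) NULL)
    if (!is.null(f)) { out$beta[i] <- f$beta; out$p[i] <- f$p }
  }
  out
}

.context_report <- function(calls, genome, cfg) {
  n <- nrow(calls)
  out <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    gene = calls$gene, rna_change = calls$rna_change,
                    tetramer = rep(NA_character_, n),
                    motif = rep(NA_character_, n),
                    ccaucg = rep(NA, n),
                    palindrome_k = rep(NA_integer_, n),
                    in_loop = rep(NA, n),
                    structure = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    w <- extract_context(genome, calls$chrom[i], calls$pos[i],
                         calls$strand[i], flank = cfg$context_flank)
    ctr <- attr(w, "center")
    if (ctr >= 4L) {
      tet <- substr(w, ctr - 3L, ctr)
      hex <- if (ctr >= 5L && nchar(w) > ctr)
        substr(w, ctr - 4L, ctr + 1L) else NULL
      mc <- motif_class(tet, hex)
      out$tetramer[i] <- tet
      out$motif[i] <- mc$class
      out$ccaucg[i] <- mc$ccaucg
    }
    out$palindrome_k[i] <- as.integer(palindrome_flank(w))
    loop <- site_in_loop(w, engine = cfg$structure_engine)
    out$in_loop[i] <- as.logical(loop)
    out$structure[i] <- as.character(attr(loop, "structure"))
  }
  out
}
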