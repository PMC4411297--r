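# RNA-alphabet helpers (sequences handled as coding-sense RNA)
.as_rna <- function(x) chartr("tT", "uU", toupper(x))
.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")
.rc_rna <- function(x) {
  ch <- rev(strsplit(.as_rna(x), "", fixed = TRUE)[[1L]])
  paste(.RNA_COMP[ch], collapse = "")
}

#' Extract the RNA-sense sequence window around a site
#'
#' Returns the coding-strand sequence of `2*flank + 1` bases centered on the
#' site, as RNA (T relabeled U), so that a C>U edited site reads C at the
#' center. For minus-strand genes the plus-strand genomic sequence is
#' reverse-complemented. Windows truncated at contig ends are returned
#' shorter, with attribute `truncated`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,pos Site location (1-based).
#' @param strand Gene-coding strand, `"+"` or `"-"`.
#' @param flank Bases on each side (default 30).
#' @return Character RNA window with attributes `center` (index of the site
#'   within the window) and `truncated`.
#' @export
extract_context <- function(genome, chrom, pos, strand, flank = 30) {
  chr_seq <- genome[[chrom]]
  lo <- max(1L, pos - flank)
  hi <- min(length(chr_seq), pos + flank)
  dna <- Biostrings::subseq(chr_seq, lo, hi)
  center <- pos - lo + 1L
  if (strand == "-") {
    dna <- Biostrings::reverseComplement(dna)
    center <- hi - pos + 1L
  }
  out <- .as_rna(as.character(dna))
  attr(out, "center") <- center
  attr(out, "truncated") <- (hi - lo + 1L) < (2L * flank + 1L)
  out
}

#' Classify the tetramer motif of an edited site
#'
#' Edited C>U sites occur preferentially within a CAUC tetramer (positions
#' -3..0, edited base last) or one of its 1-nt variants CACC, CCUC, CUUC and
#' UAUC; the most common full context is the CCAUCG hexamer.
#'
#' @param tetramer 4-letter RNA string ending at the edited base.
#' @param hexamer Optional 6-letter context (positions -4..+1) checked
#'   against CCAUCG.
#' @return List with `class` (`canonical`, `variant`, `other`) and `ccaucg`
#'   (logical or `NA` if no hexamer given).
#' @export
motif_class <- function(tetramer, hexamer = NULL) {
  tet <- .as_rna(tetramer)
  if (nchar(tet) != 4L) stop("tetramer must have length 4")
  cls <- if (tet == "CAUC") "canonical"
         else if (tet %in% c("CACC", "CCUC", "CUUC", "UAUC")) "variant"
         else "other"
  ccaucg <- NA
  if (!is.null(hexamer)) {
    hx <- .as_rna(hexamer)
    if (nchar(hx) != 6L) stop("hexamer must have length 6")
    ccaucg <- hx == "CCAUCG"
  }
  list(class = cls, ccaucg = ccaucg)
}

#' Per-position relative entropy of aligned sequence windows
#'
#' For each position j, computes \eqn{R_j = \sum_b p_{jb} \log_2
#' (p_{jb}/q_b)} over the observed base frequencies against a background
#' (uniform by default), i.e. the per-column information content of a
#' sequence logo, with a bootstrap mean and 95% CI.
#'
#' @param windows Character vector of equal-length RNA windows.
#' @param background Background base probabilities for A, C, G, U.
#' @param n_boot Bootstrap resamples (default 1000; 0 disables the CI).
#' @return Data frame with `position` (1-based column index), `entropy`
#'   (bits), and bootstrap `boot_mean`, `ci_lo`, `ci_hi`.
#' @export
relative_entropy <- function(windows, background = rep(0.25, 4),
                             n_boot = 1000) {
  if (length(windows) == 0L) stop("need at least one sequence")
  windows <- .as_rna(windows)
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows must have equal length")
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  bases <- c("A", "C", "G", "U")
  re_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      p <- tabulate(match(m[, j], bases), 4L)
      p <- p / sum(p)
      sum(ifelse(p > 0, p * log2(p / background), 0))
    }, 0)
  }
  r <- re_of(mat)
  out <- data.frame(position = seq_len(L), entropy = r,
                    boot_mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  if (n_boot > 0L && nrow(mat) > 1L) {
    boot <- matrix(0, n_boot, L)
    for (b in seq_len(n_boot)) {
      boot[b, ] <- re_of(mat[sample.int(nrow(mat), replace = TRUE), ,
                             drop = FALSE])
    }
    out$boot_mean <- colMeans(boot)
    out$ci_lo <- apply(boot, 2L, quantile, 0.025)
    out$ci_hi <- apply(boot, 2L, quantile, 0.975)
  }
  out
}

#' Longest reverse-complement palindrome flanking an edited site
#'
#' Searches for the longest k in `k_range` such that a k-mer ending just
#' upstream of the site's tetramer (position -4-a for an offset a up to
#' `max_offset`) is the reverse complement of a k-mer starting just
#' downstream of the edited base (position 1+b); such flanks can base-pair
#' into the stem of a stem-loop presenting the edited C.
#'
#' @param window RNA window (e.g. from [extract_context()]).
#' @param k_range Palindrome lengths searched (default 2..7).
#' @param max_offset Maximum gap allowed between the tetramer and either arm
#'   (default 2).
#' @param center Index of the edited base within `window` (defaults to the
#'   `center` attribute, else the middle).
#' @return Largest matching k, or 0; attribute `truncated` set if the window
#'   was too short for part of the search.
#' @export
palindrome_flank <- function(window, k_range = c(2L, 7L), max_offset = 2L,
                             center = NULL) {
  w <- .as_rna(window)
  if (is.null(center)) {
    center <- attr(window, "center")
    if (is.null(center)) center <- (nchar(w) + 1L) %/% 2L
  }
  L <- nchar(w)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  ks <- seq(max(k_range), min(k_range))
  truncated <- FALSE
  for (k in ks) {
    for (a in 0:max_offset) {
      up_end <- center - 4L - a
      up_start <- up_end - k + 1L
      for (b in 0:max_offset) {
        dn_start <- center + 1L + b
        dn_end <- dn_start + k - 1L
        if (up_start < 1L || dn_end > L) { truncated <- TRUE; next }
        up <- paste(ch[up_start:up_end], collapse = "")
        dn <- paste(ch[dn_start:dn_end], collapse = "")
        if (.rc_rna(up) == dn)
          return(structure(k, truncated = truncated))
      }
    }
  }
  structure(0L, truncated = truncated)
}

# Watson-Crick + G.U wobble pairing
.can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

#' Maximum base-pairing secondary structure (Nussinov)
#'
#' Computes a maximum base-pair structure by the Nussinov recurrence with
#' Watson-Crick and G.U pairs and a minimum hairpin loop of `min_loop`
#' unpaired bases, returning a dot-bracket string. Tie-breaking is
#' deterministic (leaving a base unpaired is preferred, then the smallest
#' pairing partner), so results are reproducible. This is a combinatorial
#' approximation, not a thermodynamic minimum-free-energy structure.
#'
#' @param seq RNA sequence (A/C/G/U; T accepted and read as U).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return Dot-bracket string with attribute `n_pairs`.
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  s <- strsplit(.as_rna(seq), "", fixed = TRUE)[[1L]]
  if (!all(s %in% c("A", "C", "G", "U")))
    stop("sequence must contain only A, C, G, U (or T)")
  n <- length(s)
  db <- rep(".", n)
  if (n >= min_loop + 2L) {
    M <- matrix(0L, n, n)
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]                      # i unpaired
        ks <- (i + min_loop + 1L):j
        for (k in ks) {
          if (.can_pair(s[i], s[k])) {
            left <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
            right <- if (k + 1L <= j) M[k + 1L, j] else 0L
            best <- max(best, left + right + 1L)
          }
        }
        M[i, j] <- best
      }
    }
    # deterministic traceback
    stack <- list(c(1L, n))
    while (length(stack) > 0L) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      if (j - i <= min_loop) next
      if (M[i, j] == M[i + 1L, j]) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
        next
      }
      for (k in (i + min_loop + 1L):j) {
        if (!.can_pair(s[i], s[k])) next
        left <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        right <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (M[i, j] == left + right + 1L) {
          db[i] <- "("; db[k] <- ")"
          if (k - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  structure(paste(db, collapse = ""), n_pairs = sum(db == "("))
}

#' Is the edited base in the loop of a stem-loop?
#'
#' Folds the window (built-in base-pair-maximization engine, or a supplied
#' sequence-to-dot-bracket function such as a thermodynamic folder) and
#' reports whether the edited base is unpaired yet enclosed by at least one
#' base pair -- i.e. presented in a loop.
#'
#' @param window RNA window with the edited base at `center`.
#' @param center Index of the edited base (defaults to the `center`
#'   attribute, else the middle).
#' @param engine `"maxpair"` for the built-in Nussinov engine, or a function
#'   `seq -> dot-bracket string`.
#' @return `TRUE`, `FALSE`, or `NA` (unknown, e.g. engine failure); the
#'   dot-bracket string is attached as attribute `structure` and the engine
#'   name as `engine`.
#' @export
site_in_loop <- function(window, center = NULL, engine = "maxpair") {
  w <- .as_rna(window)
  if (is.null(center)) {
    center <- attr(window, "center")
    if (is.null(center)) center <- (nchar(w) + 1L) %/% 2L
  }
  db <- if (is.function(engine)) {
    tryCatch(engine(w), error = function(e) NA_character_)
  } else {
    nussinov_fold(w)
  }
  engine_name <- if (is.function(engine)) "external" else "maxpair"
  if (is.na(db) || nchar(db) != nchar(w))
    return(structure(NA, structure = db, engine = engine_name))
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  unpaired <- ch[center] == "."
  before <- ch[seq_len(center - 1L)]
  enclosed <- sum(before == "(") > sum(before == ")")
  structure(unpaired && enclosed, structure = db, engine = engine_name)
}
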