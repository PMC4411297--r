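#' Parse samtools mpileup text into strand-split base counts
#'
#' Reads the 6-column samtools mpileup text dialect (chromosome, 1-based
#' position, reference base, depth, read bases, base qualities) for one
#' sample and decodes the read-base column into per-site A/C/G/T call counts
#' split by read strand. `.`/`,` count as the reference base on the
#' forward/reverse strand, upper/lower-case letters as that base on the
#' forward/reverse strand; read-start (`^` plus mapping-quality byte),
#' read-end (`$`) marks and indel strings are consumed without contributing
#' calls; `*`, `#`, `>` and `<` occupy a read slot but contribute nothing.
#' Calls whose Phred+33 base quality is below `min_base_quality` are
#' excluded.
#'
#' @param file Path to an mpileup text file (optionally gzip-compressed), or
#'   a connection.
#' @param min_base_quality Minimum Phred base quality for a call to be
#'   counted (default 20, i.e. q > 19).
#' @return A data frame of class `pileup_sample` with columns `chrom`,
#'   `pos` (1-based), `ref`, and the eight count columns `A_fwd` ... `T_rev`.
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t100\tG\t6\t..,,Aa\tFFFFFF", tf)
#' read_pileup(tf)
#' @export
read_pileup <- function(file, min_base_quality = 20) {
  lines <- readLines(file)
  parse_pileup(lines, min_base_quality = min_base_quality)
}

#' @rdname read_pileup
#' @param lines Character vector of raw mpileup lines.
#' @export
parse_pileup <- function(lines, min_base_quality = 20) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.empty_pileup_sample())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # tolerate space-separated toy input (no spaces occur inside real columns
  # we use, and Phred+33 quality bytes are never the space character)
  if (any(nf < 6L)) {
    fields[nf < 6L] <- strsplit(lines[nf < 6L], "[ \t]+")
    nf <- lengths(fields)
  }
  if (any(nf < 6L)) {
    stop("malformed pileup line ", which(nf < 6L)[1L], ": expected 6 fields")
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:6))
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  depth <- suppressWarnings(as.integer(mat[, 4L]))
  if (anyNA(pos) || anyNA(depth)) {
    stop("malformed pileup line ", which(is.na(pos) | is.na(depth))[1L],
         ": non-numeric position or depth")
  }
  dec <- .decode_pileup_calls(mat[, 5L], mat[, 6L], mat[, 3L], depth,
                              as.integer(min_base_quality))
  if (dec$bad_line > 0L) {
    stop("malformed pileup line ", dec$bad_line, ": ", dec$reason)
  }
  counts <- dec$counts
  colnames(counts) <- .COUNT_COLS
  out <- data.frame(chrom = mat[, 1L], pos = pos,
                    ref = toupper(mat[, 3L]), counts,
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup_sample", "data.frame")
  out
}

.empty_pileup_sample <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    stringsAsFactors = FALSE)
  for (cc in .COUNT_COLS) out[[cc]] <- integer()
  class(out) <- c("pileup_sample", "data.frame")
  out
}

#' Write strand-split base counts back to mpileup text
#'
#' Emits one mpileup record per site, reconstructing a read-base string from
#' the counts (reference calls as `.`/`,`, variant calls as upper/lower-case
#' letters) with a constant base quality. Re-parsing the output recovers the
#' counts exactly.
#'
#' @param x A `pileup_sample` data frame (see [read_pileup()]).
#' @param file Output path or connection.
#' @param quality Phred base quality assigned to every emitted call
#'   (default 30).
#' @return `file`, invisibly.
#' @export
write_pileup <- function(x, file, quality = 30) {
  qc <- rawToChar(as.raw(33L + quality))
  cm <- as.matrix(x[, .COUNT_COLS])
  ref <- toupper(x$ref)
  sym <- matrix("", nrow(cm), 8L)
  for (j in seq_along(.BASES)) {
    is_ref <- ref == .BASES[j]
    sym[, j] <- ifelse(is_ref, ".", .BASES[j])
    sym[, j + 4L] <- ifelse(is_ref, ",", tolower(.BASES[j]))
  }
  depth <- rowSums(cm)
  bases <- do.call(paste0, lapply(seq_len(8L), function(j)
    strrep(sym[, j], cm[, j])))
  bases[depth == 0L] <- "*"   # placeholder so the column is never empty
  quals <- strrep(qc, pmax(depth, 1L))
  writeLines(paste(x$chrom, x$pos, ref, depth, bases, quals, sep = "\t"),
             file)
  invisible(file)
}

#' Pair design for a paired test/control pileup experiment
#'
#' Samples are ordered pair1-test, pair1-control, pair2-test, ... throughout
#' the package.
#'
#' @param n_pairs Number of test/control pairs.
#' @return Data frame with columns `sample` (index), `pair`, `condition`.
#' @export
pair_design <- function(n_pairs) {
  stopifnot(n_pairs >= 1)
  data.frame(sample = seq_len(2L * n_pairs),
             pair = rep(seq_len(n_pairs), each = 2L),
             condition = rep(c("test", "control"), n_pairs),
             stringsAsFactors = FALSE)
}

#' Merge per-sample pileups into one multi-sample site table
#'
#' Takes one parsed pileup per sample (all sorted by chromosome and
#' position), unions their positions, zero-fills counts for positions a
#' sample does not cover, and checks that the reference base agrees across
#' samples at every site.
#'
#' @param samples List of `pileup_sample` data frames, ordered as in
#'   `pairing` (pair1-test, pair1-control, ...).
#' @param pairing Pairing metadata, e.g. from [pair_design()]; defaults to
#'   `pair_design(length(samples)/2)`.
#' @return An object of class `cu_pileup`: a list with `sites` (data frame
#'   `chrom`, `pos`, `ref`), `counts` (integer array site x 8 x sample) and
#'   `pairing`.
#' @export
merge_samples <- function(samples, pairing = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(pairing)) {
    if (length(samples) %% 2L != 0L)
      stop("need an even number of samples (or explicit pairing)")
    pairing <- pair_design(length(samples) / 2L)
  }
  stopifnot(nrow(pairing) == length(samples))
  key <- unique(do.call(rbind, lapply(samples, function(s)
    s[, c("chrom", "pos", "ref"), drop = FALSE])))
  dup <- duplicated(key[, c("chrom", "pos")])
  if (any(dup)) {
    d <- key[dup, ][1L, ]
    stop("inconsistent reference base across samples at ",
         d$chrom, ":", d$pos)
  }
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  rownames(key) <- NULL
  n <- nrow(key)
  kid <- paste(key$chrom, key$pos)
  counts <- array(0L, dim = c(n, 8L, length(samples)),
                  dimnames = list(NULL, .COUNT_COLS, NULL))
  for (s in seq_along(samples)) {
    ss <- samples[[s]]
    idx <- match(paste(ss$chrom, ss$pos), kid)
    counts[idx, , s] <- as.matrix(ss[, .COUNT_COLS])
  }
  structure(list(sites = key, counts = counts, pairing = pairing),
            class = "cu_pileup")
}

#' @export
print.cu_pileup <- function(x, ...) {
  cat("cu_pileup: ", nrow(x$sites), " sites x ", dim(x$counts)[3L],
      " samples (", max(x$pairing$pair), " pairs)\n", sep = "")
  invisible(x)
}

# site x 4 x sample array of strand-summed A/C/G/T calls
.base_calls <- function(pileup) {
  counts <- pileup$counts
  out <- counts[, 1:4, , drop = FALSE] + counts[, 5:8, , drop = FALSE]
  dimnames(out)[[2]] <- .BASES
  out
}
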