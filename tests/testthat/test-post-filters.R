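random_genome <- function(n, seed) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

test_that("flank uniqueness drops duplicated 30-mers, either orientation", {
  g <- random_genome(2000, 11)
  pos <- 600
  ref <- as.character(Biostrings::subseq(g[[1]], pos, pos))
  variant <- setdiff(c("A", "C", "G", "T"), ref)[1]

  # unique site in a random genome is kept (brute-force scan confirms below)
  expect_true(flank_uniqueness_filter("chr1", pos, ref, variant, g)$keep)

  # plant an exact copy of the left query elsewhere
  left30 <- as.character(Biostrings::subseq(g[[1]], pos - 29, pos))
  g2 <- g
  g2[[1]] <- Biostrings::xscat(g[[1]], Biostrings::DNAString(left30))
  expect_false(flank_uniqueness_filter("chr1", pos, ref, variant, g2)$keep)

  # duplicate present only as the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(left30)))
  g3 <- g
  g3[[1]] <- Biostrings::xscat(g[[1]], Biostrings::DNAString(rc))
  expect_false(flank_uniqueness_filter("chr1", pos, ref, variant, g3)$keep)

  # near a contig end the queries are truncated and flagged
  near <- flank_uniqueness_filter("chr1", 10,
    as.character(Biostrings::subseq(g[[1]], 10, 10)), variant, g)
  expect_true(near$truncated)
})

test_that("flank filter agrees with an exhaustive scan on random sites", {
  g <- random_genome(3000, 12)
  gs <- as.character(g[[1]])
  set.seed(13)
  for (pos in sample(40:2960, 15)) {
    ref <- substr(gs, pos, pos)
    variant <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- flank_uniqueness_filter("chr1", pos, ref, variant, g)$keep
    # oracle: slide every 30-mer query over the genome by hand
    queries <- c(paste0(substr(gs, pos - 29, pos - 1), ref),
                 paste0(substr(gs, pos - 29, pos - 1), variant),
                 paste0(ref, substr(gs, pos + 1, pos + 29)),
                 paste0(variant, substr(gs, pos + 1, pos + 29)))
    own <- c(pos - 29, pos - 29, pos, pos)
    rc_of <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(x)))
    dup <- FALSE
    for (qi in seq_along(queries)) {
      q <- queries[qi]
      for (st in seq_len(nchar(gs) - 29)) {
        frag <- substr(gs, st, st + 29)
        if ((frag == q || frag == rc_of(q)) && st != own[qi]) dup <- TRUE
      }
    }
    expect_equal(got, !dup)
  }
})

test_that("strand-bias rule (a) triggers strictly above nine one-strand reads", {
  is_t <- rep(c(TRUE, FALSE), 3)
  v <- rep(2L, 6); r <- rep(50L, 6)
  rf <- rep(25L, 6)

  ten <- strand_bias_filter(c(4, 2, 2, 1, 1, 0), v = c(4, 2, 2, 1, 1, 0),
                            r_fwd = rf, r = r, is_test = is_t)
  expect_false(ten$keep)
  expect_equal(ten$reason, "one_strand")

  nine <- strand_bias_filter(c(4, 2, 1, 1, 1, 0), v = c(4, 2, 1, 1, 1, 0),
                             r_fwd = rf, r = r, is_test = is_t)
  expect_true(nine$keep)

  balanced <- strand_bias_filter(rep(5L, 6), v = rep(10L, 6),
                                 r_fwd = rep(25L, 6), r = rep(50L, 6),
                                 is_test = is_t)
  expect_true(balanced$keep)

  none <- strand_bias_filter(rep(0L, 6), v = rep(0L, 6),
                             r_fwd = rf, r = r, is_test = is_t)
  expect_true(none$keep)
  expect_true(none$no_variant)
})

test_that("strand-bias significance sub-rule drops grossly skewed variants", {
  is_t <- rep(c(TRUE, FALSE), 3)
  # all 60 test variant calls forward, reference balanced: dropped by the
  # paired significance test even though reverse reads exist (rule (a) no)
  sb <- strand_bias_filter(v_fwd = c(20, 5, 19, 5, 18, 5),
                           v = c(20, 10, 20, 10, 20, 10),
                           r_fwd = c(40, 40, 40, 40, 40, 40),
                           r = rep(80L, 6), is_test = is_t)
  expect_false(sb$keep)
  expect_equal(sb$reason, "bias_test")
})

test_that("RNA change deduction respects the coding strand", {
  expect_equal(deduce_rna_change("G", "A", "-"), "C>U")
  expect_equal(deduce_rna_change("C", "T", "+"), "C>U")
  expect_equal(deduce_rna_change("A", "G", "+"), "A>I (A>G)")
  expect_equal(deduce_rna_change("T", "C", "-"), "A>I (A>G)")
  expect_error(deduce_rna_change("N", "A", "+"))

  # minus-strand deduction equals plus-strand deduction of the complements
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in names(comp)) for (var in setdiff(names(comp), ref)) {
    expect_equal(deduce_rna_change(ref, var, "-"),
                 deduce_rna_change(comp[[ref]], comp[[var]], "+"))
  }
})

test_that("artifact filters commute", {
  g <- random_genome(2000, 14)
  is_t <- rep(c(TRUE, FALSE), 3)
  set.seed(15)
  for (i in 1:10) {
    pos <- sample(100:1900, 1)
    ref <- as.character(Biostrings::subseq(g[[1]], pos, pos))
    variant <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- rbinom(6, 30, 0.4); vf <- rbinom(6, v, 0.5)
    r <- rbinom(6, 80, 0.9); rf <- rbinom(6, r, 0.5)
    fk <- flank_uniqueness_filter("chr1", pos, ref, variant, g)$keep
    sk <- strand_bias_filter(vf, v, rf, r, is_t)$keep
    sk2 <- strand_bias_filter(vf, v, rf, r, is_t)$keep
    fk2 <- flank_uniqueness_filter("chr1", pos, ref, variant, g)$keep
    expect_equal(fk && sk, sk2 && fk2)
  }
})
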