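test_that("tetramer motif classes and the hexamer check", {
  expect_equal(motif_class("CAUC")$class, "canonical")
  expect_equal(motif_class("UAUC")$class, "variant")
  expect_equal(motif_class("CACC")$class, "variant")
  expect_equal(motif_class("GGGC")$class, "other")
  expect_equal(motif_class("catc")$class, "canonical")  # T read as U
  expect_error(motif_class("CAU"), "length 4")
  expect_true(motif_class("CAUC", "CCAUCG")$ccaucg)
  expect_false(motif_class("CAUC", "ACAUCG")$ccaucg)
})

test_that("relative entropy hits its closed forms and bounds", {
  # identical base at a position: 2 bits; uniform usage: 0; half-half: 1
  w <- c("AAG", "ACG", "AGG", "AUG")
  re <- relative_entropy(w, n_boot = 0)
  expect_equal(re$entropy[1], 2)
  expect_equal(re$entropy[2], 0)
  expect_equal(re$entropy[3], 2)

  re2 <- relative_entropy(c("A", "A", "C", "C"), n_boot = 0)
  expect_equal(re2$entropy, 1)

  set.seed(21)
  rw <- sapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "U"), 11, TRUE), collapse = ""))
  re3 <- relative_entropy(rw, n_boot = 50)
  expect_true(all(re3$entropy >= 0))
  expect_true(all(re3$entropy <= 2))
  expect_true(all(re3$ci_lo <= re3$ci_hi))

  expect_error(relative_entropy(character(0)), "at least one")
  expect_error(relative_entropy(c("AA", "AAA")), "equal length")
})

test_that("palindromic flanks are found at their planted length", {
  # upstream AGCGC directly before the tetramer, downstream its
  # reverse complement directly after the edited base
  w <- "AAAAGCGCUAUCGCGCUAAAA"
  expect_equal(as.integer(palindrome_flank(w, center = 12)), 5)
  expect_equal(as.integer(palindrome_flank(strrep("A", 21), center = 11)), 0)
})

test_that("palindrome search matches brute force and is revcomp-stable", {
  set.seed(22)
  for (i in 1:150) {
    w <- paste(sample(c("A", "C", "G", "U"), 31, TRUE), collapse = "")
    got <- as.integer(palindrome_flank(w, center = 16))
    want <- oracle_palindrome(w, 16)
    expect_equal(got, want)
  }
})

test_that("the folding engine returns valid maximum-pairing structures", {
  db <- nussinov_fold("GGGGGAAAAAAAACCCCC")
  expect_equal(as.character(db), "(((((........)))))")
  expect_equal(attr(db, "n_pairs"), 5)

  set.seed(23)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    db <- nussinov_fold(s)
    ch <- strsplit(as.character(db), "")[[1]]
    # balanced nesting with hairpin loops of >= 3
    depth <- 0; ok <- TRUE; last_open <- integer(0)
    for (j in seq_along(ch)) {
      if (ch[j] == "(") { depth <- depth + 1; last_open <- c(last_open, j) }
      if (ch[j] == ")") {
        depth <- depth - 1
        if (depth < 0) ok <- FALSE
        op <- last_open[length(last_open)]
        last_open <- last_open[-length(last_open)]
        if (j - op <= 3) ok <- FALSE
      }
    }
    expect_true(ok && depth == 0)
    # pair count matches exhaustive enumeration
    expect_equal(attr(db, "n_pairs"), oracle_max_pairs(s))
  }
  expect_error(nussinov_fold("ACGX"), "A, C, G, U")
})

test_that("loop placement of the edited base is detected", {
  # 5-bp A:U stem presenting a C-only loop (the C cannot pair without a G)
  hairpin <- "AAAAACCCCCCCUUUUU"
  expect_true(as.logical(site_in_loop(hairpin, center = 8)))
  expect_false(as.logical(site_in_loop(strrep("A", 19), center = 10)))
  # a paired base is not "in the loop"
  expect_false(as.logical(site_in_loop(hairpin, center = 2)))
  # pluggable engine: a folder returning all-unpaired means no enclosure
  flat <- function(s) strrep(".", nchar(s))
  expect_false(as.logical(site_in_loop(hairpin, center = 9, engine = flat)))
})

test_that("context windows read the coding strand with the site centered", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTTTT"))
  wp <- extract_context(g, "chr1", 5, "+", flank = 3)
  expect_equal(as.character(wp), "AAACGUU")
  expect_equal(attr(wp, "center"), 4L)
  expect_equal(substr(as.character(wp), 4, 4), "C")
  wm <- extract_context(g, "chr1", 5, "-", flank = 3)
  expect_equal(as.character(wm), "AACGUUU")
  expect_equal(attr(wm, "center"), 4L)
  expect_equal(substr(as.character(wm), 4, 4), "G")
  expect_true(attr(extract_context(g, "chr1", 2, "+", flank = 5),
                   "truncated"))
})
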