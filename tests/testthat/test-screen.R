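pairing6 <- pair_design(3)
is_test6 <- pairing6$condition == "test"

# 4 x 6 count table: ref counts then one variant row
tab_from <- function(ref_counts, var_counts, ref = "G", variant = "A") {
  m <- matrix(0L, 4, length(ref_counts),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[ref, ] <- as.integer(ref_counts)
  m[variant, ] <- as.integer(var_counts)
  m
}

test_that("editing level is the variant fraction with a degenerate flag", {
  expect_equal(as.numeric(editing_level(10, 90)), 0.10)
  expect_equal(as.numeric(editing_level(0, 50)), 0)
  expect_equal(as.numeric(editing_level(1, 3)), 0.25)
  z <- editing_level(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(editing_level(-1, 5), "non-negative")
})

test_that("candidacy criteria match the stated rules on boundary tables", {
  # variant support via the test group even with one stray control call
  m <- tab_from(rep(c(90, 100), 3), c(10, 0, 10, 1, 10, 0))
  r <- screen_site(m, "G", pairing6)
  expect_true(r$pass)
  expect_equal(r$variant, "A")
  o <- oracle_screen(m, "G", is_test6)
  expect_equal(r$pass, o$pass)

  # 19 calls everywhere fails the >=20-in-a-pair clause
  m2 <- tab_from(rep(16, 6), rep(3, 6))
  r2 <- screen_site(m2, "G", pairing6)
  expect_false(r2$pass)
  expect_true("calls" %in% r2$reasons)

  # two distinct variants with 6 calls violate the other-variant cap
  m3 <- tab_from(rep(100, 6), rep(6, 6))
  m3["C", 1] <- 6L
  r3 <- screen_site(m3, "G", pairing6)
  expect_false(r3$pass)
  expect_true("variant_support" %in% r3$reasons)
})

test_that("screening agrees with the brute-force checker on random tables", {
  set.seed(2024)
  for (i in 1:2000) {
    m <- random_count_table()
    ref <- sample(c("A", "C", "G", "T"), 1)
    got <- screen_site(m, ref, pairing6)
    want <- oracle_screen(m, ref, is_test6)
    expect_identical(got$pass, want$pass)
    expect_identical(sort(got$reasons), sort(want$reasons))
    if (got$pass) expect_identical(got$variant, want$variant)
  }
})

test_that("screening verdicts are monotone where the rules imply it", {
  set.seed(7)
  for (i in 1:200) {
    m <- random_count_table()
    ref <- sample(c("A", "C", "G", "T"), 1)
    r <- screen_site(m, ref, pairing6)
    if (r$pass) {
      # adding variant calls to a test sample keeps criterion 3 satisfied
      m2 <- m
      m2[r$variant, 1] <- m2[r$variant, 1] + 5L
      r2 <- screen_site(m2, ref, pairing6)
      expect_false("variant_support" %in% r2$reasons)
    }
    # scaling all counts preserves the proportion-based criteria (2) and (4)
    r3 <- screen_site(m * 3L, ref, pairing6)
    expect_equal("ref_majority" %in% r$reasons,
                 "ref_majority" %in% r3$reasons)
    expect_equal("purity" %in% r$reasons, "purity" %in% r3$reasons)
  }
})

test_that("level filters apply the 2.5% / 5% / range-mean rules", {
  lv <- c(0.10, 0.12, 0.11, 0.001, 0, 0.002)  # tests then controls
  is_t <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_true(level_filter(lv, is_t)$pass)

  flat <- level_filter(rep(0.05, 6), is_t)
  expect_false(flat$pass)
  expect_equal(flat$reasons, "range_mean")

  weak <- level_filter(c(0.02, 0.02, 0.02, 0, 0, 0), is_t)
  expect_false(weak$pass)
  expect_true(all(c("level", "group_mean") %in% weak$reasons))

  zero <- level_filter(rep(0, 6), is_t)
  expect_false(zero$pass)
  expect_true(zero$degenerate)
})

test_that("annotation exclusions drop and assign sites as specified", {
  iv <- data.frame(
    chrom = "chr1",
    start = c(0, 100, 0, 300, 300, 500),
    end = c(100, 200, 200, 400, 400, 600),
    gene = c("X", "X", "Y", "P", "Q", "Z"),
    strand = c("+", "+", "-", "+", "-", "+"),
    feature = c("exon", "intron", "intron", "exon", "exon", "exon"),
    stringsAsFactors = FALSE)
  cand <- data.frame(chrom = "chr1",
                     pos = c(50, 150, 250, 350, 550),
                     ref = "G", variant = "A",
                     stringsAsFactors = FALSE)
  poly <- data.frame(chrom = "chr1", pos = 550, ref = "G", alt = "A",
                     max_freq = 0.25, stringsAsFactors = FALSE)
  out <- annotation_exclusions(cand, iv, poly)

  # exon of X(+) over intron of Y(-): kept, exon-bearing gene wins
  expect_true(out$keep[1])
  expect_equal(out$gene[1], "X")
  expect_equal(out$feature[1], "exon")
  # intron of X(+) and intron of Y(-): introns of >1 genes on both strands
  expect_false(out$keep[2])
  expect_equal(out$reason[2], "ambiguous_intron")
  # no overlapping interval
  expect_false(out$keep[3])
  expect_equal(out$reason[3], "no_gene")
  # exons of two genes on both strands
  expect_false(out$keep[4])
  expect_equal(out$reason[4], "ambiguous_exon")
  # known polymorphism above the prevalence cutoff
  expect_false(out$keep[5])
  expect_equal(out$reason[5], "polymorphism")
})
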