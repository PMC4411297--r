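# Independent oracles, written as literal transcriptions of the rules they
# check, deliberately naive and separate from the package implementation.

# ---- candidacy screening: brute-force rule checker ------------------------
# calls: 4 x S matrix (A,C,G,T); returns pass/fail, chosen variant and the
# list of violated criteria, by checking each clause longhand.
oracle_screen <- function(calls, ref, is_test) {
  S <- ncol(calls)
  bases <- c("A", "C", "G", "T")
  totals <- numeric(S)
  for (s in 1:S) totals[s] <- sum(calls[, s])
  ref_i <- which(bases == ref)

  # criterion 1
  pair_ok <- FALSE
  for (j in seq_len(S / 2)) {
    a <- 2 * j - 1; b <- 2 * j
    if (totals[a] >= 20 && totals[b] >= 20) pair_ok <- TRUE
  }
  all5 <- TRUE
  for (s in 1:S) if (totals[s] < 5) all5 <- FALSE
  c1 <- pair_ok && all5

  # criterion 2
  maj <- logical(S)
  for (s in 1:S) maj[s] <- calls[ref_i, s] >= 0.5 * totals[s]
  c2 <- all(maj[is_test]) || all(maj[!is_test])

  # criterion 3, per candidate variant base
  cand_ok <- rep(FALSE, 4)
  for (b in 1:4) {
    if (b == ref_i) next
    two_in_two_test <- sum(calls[b, is_test] >= 2) >= 2
    two_in_two_ctrl <- sum(calls[b, !is_test] >= 2) >= 2
    one_in_all_test <- all(calls[b, is_test] >= 1)
    one_in_all_ctrl <- all(calls[b, !is_test] >= 1)
    others_ok <- TRUE
    for (o in 1:4) {
      if (o == ref_i || o == b) next
      for (s in 1:S) if (calls[o, s] > 5) others_ok <- FALSE
    }
    cand_ok[b] <- (two_in_two_test || two_in_two_ctrl) &&
      (one_in_all_test || one_in_all_ctrl) && others_ok
  }
  c3 <- any(cand_ok)
  if (c3) {
    cands <- which(cand_ok)
    tot_b <- sapply(cands, function(b) sum(calls[b, ]))
    variant <- bases[min(cands[tot_b == max(tot_b)])]
  } else {
    nonref <- setdiff(1:4, ref_i)
    tot_b <- sapply(nonref, function(b) sum(calls[b, ]))
    variant <- bases[min(nonref[tot_b == max(tot_b)])]
  }
  v_i <- which(bases == variant)

  # criterion 4 with the chosen variant
  c4 <- TRUE
  for (s in 1:S) {
    if (calls[ref_i, s] + calls[v_i, s] < 0.95 * totals[s]) c4 <- FALSE
  }

  list(pass = c1 && c2 && c3 && c4, variant = variant,
       reasons = c("calls", "ref_majority", "variant_support",
                   "purity")[!c(c1, c2, c3, c4)])
}

random_count_table <- function(max_count = 200, n_samples = 6) {
  m <- matrix(0L, 4, n_samples)
  for (s in seq_len(n_samples)) {
    # mostly reference-dominated tables with occasional variants, so that
    # all criteria get exercised rather than only trivial rejections
    style <- sample(3, 1)
    if (style == 1) {
      m[, s] <- rmultinom(1, sample(0:max_count, 1), c(.85, .05, .05, .05))
    } else if (style == 2) {
      m[, s] <- rmultinom(1, sample(0:max_count, 1), c(.93, .05, .01, .01))
    } else {
      m[, s] <- sample(0:8, 4, replace = TRUE)
    }
  }
  m
}

# ---- paired binomial exact oracle ----------------------------------------
# Conditional on per-pair totals, the test-member count is hypergeometric
# under H0 (beta = 1, no overdispersion); the exact p is the null
# probability of an LRT at least as large as observed, by exhaustive
# enumeration of the joint conditional support.
oracle_exact_paired_p <- function(vt, nt, vc, nc, lrt_fun) {
  s <- vt + vc
  supp <- lapply(seq_along(s), function(i) max(0, s[i] - nc[i]):min(nt[i], s[i]))
  grid <- expand.grid(supp)
  pr <- rep(1, nrow(grid))
  for (i in seq_along(s)) pr <- pr * dhyper(grid[[i]], nt[i], nc[i], s[i])
  obs <- lrt_fun(vt, nt, vc, nc)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    x <- as.numeric(grid[r, ])
    if (lrt_fun(x, nt, s - x, nc) >= obs - 1e-9) tot <- tot + pr[r]
  }
  tot
}

# ---- palindrome search: brute force over all (k, a, b) --------------------
oracle_palindrome <- function(window, center, k_min = 2, k_max = 7,
                              max_offset = 2) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  ch <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  best <- 0
  for (k in k_min:k_max) for (a in 0:max_offset) for (b in 0:max_offset) {
    ue <- center - 4 - a; us <- ue - k + 1
    ds <- center + 1 + b; de <- ds + k - 1
    if (us < 1 || de > length(ch)) next
    up <- ch[us:ue]; dn <- ch[ds:de]
    if (identical(unname(rev(comp[up])), dn) && k > best) best <- k
  }
  best
}

# ---- Nussinov: exhaustive structure enumeration (tiny sequences) ----------
# maximum number of pairs over all pseudoknot-free structures with
# min_loop unpaired bases inside every hairpin
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  can <- function(x, y) paste0(x, y) %in% c("AU","UA","CG","GC","GU","UG")
  rec <- function(idx) {
    if (length(idx) == 0) return(0)
    i <- idx[1]
    best <- rec(idx[-1])                 # i unpaired
    for (jj in seq_along(idx)[-1]) {
      j <- idx[jj]
      if (j - i > min_loop && can(ch[i], ch[j])) {
        inside <- idx[idx > i & idx < j]
        outside <- idx[idx > j]
        best <- max(best, 1 + rec(inside) + rec(outside))
      }
    }
    best
  }
  rec(seq_along(ch))
}

# ---- pileup line oracle: character-by-character counter -------------------
oracle_pileup_counts <- function(bases, quals, ref, min_q = 20) {
  out <- c(A_fwd=0,C_fwd=0,G_fwd=0,T_fwd=0,A_rev=0,C_rev=0,G_rev=0,T_rev=0)
  bs <- strsplit(bases, "")[[1]]
  qs <- strsplit(quals, "")[[1]]
  qi <- 0; i <- 1
  while (i <= length(bs)) {
    c0 <- bs[i]
    if (c0 == "^") { i <- i + 2; next }
    if (c0 == "$") { i <- i + 1; next }
    if (c0 %in% c("+", "-")) {
      j <- i + 1
      num <- ""
      while (grepl("[0-9]", bs[j])) { num <- paste0(num, bs[j]); j <- j + 1 }
      i <- j + as.integer(num); next
    }
    qi <- qi + 1
    q <- utf8ToInt(qs[qi]) - 33
    i <- i + 1
    if (c0 %in% c("*", "#", ">", "<")) next
    if (q < min_q) next
    key <- switch(c0,
      "." = paste0(ref, "_fwd"), "," = paste0(ref, "_rev"),
      "A" = "A_fwd", "C" = "C_fwd", "G" = "G_fwd", "T" = "T_fwd",
      "a" = "A_rev", "c" = "C_rev", "g" = "G_rev", "t" = "T_rev",
      NULL)
    if (!is.null(key)) out[key] <- out[key] + 1
  }
  out
}

# random valid pileup line for one site; returns the line and its counts
random_pileup_line <- function(chrom = "chr1", pos = 1, ref = "G") {
  n <- sample(0:40, 1)
  syms <- sample(c(".", ",", "A", "a", "C", "c", "T", "t", "*", ">", "<"),
                 n, replace = TRUE,
                 prob = c(.3, .3, .07, .07, .05, .05, .04, .04, .03, .025, .025))
  quals <- intToUtf8(33 + sample(c(5, 15, 25, 35), n, replace = TRUE),
                     multiple = TRUE)
  # sprinkle read-start/end marks and indel strings between slots
  parts <- character(0)
  for (i in seq_along(syms)) {
    if (runif(1) < 0.1) parts <- c(parts, paste0("^", intToUtf8(60)))
    parts <- c(parts, syms[i])
    if (runif(1) < 0.08 && syms[i] %in% c(".", ",", "A", "a")) {
      len <- sample(1:3, 1)
      parts <- c(parts, paste0("+", len,
                               paste(sample(c("A","C","G","T"), len, TRUE),
                                     collapse = "")))
    }
    if (runif(1) < 0.1) parts <- c(parts, "$")
  }
  bases <- paste(parts, collapse = "")
  if (n == 0) { bases <- "*"; quals <- "!"; n2 <- 1 } else n2 <- n
  line <- paste(chrom, pos, ref, n2, bases,
                paste(quals, collapse = ""), sep = "\t")
  line
}

# small merged pileup built directly from count matrices (no files)
make_pileup <- function(counts_list, ref = "G", chrom = "chr1",
                        pos = NULL) {
  n_sites <- nrow(counts_list[[1]])
  if (is.null(pos)) pos <- seq_len(n_sites) * 10L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep(ref, length.out = n_sites),
                      stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(n_sites, 8L, length(counts_list)))
  for (s in seq_along(counts_list)) counts[, , s] <- counts_list[[s]]
  structure(list(sites = sites, counts = counts,
                 pairing = pair_design(length(counts_list) / 2)),
            class = "cu_pileup")
}
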