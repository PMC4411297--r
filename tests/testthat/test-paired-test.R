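test_that("exact null symmetry and degenerate inputs behave as specified", {
  d <- data.frame(v_test = c(5, 5, 5), n_test = 100,
                  v_control = c(5, 5, 5), n_control = 100)
  f <- fit_paired_bb(d)
  expect_lt(abs(f$beta - 1), 0.05)
  expect_gt(f$p, 0.5)

  expect_error(fit_paired_bb(d[1, ]), "2 pairs")

  z <- fit_paired_bb(data.frame(v_test = c(0, 0), n_test = 50,
                                v_control = c(0, 0), n_control = 50))
  expect_true(z$degenerate)
  expect_equal(z$beta, 1)
  expect_equal(z$p, 1)
})

test_that("fold changes cap at the configured magnitude", {
  d <- data.frame(v_test = c(30, 28, 31), n_test = 100,
                  v_control = c(0, 0, 0), n_control = 100)
  f <- fit_paired_bb(d)
  expect_equal(f$beta, 1e4)
  expect_equal(f$fold, 1e4)
  expect_lt(f$p, 0.01)

  down <- fit_paired_bb(data.frame(v_test = c(0, 0, 0), n_test = 100,
                                   v_control = c(30, 28, 31),
                                   n_control = 100))
  expect_equal(down$beta, 1e-4)
  expect_equal(down$fold, -1e4)
})

test_that("with no overdispersion the p-value tracks the exact paired
          conditional oracle on small tables", {
  lrt_fun <- function(vt, nt, vc, nc) {
    f <- fit_paired_bb(data.frame(v_test = vt, n_test = nt,
                                  v_control = vc, n_control = nc), rho = 0)
    max(0, 2 * (f$loglik_alt - f$loglik_null))
  }
  tables <- list(
    list(vt = c(8, 7), nt = c(30, 28), vc = c(4, 5), nc = c(30, 29)),
    list(vt = c(10, 9, 12), nt = c(30, 30, 30), vc = c(5, 6, 4),
         nc = c(30, 30, 30)),
    list(vt = c(1, 2, 1), nt = c(10, 12, 11), vc = c(2, 1, 2),
         nc = c(10, 12, 11)),
    list(vt = c(9, 6, 8), nt = c(28, 30, 29), vc = c(5, 7, 4),
         nc = c(30, 28, 30)))
  for (tb in tables) {
    ours <- fit_paired_bb(data.frame(v_test = tb$vt, n_test = tb$nt,
                                     v_control = tb$vc, n_control = tb$nc),
                          rho = 0)$p
    ex <- oracle_exact_paired_p(tb$vt, tb$nt, tb$vc, tb$nc, lrt_fun)
    expect_lt(abs(ours - ex), 0.05)
  }
})

test_that("pooled dispersion recovers the planted overdispersion", {
  set.seed(404)
  rbb <- function(n, size, pi, rho) {
    s <- (1 - rho) / rho
    rbinom(n, size, rbeta(n, pi * s, (1 - pi) * s))
  }
  n_sites <- 500; rho <- 0.01
  VT <- VC <- matrix(0, n_sites, 3)
  or <- (0.2 / 0.8) / (0.01 / 0.99)
  for (i in seq_len(n_sites)) {
    VC[i, ] <- rbb(3, 100, 0.01, rho)
    VT[i, ] <- rbb(3, 100, plogis(qlogis(0.01) + log(or)), rho)
  }
  NT <- NC <- matrix(100, n_sites, 3)
  est <- as.numeric(estimate_dispersion(VT, NT, VC, NC))
  expect_gt(est, rho * 0.5)
  expect_lt(est, rho * 1.5)
})

test_that("q-values implement the Storey bootstrap procedure", {
  q1 <- qvalues(rep(1, 20))
  expect_equal(q1$pi0, 1)
  expect_true(all(q1$qvalues == 1))

  # under uniform (all-null) p-values pi0-hat is centered near 1; its
  # bootstrap lambda selection is noisy at m = 1000, so the check is on the
  # estimator's central behavior over replicates
  set.seed(505)
  pi0s <- replicate(30, qvalues(runif(1000))$pi0)
  expect_gte(mean(pi0s), 0.85)
  expect_lte(max(pi0s), 1.0)
  expect_gte(min(pi0s), 0.5)

  # closed-form check for the smallest p-value under the robust formula
  p <- c(0.001, runif(999))
  qq <- qvalues(p)
  m <- 1000
  expected <- qq$pi0 * m * 0.001 / (rank(p, ties.method = "max")[1] *
                                      (1 - (1 - 0.001)^m))
  expect_lte(qq$qvalues[1], expected + 1e-12)
  # only monotonicity enforcement can pull it below the direct formula
  expect_gte(qq$qvalues[1], qq$pi0 * 0.001)

  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("q-values are monotone, bounded, and never below pi0 * p", {
  set.seed(506)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- qvalues(p)
    o <- order(p)
    expect_true(all(diff(q$qvalues[o]) >= -1e-12))
    expect_true(all(q$qvalues <= 1))
    expect_true(all(q$qvalues >= q$pi0 * p - 1e-12))
  }
})

test_that("differential calls require q, fold and group-mean thresholds", {
  base <- data.frame(chrom = "c", pos = 1:4,
                     beta = c(2.5, 1.5, 10, 2.5),
                     q = c(0.04, 0.04, 0.2, 0.04),
                     mean_test = c(0.06, 0.06, 0.06, 0.06),
                     mean_control = 0.001)
  out <- call_differential(base)
  expect_equal(out$called, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction[1], "up")

  # low higher-group mean blocks the call
  base$mean_test[1] <- 0.03
  expect_false(call_differential(base)$called[1])

  # secondary concordance: must replicate direction, fold and p < 0.05
  sec <- data.frame(chrom = "c", pos = c(1, 4), beta = c(3, 0.3),
                    p = c(0.01, 0.01))
  base$mean_test[1] <- 0.06
  out2 <- call_differential(base, secondary = sec)
  expect_true(out2$called[1])
  expect_false(out2$called[4])   # opposite direction in the secondary set
})
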