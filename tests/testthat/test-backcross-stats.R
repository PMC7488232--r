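# Goodness-of-fit conventions, linkage/exclusion, modifier inference,
# Welch comparison.

test_that("rounded-expectation chi-square reproduces the printed conventions", {
  r <- chi_square_gof(c(46, 0), c(0.5, 0.5))
  expect_equal(r$expected, c(23, 23))
  expect_equal(r$chi2, 46)
  expect_equal(r$df, 1L)
  r2 <- chi_square_gof(c(17, 29), c(0.25, 0.75))
  expect_equal(r2$expected, c(12, 34))
  expect_equal(round(r2$chi2, 2), 2.82)
  r3 <- chi_square_gof(c(17, 29), c(0.125, 0.875))
  expect_equal(r3$expected, c(6, 40))
  expect_equal(round(r3$chi2, 2), 23.19)
  r4 <- chi_square_gof(c(10, 10), c(0.5, 0.5))
  expect_equal(r4$chi2, 0)
  expect_equal(r4$p, 1)
  # expectations always sum to N under rounding
  set.seed(601)
  for (rep in 1:25) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    f <- runif(1, 0.1, 0.9)
    r <- chi_square_gof(c(n1, n2), c(f, 1 - f))
    expect_equal(sum(r$expected), n1 + n2)
  }
  expect_error(chi_square_gof(c(1, 0), c(0, 1)), "zero")
  expect_error(chi_square_gof(c(0, 0), c(0.5, 0.5)), "N = 0")
  # when rounding would zero a class with positive raw expectation,
  # the unrounded expectations are used instead
  r5 <- chi_square_gof(c(1, 0), c(0.1, 0.9))
  expect_equal(r5$expected, c(0.1, 0.9))
})

test_that("a fully one-sided 1:1 outcome gives chi2 = N exactly", {
  # exact for the unrounded statistic always, and for the rounded one
  # whenever N splits into whole animals
  for (n in c(1, 7, 46, 200)) {
    r <- chi_square_gof(c(n, 0), c(0.5, 0.5))
    expect_equal(r$chi2_raw, n)
    if (n %% 2 == 0) expect_equal(r$chi2, n)
  }
})

test_that("chi2 is monotone in the distance from expectation", {
  n <- 46
  ch <- vapply(0:23, function(r)
    chi_square_gof(c(r, n - r), c(0.25, 0.75))$chi2, numeric(1))
  dist <- abs((0:23) - 12)
  expect_true(all(diff(ch[order(dist)]) >= -1e-12))
})

test_that("upper-tail p agrees with independent distribution oracles to 1e-10", {
  # df = 1: chi-square is a squared standard normal, so the upper tail is
  # 2 * P(Z > sqrt(chi2)) — an independent route through pnorm
  for (chi2 in c(0.5, 1.29, 2.82, 3.13, 9.25, 23.19, 46)) {
    r <- chi_square_gof(c(100, 100), c(0.5, 0.5))
    expect_equal(pchisq(chi2, 1, lower.tail = FALSE),
                 2 * pnorm(sqrt(chi2), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # general df: numeric integration of the density
  set.seed(602)
  for (rep in 1:10) {
    chi2 <- runif(1, 0.5, 30); df <- sample(2:5, 1)
    num <- integrate(function(x) dchisq(x, df), chi2, Inf,
                     rel.tol = 1e-12)$value
    expect_lt(abs(pchisq(chi2, df, lower.tail = FALSE) - num), 1e-10)
  }
  r <- segregation_test(46, 125)
  expect_equal(r$p, 2 * pnorm(sqrt(r$chi2), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("segregation distortion matches the whole-animal convention", {
  r <- segregation_test(46, 125)
  expect_equal(r$expected, c(63, 62))
  expect_equal(round(r$chi2, 2), 9.25)
  expect_lt(r$p, 0.05)
  r2 <- segregation_test(165, 310)
  expect_equal(round(r2$chi2, 2), 1.29)
  expect_gt(r2$p, 0.05)
  expect_equal(segregation_test(50, 100)$chi2, 0)
  expect_error(segregation_test(1, 0), "n_total")
})

test_that("exclusion verdicts follow the homozygote threshold", {
  r <- exclusion_test(rep("BW/PO", 46), "mSox10")
  expect_equal(r$verdict, "linked")
  expect_equal(r$gof$chi2, 46)
  r2 <- exclusion_test(c(rep("BW/PO", 20), rep("PO/PO", 6)))
  expect_equal(r2$verdict, "excluded")
  # a single homozygote is below the default threshold but excludes at 1
  r3 <- exclusion_test(c(rep("BW/PO", 30), "PO/PO"))
  expect_equal(r3$verdict, "linked")
  r4 <- exclusion_test(c(rep("BW/PO", 30), "PO/PO"), exclusion_threshold = 1L)
  expect_equal(r4$verdict, "excluded")
  # no-calls are dropped and counted
  r5 <- exclusion_test(c(rep("BW/PO", 10), "no_call"))
  expect_equal(r5$n_affected, 10L)
  expect_equal(r5$n_no_call, 1L)
  expect_error(exclusion_test(rep("no_call", 3)), "no usable")
  expect_error(exclusion_test(c("BW/BW")), "unexpected")
  # full cosegregation is never excluded, any n
  for (n in c(1, 5, 46)) {
    expect_equal(exclusion_test(rep("BW/PO", n))$verdict, "linked")
    expect_equal(exclusion_test(rep("BW/PO", n),
                                exclusion_threshold = 1L)$verdict, "linked")
  }
})

test_that("a marker 1 cM from the causal locus is nearly always called linked", {
  # with ~46 affected animals and Haldane r(1 cM) = 0.0099, the chance of
  # seeing >= 2 recombinant homozygotes (the exclusion threshold) is
  # P[Bin(46, r) >= 2] ~ 7%, so the marker stays linked in ~93% of crosses
  r1 <- 0.5 * (1 - exp(-2 * 1 / 100))
  p_linked <- pbinom(1, 46, r1)
  ok <- 0L; reps <- 200L
  for (r in seq_len(reps)) {
    cfg <- cross_sim_config(marker_positions_cM = c(0, 1),
                            causal_marker_index = 1L, rescue_prob = 0,
                            n_n2 = 92L, seed = 700L + r)
    ped <- simulate_backcross(cfg)
    n2 <- ped$animals[ped$animals$generation == "N2", ]
    aff <- which(n2$spotted)
    if (length(aff) < 2) next
    calls <- ped$marker_genotypes[aff, 2L]
    if (exclusion_test(calls)$verdict == "linked") ok <- ok + 1L
  }
  expect_lt(abs(ok / reps - p_linked),
            3.5 * sqrt(p_linked * (1 - p_linked) / reps) + 0.02)
  expect_gte(ok / reps, 0.85)
})

test_that("linked interval brackets the all-heterozygous block", {
  mk <- c("A", "B", "C", "D", "E")
  gt <- matrix("BW/PO", nrow = 4, ncol = 5, dimnames = list(NULL, mk))
  gt[1, 1] <- "PO/PO"; gt[3, 5] <- "PO/PO"
  iv <- linked_interval(mk, gt)
  expect_equal(iv$left, "A"); expect_equal(iv$right, "E")
  expect_equal(iv$block, c("B", "C", "D"))
  expect_false(iv$open_left || iv$open_right)
  gt2 <- matrix("BW/PO", nrow = 4, ncol = 5, dimnames = list(NULL, mk))
  iv2 <- linked_interval(mk, gt2)
  expect_true(iv2$open_left && iv2$open_right)
  expect_equal(iv2$block, mk)
  gt3 <- gt; gt3[2, 2:4] <- "PO/PO"; gt3[1, 1] <- "PO/PO"; gt3[4, 5] <- "PO/PO"
  expect_error(linked_interval(mk, gt3), "no linked block")
})

test_that("simulated interval contains the causal marker in >= 95% of crosses", {
  hits <- 0L; reps <- 100L
  for (r in seq_len(reps)) {
    cfg <- cross_sim_config(marker_positions_cM = seq(0, 90, by = 10),
                            causal_marker_index = 5L, rescue_prob = 0,
                            n_n2 = 125L, seed = 800L + r)
    ped <- simulate_backcross(cfg)
    n2idx <- which(ped$animals$generation == "N2")
    aff <- which(ped$animals$spotted[n2idx])
    gt <- ped$marker_genotypes[aff, , drop = FALSE]
    iv <- tryCatch(linked_interval(colnames(gt), gt), error = function(e) NULL)
    if (!is.null(iv) && "m05" %in% iv$block) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("expected resemblance fractions are 2^-k", {
  expect_equal(expected_resemblance_fraction(1), 0.5)
  expect_equal(expected_resemblance_fraction(2), 0.25)
  expect_equal(expected_resemblance_fraction(3), 0.125)
  expect_error(expected_resemblance_fraction(0), "integer")
  expect_error(expected_resemblance_fraction(2.5), "integer")
})

test_that("modifier inference reproduces the reject/retain pattern", {
  mi <- modifier_inference(17, 46, k_range = 1:3)
  expect_equal(round(mi$per_k[["1"]]$chi2, 2), 3.13)
  expect_equal(round(mi$per_k[["2"]]$chi2, 2), 2.82)
  expect_equal(round(mi$per_k[["3"]]$chi2, 2), 23.19)
  expect_equal(mi$retained_k, c(1L, 2L))
  mi2 <- modifier_inference(23, 46, k_range = 1L)
  expect_equal(mi2$per_k[["1"]]$chi2, 0)
  expect_equal(mi2$retained_k, 1L)
  expect_error(modifier_inference(50, 46), "n_resemble")
})

test_that("the true modifier count is retained at near-nominal rates", {
  set.seed(603)
  for (k_true in 1:3) {
    for (n in c(50, 200)) {
      reps <- 300L
      retained <- logical(reps)
      for (r in seq_len(reps)) {
        x <- rbinom(1, n, expected_resemblance_fraction(k_true))
        mi <- modifier_inference(x, n, k_range = 1:3)
        retained[r] <- k_true %in% mi$retained_k
      }
      expect_gte(mean(retained), 0.90)
    }
  }
})

test_that("Welch from summaries matches the printed comparison and t.test", {
  w <- welch_from_summary(77.6, 36.6, 25, 14.5, 13, 46)
  expect_equal(round(w$t, 2), 8.34)
  expect_equal(w$df_report, 27L)
  expect_lt(w$p, 1e-7)
  expect_equal(welch_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_gt(welch_from_summary(10, 2, 8, 5, 2, 8)$t, 0)  # sign of m1 - m2
  expect_error(welch_from_summary(1, 0, 5, 2, 1, 5), "sds")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "sizes")
  # oracle: reconstruct groups with these exact summaries, run t.test
  make_group <- function(m, s, n) {
    z <- scale(rnorm(n))[, 1]
    m + s * z
  }
  set.seed(604)
  g1 <- make_group(77.6, 36.6, 25); g2 <- make_group(14.5, 13, 46)
  tt <- t.test(g1, g2)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(w$df_raw, unname(tt$parameter), tolerance = 1e-8)
  expect_equal(w$p, tt$p.value, tolerance = 1e-8)
})
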