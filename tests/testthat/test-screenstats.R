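test_that("normalised activity is the ratio of mean rates, as a percentage", {
  expect_equal(normalised_activity(c(2, 2, 2), c(1, 1, 1)), 50)
  expect_equal(normalised_activity(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(normalised_activity(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_warning(out <- normalised_activity(c(0, 0), c(1, 1)), "undefined")
  expect_true(is.na(out))
})

test_that("signed-rank p matches exact enumeration and handles degeneracy", {
  expect_equal(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), 1)
  # 12 pairs, all decreased: exact value for the one-sided-most configuration
  b <- seq(1, 12)
  expect_equal(paired_wilcoxon(b, b - 0.5), 2 / 2^12)
  # full 2^n enumeration oracle on random instances, including ties
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    bb <- round(runif(n, 0, 3), 1)
    aa <- round(bb + rnorm(n, -0.5, 0.7), 1)
    expect_equal(paired_wilcoxon(bb, aa), oracle_signed_rank_p(bb, aa),
                 tolerance = 1e-12)
  }
  # agreement with the classical exact test when ranks are tie-free
  set.seed(8)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    bb <- runif(n)
    aa <- bb + rnorm(n)
    expect_equal(paired_wilcoxon(bb, aa),
                 wilcox.test(aa, bb, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("null p values are uniform", {
  set.seed(3)
  ps <- replicate(500, paired_wilcoxon(runif(16), runif(16)))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(fdr_adjust(0.004), 0.004)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_length(fdr_adjust(numeric(0)), 0)
})

test_that("robust z' and Cohen's d match their worked examples", {
  expect_equal(robust_z(1:5, 1:5), 0)
  expect_equal(robust_z(1:5, 1:5 - 2), -2) # MAD 1 in both lists
  # pure location shift by c with MAD m: z = -c/m
  x <- c(2, 4, 6, 8, 10) # raw MAD 2
  expect_equal(robust_z(x, x - 3), -1.5)

  expect_equal(cohen_d(1:4, 1:4), 0)
  expect_equal(cohen_d(c(0, 2), c(4, 6)), 4 / sqrt(2))
  # scale invariance
  b <- runif(10); a <- runif(10)
  expect_equal(cohen_d(3.7 * b, 3.7 * a), cohen_d(b, a))
})

test_that("robust z', Cohen's d and BH agree with naive oracles at 1e-12", {
  set.seed(123)
  for (i in 1:1000) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    b <- rlnorm(n1); a <- rlnorm(n2)
    expect_equal(robust_z(b, a), oracle_robust_z(b, a), tolerance = 1e-12)
    expect_equal(cohen_d(b, a), oracle_cohen_d(b, a), tolerance = 1e-12)
    p <- runif(sample(1:8, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("swapping before/after negates both effect sizes", {
  set.seed(9)
  for (i in 1:50) {
    b <- rlnorm(8); a <- rlnorm(8)
    expect_equal(robust_z(a, b), -robust_z(b, a))
    expect_equal(cohen_d(a, b), -cohen_d(b, a))
  }
})

mk_metrics <- function(na = 5, p_fdr = 0.001, z = -4, d = -2, n_active = 10,
                       sep = 4) {
  structure(list(compound_id = "X", rates_before = numeric(0),
                 rates_after = numeric(0), normalised_activity = na,
                 p_raw = p_fdr, p_fdr = p_fdr, robust_z = z, cohen_d = d,
                 n_active = n_active, median_separation_mads = sep),
            class = "screen_metrics")
}

test_that("composite hit call applies every threshold and tiers reductions", {
  hc <- call_hit(mk_metrics(na = 5))
  expect_true(hc$is_hit)
  expect_equal(hc$tier, "high") # reduction 95% > 90%
  expect_equal(call_hit(mk_metrics(na = 25))$tier, "moderate")
  expect_equal(call_hit(mk_metrics(na = 45))$tier, "low")

  miss <- call_hit(mk_metrics(n_active = 8))
  expect_false(miss$is_hit)
  expect_equal(miss$failed_criteria, "min_active")
  expect_equal(miss$tier, "none")

  expect_false(call_hit(mk_metrics(na = 55))$is_hit)
  expect_false(call_hit(mk_metrics(p_fdr = 0.02))$is_hit)
  expect_false(call_hit(mk_metrics(z = -1.5))$is_hit)
  expect_false(call_hit(mk_metrics(d = -0.5))$is_hit)

  # the optional median-separation criterion only bites in fig3 mode
  m <- mk_metrics(sep = 1)
  expect_true(call_hit(m)$is_hit)
  f3 <- call_hit(m, fig3_mode = TRUE)
  expect_false(f3$is_hit)
  expect_equal(f3$failed_criteria, "min_median_sep_mads")
})

test_that("tier intervals partition the reduction range above 50%", {
  for (na in seq(0.5, 49.9, by = 0.7)) {
    hc <- call_hit(mk_metrics(na = na))
    expect_true(hc$is_hit)
    r <- 100 - na
    want <- if (r > 90) "high" else if (r > 70) "moderate" else "low"
    expect_equal(hc$tier, want)
  }
  # tier boundaries: reduction exactly 90 / 70 fall in the lower tier
  expect_equal(call_hit(mk_metrics(na = 10))$tier, "moderate")
  expect_equal(call_hit(mk_metrics(na = 30))$tier, "low")
})

test_that("only baseline-active channels enter the paired statistics", {
  before <- c(2, 3, 0.1, 0.33, 4) # two at/below the 0.33 Hz rule
  after <- c(1, 1.5, 0.1, 0.2, 2)
  m <- screen_metrics("X", before, after)
  expect_equal(m$n_active, 3)
  expect_equal(m$normalised_activity, 100 * mean(c(1, 1.5, 2)) / 3)
  expect_length(m$rates_before, 3)
})

test_that("planted hits are recovered in at least 95% of 100 seeds", {
  truths <- planted_library()
  expo <- planted_exposures(truths)
  planted <- grep("^HIT", names(truths), value = TRUE)
  hits_ok <- logical(100)
  for (s in 1:100) {
    rates <- simulate_screen_rates(expo, truths, seed = 1000 + s)
    calls <- screen_from_rates(rates)
    called <- names(calls)[vapply(calls, `[[`, logical(1), "is_hit")]
    hits_ok[s] <- setequal(called, planted)
  }
  expect_gte(mean(hits_ok), 0.95)
})
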