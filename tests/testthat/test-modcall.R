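# Kinetic modification calling, scoring, fraction estimation.

test_that("IPD ratio is the ratio of native to control means", {
  expect_equal(compute_ipd_ratio(c(2, 2), c(1, 1)), 2)
  expect_equal(compute_ipd_ratio(c(1, 3), 2), 1)
  expect_error(compute_ipd_ratio(numeric(0), c(1)), "undefined site")
  expect_error(compute_ipd_ratio(c(1), 0), "control mean")
  set.seed(1)
  x <- rlnorm(500, 0, 0.4); y <- rlnorm(500, 0, 0.4)
  expect_lt(abs(compute_ipd_ratio(x, y) - 1), 0.15)
})

test_that("score is the Phred-scaled one-sided Welch p-value", {
  set.seed(2)
  x <- rlnorm(30, 0.8, 0.4); y <- rlnorm(30, 0, 0.4)
  p <- t.test(log(x), log(y), alternative = "greater")$p.value
  expect_equal(score_site(x, y), -10 * log10(p), tolerance = 1e-8)
  # identical samples: tie region, score floored at 0
  expect_equal(score_site(c(1, 1, 1), c(1, 1, 1)), 0)
  # zero-variance separated samples: finite, large, never NaN
  s <- score_site(c(3, 3, 3), c(1, 1, 1))
  expect_true(is.finite(s) && s > 100)
})

test_that("null score rate at mQv 22 stays at or below the nominal level", {
  for (seed in c(21, 22, 23)) {
    b <- benchmark_null_calibration(seed = seed, n_sites = 6000L)
    expect_lte(b$rate, b$bound)
  }
})

test_that("coverage and score filters reproduce the published decision rule", {
  g <- toy_genome(c(c1 = strrep("CA", 30)))
  mk <- function(n, mu) exp(rnorm(n, mu, 0.05))
  set.seed(3)
  kin <- toy_kinetics(
    contig = rep("c1", 4L),
    pos = c(0L, 2L, 4L, 7L),           # bases C, C, C, A (+ strand)
    strand = rep("+", 4L),
    native = list(mk(8, 1.2), mk(25, 1.2), mk(25, 0), mk(30, 1.2)),
    control = list(mk(8, 0), mk(25, 0), mk(25, 0), mk(30, 0)))
  calls <- call_modifications(kin, g, call_filter())
  # coverage 8 < 10: removed entirely
  expect_false(0L %in% calls$pos)
  # coverage 25, strong signal, base C: primary 4mC call
  c2 <- calls[calls$pos == 2L, ]
  expect_equal(c2$mark, "4mC")
  expect_true(c2$primary)
  expect_gte(c2$score, 22)
  # unmodified site: never primary
  expect_false(any(calls$primary[calls$pos == 4L]))
  # base A on + strand: 6mA
  expect_equal(calls$mark[calls$pos == 7L], "6mA")
  # output sorted and positive-ratio only
  expect_true(all(diff(calls$pos) > 0))
  expect_true(all(calls$ipd_ratio > 1))
})

test_that("positions outside the genome raise a coordinate error", {
  g <- toy_genome(c(c1 = "ACGTACGT"))
  kin <- toy_kinetics("c1", 99L, "+", list(exp(rnorm(20))), list(exp(rnorm(20))))
  expect_error(call_modifications(kin, g), "coordinate error")
})

test_that("re-filtering filtered calls changes nothing", {
  cfg <- small_config(seed = 24)
  g <- simulate_genome(cfg)
  m <- plant_methylome(g, cfg)
  kin <- simulate_kinetics(g, m, cfg)
  f <- call_filter()
  calls <- call_modifications(kin, g, f)
  expect_identical(filter_calls(calls, f), calls)
})

test_that("fraction estimator is exact at the extremes and order-invariant", {
  near_mod <- exp(rnorm(40, log(3), 0.05))
  near_un <- exp(rnorm(40, 0, 0.05))
  expect_equal(estimate_fraction(near_mod), 1)
  expect_equal(estimate_fraction(near_un), 0)
  mixed <- c(near_mod[1:10], near_un[1:30])
  expect_equal(estimate_fraction(mixed), estimate_fraction(rev(mixed)))
  expect_equal(estimate_fraction(sample(mixed)), estimate_fraction(mixed))
  f <- estimate_fraction(mixed)
  expect_true(f >= 0 && f <= 1)
  expect_error(estimate_fraction(numeric(0)), "zero coverage")
})

test_that("fraction classes follow the published bins", {
  expect_equal(classify_fraction(1.0), "high")
  expect_equal(classify_fraction(0.8), "high")
  expect_equal(classify_fraction(0.6), "moderate")
  expect_equal(classify_fraction(0.5), "moderate")
  expect_equal(classify_fraction(0.1), "low")
  expect_equal(classify_fraction(0.05), "sub_threshold")
  expect_error(classify_fraction(1.2), "must lie")
  expect_error(classify_fraction(-0.1), "must lie")
})

test_that("fraction summaries are exact arithmetic over the call list", {
  calls <- data.frame(mark = "4mC", fraction = c(1, 1, 0.5, 0.5),
                      stringsAsFactors = FALSE)
  s <- fraction_summary(calls)
  expect_equal(s$mean_fraction, 0.75)
  expect_equal(s$pct_fully_methylated, 50)
  expect_equal(s$n_high, 2L)
  expect_equal(s$n_moderate, 2L)
  # all high: high:low ratio reported as Inf sentinel
  s2 <- fraction_summary(data.frame(mark = "6mA", fraction = c(1, 1)))
  expect_equal(s2$high_low_ratio, Inf)
  s3 <- fraction_summary(data.frame(mark = "6mA", fraction = 0.74))
  expect_equal(s3$mean_fraction, 0.74)
  expect_equal(nrow(fraction_summary(data.frame(mark = character(),
                                                fraction = numeric()))), 0L)
})

test_that("recall grows with coverage and kinetic effect size", {
  recall_at <- function(passes, mult, seed) {
    cfg <- sim_config(seed = seed,
                      genome = list(length = 4000L, n_contigs = 1L),
                      genes = list(n = 0L), te_families = no_feature_families(),
                      tandem_repeats = list(n = 0L),
                      kinetics = list(passes = passes, multiplier = mult))
    g <- simulate_genome(cfg)
    ch <- strsplit(g$contigs[[1]], "")[[1]]
    pos <- which(ch %in% c("C", "A"))[1:700] - 1L
    m <- data.frame(contig = "contig_01", pos = pos,
                    strand = ifelse(ch[pos + 1L] == "C", "+", "+"),
                    mark = ifelse(ch[pos + 1L] == "C", "4mC", "6mA"),
                    fraction = 1, stringsAsFactors = FALSE)
    k <- simulate_kinetics(g, m, cfg, positions = m)
    calls <- call_modifications(k, g)
    sum(calls$primary) / nrow(m)
  }
  grid_cov <- c(20L, 30L, 45L)
  grid_mult <- c(2, 3, 4)
  rec <- outer(grid_cov, grid_mult,
               Vectorize(function(p, m) recall_at(p, m, seed = 31)))
  eps <- 0.04   # allows Monte-Carlo jitter at 700 sites per cell
  for (i in 1:3) {
    expect_true(all(diff(rec[, i]) > -eps))   # coverage direction
    expect_true(all(diff(rec[i, ]) > -eps))   # multiplier direction
  }
  expect_gt(rec[3, 3], 0.95)
})
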