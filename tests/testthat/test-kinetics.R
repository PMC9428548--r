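test_that("depolymerization rate: exact lines, truncation, errors", {
  tr <- length_trace(c(0, 60, 120, 180), c(10, 9, 8, 7), addition_time = 0)
  expect_equal(depolymerization_rate(tr)$rate, 1.0, tolerance = 1e-12)
  tr2 <- length_trace(c(0, 60, 120), c(5, 5, 5), addition_time = 0)
  expect_equal(depolymerization_rate(tr2)$rate, 0.0, tolerance = 1e-12)
  ## growing microtubule -> signed negative rate
  tr3 <- length_trace(c(0, 60, 120), c(5, 6, 7), addition_time = 0)
  expect_equal(depolymerization_rate(tr3)$rate, -1.0, tolerance = 1e-12)
  expect_error(depolymerization_rate(
    length_trace(c(0, 10), c(5, 4), addition_time = 0)), "too few")
  ## truncation at the resolution floor ignores post-shrinkage noise
  t4 <- c(0, 60, 120, 180, 240, 300)
  l4 <- c(10, 7, 4, 1, 0.2, 0.3)
  r4 <- depolymerization_rate(length_trace(t4, l4, addition_time = 0))
  expect_equal(r4$n_points, 4)    # fit stops before the first sub-floor point
  ## Theil-Sen option exists and matches OLS on a clean line
  expect_equal(depolymerization_rate(tr, method = "theil_sen")$rate, 1.0)
})

test_that("depolymerization recovery at the measured Anc13 rate", {
  cfg <- sim_config(seed = 88, v_depol = 23.05, n_traces = 1,
                    length_noise = 0.2, interval = 5, init_length = 14)
  tr <- simulate_length_traces(cfg)$traces[[1]]
  fit <- depolymerization_rate(tr)
  expect_lt(abs(fit$rate - 23.05), 3 * fit$se)
})

test_that("aggregate_rates mean/sd/n and Monte-Carlo check of a printed row", {
  a <- aggregate_rates(c(2.0, 2.2, 2.1))
  expect_equal(a$mean, 2.1)
  expect_equal(a$n, 3)
  expect_equal(a$sd, stats::sd(c(2.0, 2.2, 2.1)))
  s <- aggregate_rates(5)
  expect_true(s$single)
  expect_equal(s$sd, 0)
  expect_error(aggregate_rates(numeric(0)), "no rates")
  ## 18 draws at the measured MCAK row reproduce it within sampling error
  set.seed(1)
  draws <- rnorm(18, 2.12, 0.17)
  agg <- aggregate_rates(draws)
  expect_lt(abs(agg$mean - 2.12), 3 * 0.17 / sqrt(18))
})

test_that("koff closed forms with and without censoring", {
  d <- dwell_set(c(1, 1, 1), rep("end", 3), movie_length = 10,
                 frame_interval = 0)
  expect_equal(koff_mle(d, "end")$k_off, 1.0, tolerance = 1e-12)
  ## censored closed form: 2 events / 6 s total exposure
  d2 <- dwell_set(c(1, 2, 3), rep("end", 3), censored = c(FALSE, FALSE, TRUE),
                  movie_length = 3, frame_interval = 0)
  expect_equal(koff_mle(d2, "end")$k_off, 2 / 6, tolerance = 1e-12)
  ## uncensored MLE equals 1/mean exactly
  set.seed(3)
  x <- rexp(40, 2)
  d3 <- dwell_set(x, rep("lattice", 40), movie_length = 1e6,
                  frame_interval = 0)
  expect_equal(koff_mle(d3, "lattice")$k_off, 1 / mean(x), tolerance = 1e-12)
  ## profile CI brackets the estimate
  ci <- koff_mle(d3, "lattice")$ci
  expect_lt(ci[1], 1 / mean(x)); expect_gt(ci[2], 1 / mean(x))
  d4 <- dwell_set(2, "end", censored = TRUE, movie_length = 2,
                  frame_interval = 0)
  expect_error(koff_mle(d4, "end"), "censored")
})

test_that("koff estimators are order-invariant", {
  set.seed(13)
  x <- rexp(60, 1.5)
  perm <- sample(60)
  d1 <- dwell_set(x, rep("end", 60), movie_length = 1e5, frame_interval = 0)
  d2 <- dwell_set(x[perm], rep("end", 60), movie_length = 1e5,
                  frame_interval = 0)
  expect_equal(koff_mle(d1, "end")$k_off, koff_mle(d2, "end")$k_off)
})

test_that("kon arithmetic, zero-event warning and unit consistency", {
  d <- dwell_set(rep(1, 10), rep("end", 10), movie_length = 10,
                 frame_interval = 0.01, mt_length = 5, concentration = 0.04)
  expect_equal(kon_rate(d)$k_on, 5.0)
  d0 <- dwell_set(numeric(0), character(0), movie_length = 10,
                  frame_interval = 0.01, mt_length = 5, concentration = 0.04)
  expect_warning(r0 <- kon_rate(d0), "no binding events")
  expect_equal(r0$k_on, 0)
  ## lengths in nm with rates converted: k_on scales by 1/1000
  dnm <- dwell_set(rep(1, 10), rep("end", 10), movie_length = 10,
                   frame_interval = 0.01, mt_length = 5000,
                   concentration = 0.04)
  expect_equal(kon_rate(dnm)$k_on * 1000, kon_rate(d)$k_on)
})

test_that("fraction of long events handles censoring and matches exp(-kT)", {
  d <- dwell_set(c(1, 3), c("end", "end"), movie_length = 10,
                 frame_interval = 0)
  expect_equal(fraction_long_events(d, 2), 0.5)
  d2 <- dwell_set(c(0.5, 1, 1.5), rep("lattice", 3), movie_length = 10,
                  frame_interval = 0)
  expect_equal(fraction_long_events(d2, 2), 0)
  ## censored event longer than threshold counts as long
  d3 <- dwell_set(c(1, 3), c("end", "end"), censored = c(FALSE, TRUE),
                  movie_length = 3, frame_interval = 0)
  expect_equal(fraction_long_events(d3, 2), 0.5)
  ## closed-form check: P(d > T) = exp(-kT)
  set.seed(5)
  k <- 1.2; n <- 20000
  d4 <- dwell_set(rexp(n, k), rep("end", n), movie_length = 1e9,
                  frame_interval = 0)
  p <- exp(-k * 2)
  expect_lt(abs(fraction_long_events(d4, 2) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("ATPase turnover: arithmetic, flat signal, coupled conversion", {
  a <- atpase_assay(c(0, 60, 120), c(0, 18, 36), motor = 0.1, mode = "hplc_adp")
  expect_equal(atpase_rate(a)$rate, 3.0, tolerance = 1e-12)
  flat <- atpase_assay(c(0, 60, 120, 180), rep(1, 4), motor = 0.1,
                       mode = "hplc_adp")
  expect_equal(atpase_rate(flat)$rate, 0)
  ## coupled mode: absorbance slope -> uM/s through extinction * path
  t <- seq(0, 60, 2)
  k <- 8.07; motor <- 0.1; eps <- 6220
  A <- 1.2 - eps * 1 * k * motor * 1e-6 * t
  ac <- atpase_assay(t, A, motor, mode = "nadh_coupled", extinction = eps)
  expect_equal(atpase_rate(ac)$rate, k, tolerance = 1e-9)
  ## wrong-direction slopes are rejected
  expect_error(atpase_rate(atpase_assay(c(0, 60, 120), c(36, 18, 0),
                                        motor = 0.1, mode = "hplc_adp")),
               "inconsistent")
  expect_error(atpase_assay(c(0, 60), c(0, 1), motor = 0.1), "3 time points")
  expect_error(atpase_assay(c(0, 60, 120), c(0, 1, 2), motor = 0), "> 0")
})

test_that("fold changes reproduce printed comparative values", {
  rt <- kinesin13_rates()
  expect_equal(fold_change(rt, "Anc13", "MCAK", "depolymerization")$ratio,
               23.05 / 2.12, tolerance = 1e-12)   # printed as 11-fold
  expect_equal(fold_change(rt, "Anc13", "Anc13", "depolymerization")$ratio, 1.0)
  ## Table 2 ratio: Anc13 lattice/end = 1.36/1.23 (printed 1.11)
  expect_equal(rt[rt$label == "Anc13" & rt$quantity == "koff_lattice", "value"] /
                 rt[rt$label == "Anc13" & rt$quantity == "koff_end", "value"],
               1.36 / 1.23, tolerance = 1e-12)
  ## reciprocal product is exactly 1
  f1 <- fold_change(rt, "Anc13", "MCAK", "depolymerization")$ratio
  f2 <- fold_change(rt, "MCAK", "Anc13", "depolymerization")$ratio
  expect_equal(f1 * f2, 1, tolerance = 1e-15)
  expect_error(fold_change(rt, "Anc13", "nope", "depolymerization"),
               "exactly one row")
})

test_that("tubulins per ATP: comparator anchoring and identity", {
  rt <- kinesin13_rates()
  s <- tubulins_per_atp(rt, "Anc13", "MCAK")
  ## arithmetic oracle from the printed tables
  expect_equal(s$stoichiometry, 1 * (23.05 / 2.12) * (3.69 / 8.07),
               tolerance = 1e-12)
  expect_equal(round(s$stoichiometry, 2), 4.97)
  ## target == comparator returns the anchor exactly
  same <- tubulins_per_atp(rt, "MCAK", "MCAK")
  expect_equal(same$stoichiometry, 1, tolerance = 1e-15)
  expect_error(tubulins_per_atp(rt, "Anc13", "missing"), "exactly one row")
  ## absolute route with lattice geometry: v * 1625/60 dimers/s per motor pool
  g <- geometry_constants()
  expect_equal(g$dimers_per_um, 1625)
  abs_s <- tubulins_per_atp(rt, "Anc13", "MCAK", geometry = g, end_motors = 10)
  expect_equal(abs_s$stoichiometry, (23.05 / 60 * 1625) / (8.07 * 10),
               tolerance = 1e-12)
})

test_that("break frequency filters by length", {
  rec <- data.frame(length = c(rep(8, 47)), breaks = c(rep(1, 33), rep(0, 14)))
  bf <- break_frequency(rec)
  expect_equal(bf$proportion, 33 / 47, tolerance = 1e-12)  # approx 70%
  expect_equal(bf$n, 47)
  none <- data.frame(length = rep(10, 5), breaks = 0)
  expect_equal(break_frequency(none)$proportion, 0)
  short <- data.frame(length = rep(2, 5), breaks = 1)
  expect_error(break_frequency(short), "longer than")
})

test_that("koff recovery at the measured end off-rate with quantization", {
  ## 8.7 Hz frame quantization and 23 s movie, k from the measured end rate
  cfg <- sim_config(seed = 99, k_off_end = 1.23, k_off_lattice = 1.36,
                    concentration = 0.4)   # high density for a tight test
  d <- simulate_dwells(cfg)
  fit <- koff_mle(d, "end")
  expect_lt(abs(fit$k_off - 1.23), 3 * fit$se)
})
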