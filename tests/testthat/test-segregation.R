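test_that("segregation parameters are validated", {
  expect_s3_class(segregation_params(0.1, 0.2, 0.01), "segregation_params")
  expect_error(segregation_params(0.6, 0.6), "<= 1")
  expect_error(segregation_params(-0.1), "is_prob")
  expect_error(segregation_params(divisions_per_day = 0), "positive integer")
})

test_that("single divisions follow the segregation mechanics", {
  p0 <- segregation_params()
  d <- sample_division(1, 1, p0)
  expect_equal(unname(d), matrix(c(1, 1, 1, 1), 2, byrow = TRUE))

  pns <- segregation_params(p_nondisjunction = 1)
  d <- sample_division(1, 1, pns)
  expect_setequal(d[, "copies"], c(2, 0))
  expect_setequal(d[, "expressing"], c(2, 0))

  expect_error(sample_division(5, 0, p0), "k_max")
})

test_that("division kernel matches brute-force single-copy enumeration", {
  p <- segregation_params(p_nondisjunction = 0.1, p_lag_loss = 0.2)
  kern <- minichrom:::division_kernel_class(1, 1, p)
  # brute force over the five chromatid routings of one expressing copy
  d1 <- c(1, 2, 0, 1, 0); d2 <- c(1, 0, 2, 0, 1)
  pr <- c(0.7, 0.05, 0.05, 0.1, 0.1)
  expected <- aggregate(prob ~ c1 + e1 + c2 + e2,
                        data.frame(c1 = d1, e1 = d1, c2 = d2, e2 = d2, prob = pr),
                        FUN = sum)
  kern_sorted <- kern[order(kern$c1, kern$c2), ]
  expected_sorted <- expected[order(expected$c1, expected$c2), ]
  expect_equal(kern_sorted$prob, expected_sorted$prob)
  expect_equal(sum(kern$prob), 1)

  # empirical frequencies over many seeded draws agree with the enumeration
  kernels <- build_division_kernels(p)
  set.seed(421)
  outcomes <- replicate(20000, {
    d <- sample_division(1, 1, p, kernels)
    paste(d[1, 1], d[1, 2], d[2, 1], d[2, 2])
  })
  emp <- table(outcomes) / length(outcomes)
  key <- paste(kern$c1, kern$e1, kern$c2, kern$e2)
  for (i in seq_along(key)) {
    se <- sqrt(kern$prob[i] * (1 - kern$prob[i]) / 20000)
    expect_lt(abs(emp[[key[i]]] - kern$prob[i]), 4 * se + 1e-9)
  }
})

test_that("chromatid conservation holds in every kernel outcome", {
  for (pll in c(0, 0.2)) {
    p <- segregation_params(p_nondisjunction = 0.15, p_lag_loss = pll, k_max = 4L)
    for (cc in 0:2) for (ee in 0:cc) {
      kern <- minichrom:::division_kernel_class(cc, ee, p)
      if (pll == 0) {
        expect_true(all(kern$c1 + kern$c2 == 2 * cc))
      } else {
        # lag losses remove whole chromatids: deficit between 0 and copies
        expect_true(all(kern$c1 + kern$c2 <= 2 * cc))
        expect_true(all(kern$c1 + kern$c2 >= cc))
      }
      expect_true(all(kern$e1 <= kern$c1 & kern$e2 <= kern$c2))
    }
  }
})

test_that("stochastic propagation doubles the population and respects null params", {
  p0 <- segregation_params()
  st <- population_state(1000, 1, 1)
  st2 <- propagate_generation_stochastic(st, p0)
  expect_equal(sum(st2), 2000)
  expect_equal(st2[2, 2], 2000)  # all still (1,1)

  p <- segregation_params(p_nondisjunction = 0.05, p_lag_loss = 0.1)
  st3 <- propagate_generation_stochastic(st, p)
  expect_equal(sum(st3), 2000)
})

test_that("stochastic propagation converges to the expected operator", {
  p <- segregation_params(p_nondisjunction = 0.04, p_lag_loss = 0.06,
                          p_silence = 0.02)
  k <- p$k_max
  prop <- matrix(0, k + 1, k + 1)
  prop[2, 2] <- 1
  for (g in 1:5) prop <- propagate_generation_expected(prop, p)
  expect_equal(sum(prop), 1)

  set.seed(77)
  n0 <- 2e5
  st <- population_state(n0, 1, 1)
  kernels <- build_division_kernels(p)
  for (g in 1:5) st <- propagate_generation_stochastic(st, p, kernels)
  emp <- st / sum(st)
  # 3 SE binomial bound per class (conservative: branching adds correlation,
  # so compare only well-populated classes at 4 SE)
  for (i in seq_len(k + 1)) for (j in seq_len(k + 1)) {
    if (prop[i, j] > 1e-3) {
      se <- sqrt(prop[i, j] * (1 - prop[i, j]) / sum(st))
      expect_lt(abs(emp[i, j] - prop[i, j]), 4 * se + 2e-3)
    }
  }
})

test_that("pure lag loss gives exact geometric retention decay", {
  pll <- 0.00286
  p <- segregation_params(p_lag_loss = pll)
  prop <- matrix(0, 5, 5); prop[2, 2] <- 1
  for (g in 1:21) prop <- propagate_generation_expected(prop, p)
  retained <- 1 - sum(prop[1, ])
  expect_equal(retained, (1 - pll / 2)^21, tolerance = 1e-12)

  # stochastic trajectory within Monte-Carlo error of the closed form
  # (population capped by passage subsampling, as in the bulk assay)
  tc <- simulate_flow_timecourse(p, days = 7, sample_days = c(0, 7),
                                 initial_cells = 2e5, max_cells = 2e5,
                                 seed = 99)
  frac_neg <- tc$fraction_gfp_negative[tc$day == 7]
  expected <- 1 - (1 - pll / 2)^21
  se <- sqrt(expected * (1 - expected) / 2e5)
  expect_lt(abs(frac_neg - expected), 3 * se + 2e-3)
})

test_that("effective loss rate equals the per-daughter null-inheritance probability", {
  expect_equal(effective_loss_rate(segregation_params(0, 0)), 0)
  expect_equal(effective_loss_rate(segregation_params(0.002, 0.002)), 0.002)
  expect_equal(effective_loss_rate(segregation_params(0, 0.004)), 0.002)

  # verified by counting chromosome-free daughters over many divisions
  p <- segregation_params(p_nondisjunction = 0.002, p_lag_loss = 0.002)
  set.seed(5)
  st <- propagate_generation_stochastic(population_state(5e5, 1, 1), p)
  frac_null <- sum(st[1, ]) / sum(st)
  se <- sqrt(0.002 * 0.998 / 1e6)
  expect_lt(abs(frac_null - 0.002), 3 * se)
})

test_that("retention model evaluates and bounds correctly", {
  expect_equal(expected_retention(0, 50), 1)
  expect_equal(expected_retention(0.00143, 21), 0.9703956, tolerance = 1e-6)
  expect_equal(expected_retention(0.002, 75), 0.998^75)
  # monotone nonincreasing in n and in r
  r_grid <- c(0.001, 0.01, 0.1)
  for (r in r_grid) {
    f <- expected_retention(r, 0:50)
    expect_true(all(diff(f) <= 0))
  }
  expect_true(all(diff(expected_retention(r_grid, 21)) <= 0))
})

test_that("GFP classification maps states to flow gates", {
  st <- population_state(10, 0, 0)
  expect_equal(classify_gfp(st)$fraction_gfp_negative, 1)

  st <- population_state(4, 2, 2)
  st[2, 1] <- 6  # (1, 0): silenced carriers
  fr <- classify_gfp(st)
  expect_equal(fr$fraction_gfp_double_or_more, 0.4)
  expect_equal(fr$fraction_gfp_negative, 0.6)  # silenced counted negative
  expect_equal(fr$fraction_gfp_negative + fr$fraction_gfp_single +
                 fr$fraction_gfp_double_or_more, 1)
})

test_that("silencing changes GFP fractions but not DNA-level retention", {
  base <- segregation_params(p_lag_loss = 0.01)
  sil <- segregation_params(p_lag_loss = 0.01, p_silence = 0.05)
  prop0 <- matrix(0, 5, 5); prop0[2, 2] <- 1
  pa <- pb <- prop0
  for (g in 1:10) {
    pa <- propagate_generation_expected(pa, base)
    pb <- propagate_generation_expected(pb, sil)
  }
  # identical copy-number marginals
  expect_equal(rowSums(pa), rowSums(pb), tolerance = 1e-12)
  # but silencing inflates the GFP-negative fraction
  expect_gt(sum(pb[, 1]), sum(pa[, 1]))
})

test_that("nondisjunction feeds a growing double-GFP fraction", {
  p <- segregation_params(p_nondisjunction = 0.02)
  prop <- matrix(0, 5, 5); prop[2, 2] <- 1
  dbl <- numeric(10)
  for (g in 1:10) {
    prop <- propagate_generation_expected(prop, p)
    dbl[g] <- sum(prop[, 3:5])
  }
  expect_gt(dbl[1], 0)
  expect_true(all(diff(dbl) > -1e-12))

  p0 <- segregation_params(p_lag_loss = 0.1)
  prop <- matrix(0, 5, 5); prop[2, 2] <- 1
  for (g in 1:10) prop <- propagate_generation_expected(prop, p0)
  expect_equal(sum(prop[, 3:5]), 0)
})
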