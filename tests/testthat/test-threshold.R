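test_that("ks_optimal_probability_threshold enumerated cases", {
  # perfect separation; smallest maximiser convention
  r <- ks_optimal_probability_threshold(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(r$ks_distance, 1)
  expect_equal(r$p_star, 0.2)
  # identical singleton classes
  r2 <- ks_optimal_probability_threshold(0.5, 0.5)
  expect_equal(r2$ks_distance, 0)
  expect_equal(r2$p_star, 0.5)
  # hand-enumerated: D maximal at 0.4 with 2/3
  r3 <- ks_optimal_probability_threshold(c(0.1, 0.4, 0.6), c(0.5, 0.7, 0.9))
  expect_equal(r3$p_star, 0.4)
  expect_equal(r3$ks_distance, 2 / 3)
  expect_equal(r3$candidate_count, 6L)
  expect_error(ks_optimal_probability_threshold(numeric(0), 0.5), "non-empty")
})

test_that("ks distance equals the classical two-sample K-S statistic", {
  set.seed(41)
  for (i in 1:50) {
    p0 <- runif(sample(3:20, 1))
    p1 <- runif(sample(3:20, 1))
    mine <- ks_optimal_probability_threshold(p0, p1)$ks_distance
    oracle <- suppressWarnings(ks.test(p0, p1)$statistic)
    expect_equal(mine, unname(oracle), tolerance = 1e-12)
  }
})

test_that("invert_to_prl_threshold closed forms and beta handling", {
  expect_equal(invert_to_prl_threshold(0.5, one_draw(alpha = -3), "female"),
               1000)
  expect_equal(invert_to_prl_threshold(0.5, one_draw(), "male"), 1)
  # logit(0.7311) ~ 1 -> 10^((1+6)/2) = 10^3.5
  expect_equal(invert_to_prl_threshold(plogis(1), one_draw(alpha = -6, beta = 2),
                                       "female"),
               10^3.5, tolerance = 1e-6)
  # gender offsets shift the threshold
  d <- one_draw(alpha = -3, u_f = -0.5, u_m = 0.5, beta = 1)
  expect_gt(invert_to_prl_threshold(0.5, d, "female"),
            invert_to_prl_threshold(0.5, d, "male"))
  # population inversion = count-weighted mean offset
  t_pop <- invert_to_prl_threshold(0.5, d, "population",
                                   gender_weights = c(female = 3, male = 1))
  expect_equal(t_pop, 10^((0 + 3 - (0.75 * -0.5 + 0.25 * 0.5)) / 1))
  # beta <= 0 excluded as NA
  expect_true(is.na(invert_to_prl_threshold(0.5, one_draw(beta = -1), "male")))
})

test_that("summarize_threshold: constants, symmetry, lognormal skew", {
  s <- summarize_threshold(rep(250, 10))
  expect_equal(s$mle, 250)
  expect_equal(s$median, 250)
  expect_equal(s$cri_low, 250)
  expect_equal(s$cri_high, 250)

  set.seed(5)
  sym <- 10^rnorm(4000, 3, 0.2)  # symmetric on log scale
  ss <- summarize_threshold(sym)
  expect_lt(abs(log10(ss$mle) - log10(ss$median)), 0.08)
  expect_true(ss$cri_low <= ss$median && ss$median <= ss$cri_high)

  # right-skewed lognormal (natural scale): mode < median
  ln <- exp(rnorm(4000, 0, 1))
  sl <- summarize_threshold(ln)
  expect_lt(sl$mle, sl$median)
})

test_that("threshold_distribution: degenerate sample, stratum errors", {
  co <- generate_cohort(default_paper_params(seed = 2))
  mi <- model_input(complete_case_filter(co))
  one <- fake_sample(data.frame(alpha = -5.5, u_female = -0.5, u_male = 0.5,
                                sigma_u = 1, beta = 2))
  td <- threshold_distribution(one, mi)
  expect_length(td$thresholds, 1L)
  expect_equal(td$summaries$mle, td$summaries$median)
  # stratum with a single class errors by name
  young_inv <- cohort_table(data.frame(
    sex = rep("female", 30), age = rep(c(20, 60), 15),
    prl = exp(seq(3, 8, length.out = 30)),
    invasion = rep(c(1L, 0L), c(15, 15))))
  # all invasive patients are under 50 here
  young_inv$invasion <- as.integer(young_inv$age < 50)
  mi2 <- model_input(young_inv)
  expect_error(
    threshold_distribution(one, mi2, subgroup_spec("young", age = "under50")),
    "young")
  # beta <= 0 draws excluded and tallied; all-negative errors
  neg <- fake_sample(data.frame(alpha = c(-5, -5), u_female = 0, u_male = 0,
                                sigma_u = 1, beta = c(2, -1)))
  td2 <- threshold_distribution(neg, mi)
  expect_equal(td2$n_excluded, 1L)
  expect_true(td2$unreliable)  # 50% > 5%
})

test_that("raw-score equivalence: single-gender K-S threshold = Youden cutpoint", {
  # under one draw with beta > 0, p is strictly monotone in prl, so the
  # inverted K-S cutoff must match the exhaustive-search raw cutpoint
  set.seed(19)
  for (rep_i in 1:20) {
    prl <- unique(round(10^runif(sample(8:20, 1), 1.5, 3.5), 1))
    n <- length(prl)
    # labels positively associated with prl (noisy upper tail)
    y <- as.integer(rank(prl) + rnorm(n, 0, 2) > stats::median(rank(prl)))
    if (length(unique(y)) < 2) next
    draw <- one_draw(alpha = runif(1, -8, -2), beta = runif(1, 0.5, 3))
    p <- plogis(draw$alpha + draw$beta * log10(prl))
    ks <- ks_optimal_probability_threshold(p[y == 0], p[y == 1])
    t_inv <- invert_to_prl_threshold(ks$p_star, draw, "female")
    # the inverted cutoff is an observed prolactin value (monotone link)
    expect_equal(min(abs(prl - t_inv)) / t_inv, 0, tolerance = 1e-6)
    # exhaustive Youden over all observed candidates (positivity prl >= c):
    # its maximum equals the K-S distance when the score is positively
    # oriented -- the classical identity
    J <- vapply(prl, function(c) {
      mean(prl[y == 1] >= c) + mean(prl[y == 0] < c) - 1
    }, 0)
    expect_equal(ks$ks_distance, max(J), tolerance = 1e-9)
    # and equals the classical two-sample K-S statistic on the raw values
    expect_equal(ks$ks_distance,
                 unname(suppressWarnings(ks.test(prl[y == 0],
                                                 prl[y == 1])$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("pipeline equivariance: scaling PRL by 10 shifts thresholds by 10", {
  co <- generate_cohort(default_paper_params(seed = 4))
  cc <- complete_case_filter(co)
  mi <- model_input(cc)
  s <- fake_sample(data.frame(alpha = rnorm(200, -5.5, 0.3),
                              u_female = rnorm(200, -0.5, 0.2),
                              u_male = rnorm(200, 0.5, 0.2),
                              sigma_u = 1, beta = rnorm(200, 2, 0.15)))
  td <- threshold_distribution(s, mi)
  # same draws re-expressed for scaled data: alpha' = alpha - beta (x+1 shift)
  cc10 <- cc
  cc10$prl <- cc10$prl * 10
  mi10 <- model_input(cc10)
  s10 <- s
  s10$draws$alpha <- s10$draws$alpha - s10$draws$beta
  td10 <- threshold_distribution(s10, mi10)
  expect_equal(td10$thresholds, 10 * td$thresholds, tolerance = 1e-9)
  expect_equal(td10$summaries$median, 10 * td$summaries$median,
               tolerance = 1e-9)
})

test_that("threshold_table covers the 15 strata and flags inestimable cells", {
  co <- generate_cohort(default_paper_params(seed = 3))
  mi <- model_input(complete_case_filter(co))
  s <- fake_sample(data.frame(alpha = rnorm(100, -5.5, 0.3),
                              u_female = rnorm(100, -0.5, 0.2),
                              u_male = rnorm(100, 0.5, 0.2),
                              sigma_u = 1, beta = rnorm(100, 2, 0.15)))
  tt <- threshold_table(s, mi)
  expect_equal(nrow(tt), 15L)
  est <- tt[tt$estimable, ]
  expect_gt(nrow(est), 5L)
  expect_true(all(est$cri_low <= est$median & est$median <= est$cri_high))
  expect_true(all(est$mle > 0))
})
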