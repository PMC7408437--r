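test_that("km_estimate matches closed forms and the hand product-limit oracle", {
  # 10 subjects, events at months 1..5, five survivors past 24
  time <- c(1:5, rep(30, 5)); event <- c(rep(1, 5), rep(0, 5))
  expect_equal(km_estimate(time, event, 24), 0.5)
  # all censored
  expect_equal(km_estimate(rep(10, 6), rep(0, 6), 24), 1)
  # mixed censoring fixture vs the independent product-limit loop
  t8 <- c(2, 3, 3, 5, 8, 8, 12, 15)
  e8 <- c(1, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(km_estimate(t8, e8, 14), naive_km(t8, e8, 14), tolerance = 1e-12)
  expect_equal(km_estimate(t8, e8, 6), naive_km(t8, e8, 6), tolerance = 1e-12)
  # censoring-free KM equals the empirical surviving fraction
  set.seed(2)
  tt <- rexp(50, 0.07)
  expect_equal(km_estimate(tt, rep(1, 50), 12), mean(tt > 12))
  # non-increasing in horizon, bounded in [0, 1]
  s <- vapply(c(0, 6, 12, 24, 48), function(h) km_estimate(t8, e8, h), numeric(1))
  expect_true(all(diff(s) <= 0) && all(s >= 0 & s <= 1))
  expect_error(km_estimate(numeric(0), numeric(0), 24), "empty")
})

test_that("logrank contracts: symmetry, monotone-time invariance, power", {
  set.seed(4)
  time <- rexp(80, 0.05); event <- rbinom(80, 1, 0.8)
  grp <- rep(1:2, 40)
  a <- logrank(time, event, grp)
  b <- logrank(time, event, 3 - grp)           # label swap
  expect_equal(a$statistic, b$statistic)
  d <- logrank(sqrt(time), event, grp)         # monotone transform of time
  expect_equal(a$statistic, d$statistic, tolerance = 1e-12)
  expect_error(logrank(time, event, rep(1, 80)), "2 groups")

  # planted hazard ratio 1.7: median p over modest reps well under 0.01
  ps <- vapply(1:25, function(s) {
    set.seed(100 + s)
    t1 <- rexp(200, 0.05); t2 <- rexp(200, 0.085)
    cens <- rexp(400, 0.015)
    tt <- pmin(c(t1, t2), cens); ev <- as.integer(c(t1, t2) <= cens)
    logrank(tt, ev, rep(1:2, each = 200))$p
  }, numeric(1))
  expect_lt(stats::median(ps), 0.01)
})

test_that("cox_fit recovers a planted hazard ratio and obeys reparameterization", {
  set.seed(9)
  hrs <- replicate(30, {
    x <- rbinom(400, 1, 0.5)
    tt <- rexp(400, 0.05 * 1.7^x)
    cens <- rexp(400, 0.015)
    fit <- cox_fit(pmin(tt, cens), as.integer(tt <= cens), data.frame(x = x))
    c(fit$coef$hr, fit$coef$lo95 <= 1.7 & fit$coef$hi95 >= 1.7)
  })
  expect_gt(mean(hrs[1, ]), 1.55)
  expect_lt(mean(hrs[1, ]), 1.85)
  expect_gte(mean(hrs[2, ]), 0.85)  # CI coverage near nominal on 30 reps

  # scaling a continuous covariate by c scales beta by 1/c, p unchanged
  z <- rnorm(400)
  tt <- rexp(400, 0.05 * exp(0.4 * z))
  f1 <- cox_fit(tt, rep(1, 400), data.frame(z = z))
  f2 <- cox_fit(tt, rep(1, 400), data.frame(z = 10 * z))
  expect_equal(f1$coef$beta, 10 * f2$coef$beta, tolerance = 1e-6)
  expect_equal(f1$coef$p, f2$coef$p, tolerance = 1e-8)

  expect_error(cox_fit(tt, rep(1, 400), data.frame(k = rep(1, 400))), "constant")
})

test_that("define_uhr designates the planted worst cluster and summarizes it", {
  picks <- vapply(1:10, function(s) {
    sim <- simulate_cohort(cohort_spec(n_samples = 150, n_genes = 30,
                                       hazards = c(0.05, 0.05, 0.12), seed = s))
    st <- define_uhr(sim$truth$sample_labels, sim$clinical$os_months,
                     sim$clinical$os_event)
    st$uhr_cluster
  }, numeric(1))
  expect_gte(mean(picks == 3), 0.9)

  sim <- simulate_cohort(cohort_spec(hazards = c(0.05, 0.05, 0.12), seed = 2))
  st <- define_uhr(sim$truth$sample_labels, sim$clinical$os_months,
                   sim$clinical$os_event)
  expect_identical(levels(st$labels), c("HR", "UHR"))
  expect_identical(sum(st$labels == "UHR"),
                   sum(sim$truth$sample_labels == st$uhr_cluster))
  expect_lt(st$km_subtype[["UHR"]], st$km_subtype[["HR"]])
  expect_lt(st$logrank_p, 0.05)
  expect_gt(st$fit$coef$hr[1], 1)
  expect_false(st$unstable)
})

test_that("degenerate designation is flagged unstable", {
  # two clusters with identical deterministic outcomes: KM gap is 0
  time <- rep(c(10, 20, 30, 40), times = 3)
  event <- rep(1, 12)
  labels <- rep(1:3, each = 4)
  st <- define_uhr(labels, time, event, horizon = 24)
  expect_true(st$unstable)
})

test_that("UHR designation reproduces across independently seeded cohorts", {
  spec1 <- cohort_spec(hazards = c(0.05, 0.05, 0.12), seed = 21)
  spec2 <- cohort_spec(hazards = c(0.05, 0.05, 0.12), seed = 22)
  picks <- vapply(list(spec1, spec2), function(sp) {
    sim <- simulate_cohort(sp)
    model <- spectral_cocluster(sim$expr, k = 3, seed = sp$seed)
    st <- define_uhr(model, sim$clinical$os_months, sim$clinical$os_event)
    # map fitted UHR cluster back to the planted partition
    fitted_uhr <- names(which.max(table(
      sim$truth$sample_labels[model$sample_labels == st$uhr_cluster])))
    as.integer(fitted_uhr)
  }, integer(1))
  expect_identical(picks[1], picks[2])
  expect_identical(picks[1], 3L)
})
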