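test_that("tip branching: edge probabilities give exact tip counts", {
  set.seed(1)
  none <- simulate_tips(8, 0)
  expect_equal(none$b0, 1)
  expect_equal(none$b1, 1)
  all_split <- simulate_tips(3, 1)
  expect_equal(all_split$b0, 8)
  expect_equal(all_split$b1, 4)
  expect_true(all(diff(all_split$history) >= 0))
})

test_that("tip branching: mean b0/b1 converges to 1 + branch_prob", {
  set.seed(2024)
  ratios <- replicate(10000, {
    t <- simulate_tips(10, 0.3)
    t$b0 / t$b1
  })
  # E[b0 | b1] = b1 (1 + p); MC error ~ sd/100
  expect_equal(mean(ratios), 1.3, tolerance = 0.01)
})

test_that("sim_params rejects degenerate parameterizations", {
  expect_error(sim_params(count_beta = c(1, 0.5, 0.01)), "quadratic")
  expect_error(sim_params(branch_prob = 1.5), "branch_prob")
  expect_error(sim_params(first_reproductive_age = 3), "first_reproductive_age")
  expect_error(sim_params(random_effect_sd = c(intercept = -1)), "SDs")
})

test_that("noise-free limit is fully deterministic and reproducible", {
  p <- sim_params(nb_dispersion = Inf,
                  random_effect_sd = c(intercept = 0, slope = 0),
                  size_noise_sd = 0, s1_mass_sd = 0, branch_prob = 0,
                  n_shoots = 2, seed = 5)
  d1 <- simulate_site(p)
  d2 <- simulate_site(p)
  expect_identical(d1$shoots[[1]]$segments, d2$shoots[[1]]$segments)
  expect_identical(d1$shoots[[1]]$reproductive_mass, d2$shoots[[1]]$reproductive_mass)
  # counts collapse to the rounded quadratic mean, masses to their means
  s <- d1$shoots[[1]]
  ages <- s$segments$age_years
  mu <- exp(p$count_beta[1] + p$count_beta[2] * ages + p$count_beta[3] * ages^2)
  mu[ages < p$first_reproductive_age] <- 0
  expect_identical(s$segments$receptacle_count, as.integer(round(mu)))
})

test_that("segments younger than first_reproductive_age carry no receptacles", {
  d <- simulate_site(sim_params(first_reproductive_age = 2, n_shoots = 30, seed = 8))
  for (s in d$shoots) {
    expect_true(all(s$segments$receptacle_count[s$segments$age_years < 2] == 0))
  }
  d1 <- simulate_site(sim_params(first_reproductive_age = 1, n_shoots = 10, seed = 8))
  any_age1 <- any(vapply(d1$shoots, function(s)
    s$segments$receptacle_count[s$segments$age_years == 1] > 0, logical(1)))
  expect_true(any_age1)
})

test_that("expected count peaks near -beta1/(2 beta2)", {
  p <- sim_params(count_beta = c(1.5, 0.5, -0.06), first_reproductive_age = 0,
                  n_shoots = 5000, seed = 3)
  d <- simulate_site(p)
  tab <- counts_by_age(d)
  m <- tapply(tab$receptacle_count, tab$age_years, mean)
  emp_argmax <- as.integer(names(which.max(m)))
  expect_true(emp_argmax %in% c(4L, 5L))  # true argmax 0.5/(2*0.06) = 4.17
})

test_that("counts are overdispersed relative to Poisson at finite k", {
  p <- sim_params(count_beta = c(1.5, 0.4, -0.06), first_reproductive_age = 0,
                  nb_dispersion = 1, random_effect_sd = c(intercept = 0, slope = 0),
                  n_shoots = 2000, seed = 13)
  d <- simulate_site(p)
  tab <- counts_by_age(d)
  by_age <- split(tab$receptacle_count, tab$age_years)
  v_over_m <- vapply(by_age, function(x) stats::var(x) / mean(x), numeric(1))
  expect_true(all(v_over_m > 1))
})

test_that("log mean counts are empirically concave in age", {
  p <- sim_params(count_beta = c(1.5, 0.5, -0.06), first_reproductive_age = 0,
                  n_shoots = 5000, seed = 21)
  tab <- counts_by_age(simulate_site(p))
  logm <- log(tapply(tab$receptacle_count, tab$age_years, mean))
  # quadratic refit of the empirical log means has a negative curvature
  ages <- as.numeric(names(logm))
  curv <- stats::coef(stats::lm(logm ~ ages + I(ages^2)))[[3]]
  expect_lt(curv, 0)
})

test_that("simulated sites are reproducible under a fixed seed", {
  p <- sim_params(n_shoots = 10, seed = 77)
  d1 <- simulate_site(p)
  d2 <- simulate_site(p)
  expect_equal(d1$receptacle_pools, d2$receptacle_pools)
  expect_equal(vapply(d1$shoots, function(s) s$vegetative_mass, numeric(1)),
               vapply(d2$shoots, function(s) s$vegetative_mass, numeric(1)))
})

test_that("built-in profiles validate and span the observed allocation ranges", {
  profs <- default_profiles()
  expect_gte(length(profs), 4L)
  targets <- lapply(profs, attr, "targets")
  re <- vapply(targets, `[[`, numeric(1), "RE")
  tau <- vapply(targets, `[[`, numeric(1), "turnover")
  expect_equal(unname(re[["qeqertarsuaq-like"]]), 0.14)
  expect_equal(unname(tau[["hirsholmene-like"]]), 0.67)
  expect_lte(min(re), 0.11); expect_gte(max(re), 0.73)
  expect_lte(min(tau), 0.22); expect_gte(max(tau), 0.67)
  # every profile is a valid parameterization: re-running the constructor
  # on its own fields succeeds
  for (p in profs) {
    expect_s3_class(do.call(sim_params, unclass(p)), "asco_sim_params")
  }
})

test_that("northern and temperate profiles reproduce their site means at n = 500", {
  profs <- default_profiles()
  north <- profs[["kronprinsen-like"]]
  north$n_shoots <- 500L; north$seed <- 301L
  s <- site_summary(simulate_site(north))
  expect_lt(abs(s$mean[s$metric == "RE"] - 0.11), 0.03)

  temperate <- profs[["hirsholmene-like"]]
  temperate$n_shoots <- 500L; temperate$seed <- 302L
  s2 <- site_summary(simulate_site(temperate))
  expect_lt(abs(s2$mean[s2$metric == "turnover"] - 0.67), 0.05)
})

test_that("unattainable turnover targets are refused with the attainable range", {
  expect_error(
    calibrate_profile(target_re = 0.2, target_turnover = 0.9,
                      max_age = 12L, branch_prob = 0.1, n_cal = 500L),
    "not attainable")
})
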