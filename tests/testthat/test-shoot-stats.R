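test_that("counts_by_age builds the long table and caps ages at 12", {
  s <- make_test_shoot(ages = 0:2, counts = c(0L, 2L, 5L))
  d <- site_dataset(site_record("demo", latitude = 60), list(s))
  tab <- counts_by_age(d)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$receptacle_count, c(0L, 2L, 5L))

  old <- make_test_shoot(ages = 0:13, masses = rep(0.05, 14),
                         counts = c(rep(1L, 13), 3L), V = 2)
  d2 <- site_dataset(site_record("demo", latitude = 60), list(old))
  expect_message(tab2 <- counts_by_age(d2), "excluded")
  expect_false(13L %in% tab2$age_years)
  expect_identical(attr(tab2, "n_excluded"), 1L)
})

test_that("count-age fit recovers the concave quadratic and its peak", {
  p <- sim_params(count_beta = c(1.5, 0.5, -0.06), first_reproductive_age = 0,
                  n_shoots = 200, seed = 314)
  tab <- counts_by_age(simulate_site(p))
  for (m in c("pooled-NB", "NB-with-shoot-intercepts")) {
    f <- fit_count_age(tab, method = m)
    expect_true(f$converged)
    expect_lt(f$beta[["beta2"]], 0)
    expect_lt(abs(f$argmax_age - 0.5 / (2 * 0.06)), 1)
  }
  # the mixed fit estimates the shoot-level intercept variance
  fm <- fit_count_age(tab, method = "NB-with-shoot-intercepts")
  expect_gt(fm$shoot_intercept_var, 0)
})

test_that("all-zero counts give a flagged degenerate fit, not an error", {
  tab <- tibble::tibble(shoot_id = rep(c("a", "b"), each = 5),
                        age_years = rep(0:4, 2),
                        receptacle_count = 0L)
  f <- fit_count_age(tab)
  expect_false(f$converged)
  expect_match(f$reason, "all counts are zero")
  expect_true(is.na(f$argmax_age))
})

test_that("near-Poisson data: NB and Poisson agree on the age trend", {
  p <- sim_params(count_beta = c(1.2, 0.5, -0.06), first_reproductive_age = 0,
                  nb_dispersion = 1e6, random_effect_sd = c(intercept = 0, slope = 0),
                  n_shoots = 200, seed = 271)
  tab <- counts_by_age(simulate_site(p))
  f <- fit_count_age(tab, method = "pooled-NB")
  pois <- stats::glm(receptacle_count ~ age_years + I(age_years^2),
                     family = stats::poisson, data = tab)
  expect_gt(f$dispersion_k, 50)  # equidispersion -> large NB size estimate
  expect_equal(unname(f$beta), unname(stats::coef(pois)), tolerance = 1e-3)
})

test_that("size-age OLS is exact on noiseless lines and degenerate on constants", {
  ages <- 2:12
  exact <- tibble::tibble(age_years = ages,
                          mean_receptacle_mass = -0.0011 * ages + 0.023)
  f <- suppressWarnings(fit_size_age(exact))
  expect_equal(f$slope, -0.0011)
  expect_equal(f$intercept, 0.023)
  expect_equal(f$r_squared, 1)

  flat <- tibble::tibble(age_years = ages, mean_receptacle_mass = 0.02)
  f0 <- suppressWarnings(fit_size_age(flat))
  expect_equal(f0$slope, 0)
  expect_true(is.na(f0$r_squared) || f0$r_squared == 0)

  expect_error(fit_size_age(exact[1:2, ]), "at least 3")
})

test_that("size-age fit recovers the generating slope from pooled masses", {
  p <- sim_params(size_intercept = 0.03, size_slope = -0.0015,
                  size_noise_sd = 0.002, first_reproductive_age = 1,
                  n_shoots = 200, seed = 55)
  d <- simulate_site(p)
  f <- fit_size_age(tibble::tibble(
    age_years = d$receptacle_pools$age_years,
    mean_receptacle_mass = d$receptacle_pools$mean_receptacle_mass))
  ci <- stats::confint(f$fit)["age_years", ]
  expect_gt(-0.0015, ci[1])
  expect_lt(-0.0015, ci[2])
})

test_that("half-production age matches the cumulative-sum oracle", {
  expect_identical(cumulative_half_age(c(0, 2, 4, 6, 4, 2)), 3)
  # single productive age
  expect_identical(cumulative_half_age(c(0, 0, 7, 0)), 2)
  # symmetric distributions: half age equals the (lower) median age
  set.seed(9)
  for (i in 1:20) {
    half <- sample(0:20, sample(2:8, 1))
    counts <- c(half, rev(half))
    expect_identical(cumulative_half_age(counts), half_age_oracle(counts))
  }
  # scale invariance
  cts <- c(1, 5, 9, 2, 0, 3)
  for (k in c(0.5, 2, 17)) {
    expect_identical(cumulative_half_age(k * cts), cumulative_half_age(cts))
  }
  expect_error(cumulative_half_age(c(0, 0, 0)), "all counts are zero")
})
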