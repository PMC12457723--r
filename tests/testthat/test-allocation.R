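test_that("allocation arithmetic follows the defining equations", {
  expect_equal(tip_count(12, 8), 10)
  expect_equal(tip_count(1, 1), 1)
  expect_equal(tip_count(7, 4), 5.5)
  expect_error(tip_count(0, 1), ">= 1")

  expect_equal(annual_vegetative_growth(0.1, 10), 1.0)
  expect_equal(annual_vegetative_growth(0.2, 5.5), 1.1)
  expect_error(annual_vegetative_growth(-0.1, 2), "> 0")

  expect_equal(turnover_rate(1.0, 4.0), 0.25)
  expect_equal(turnover_rate(0.5, 0.5), 1.0)
  for (V in c(0.3, 1, 7, 120)) expect_equal(turnover_rate(0.22 * V, V), 0.22)
  expect_error(turnover_rate(1, 0), "> 0")

  expect_equal(reproductive_effort(0, 5), 0)
  expect_equal(reproductive_effort(1, 4), 0.25)
  expect_equal(reproductive_effort(3.65, 5.0), 0.73)

  expect_equal(annual_reproductive_allocation(0, 1), 0)
  expect_equal(annual_reproductive_allocation(1, 1), 0.5)
  expect_equal(annual_reproductive_allocation(3, 1), 0.75)
  expect_error(annual_reproductive_allocation(0, 0), "undefined")
})

test_that("carbon conversion and C-unit allocation behave as products and ratios", {
  expect_equal(to_carbon(10, 0.30), 3.0)
  expect_equal(to_carbon(0, 0.4), 0)
  expect_equal(to_carbon(6522 * 0.14, 0.25), 228.27)
  expect_error(to_carbon(1, 1.2), "\\[0, 1\\]")

  # equal fractions cancel: C-unit allocation equals the dry-mass allocation
  expect_equal(carbon_allocation(2, 3, 0.3, 0.3),
               annual_reproductive_allocation(2, 3))
  expect_equal(carbon_allocation(1, 1, 0.2, 0.3), 0.4)
  # receptacles poorer in C than vegetative tissue pull the allocation down
  expect_lt(carbon_allocation(2, 3, 0.25, 0.35),
            annual_reproductive_allocation(2, 3))
})

test_that("shoot_allocation composes the chain and honours broken shoots", {
  s <- make_test_shoot(b0 = 12, b1 = 8, V = 4, R = 1)
  a <- shoot_allocation(s, mean_s1_mass = 0.1)
  expect_equal(a$n_tips, 10)
  expect_equal(a$annV, 1.0)
  expect_equal(a$turnover, 0.25)
  expect_equal(a$RE, 0.25)
  expect_equal(a$annRA, 0.5)

  zero <- make_test_shoot(R = 0)
  a0 <- shoot_allocation(zero, mean_s1_mass = 0.1)
  expect_equal(a0$annRA, 0)
  expect_equal(a0$RE, 0)

  br <- make_test_shoot(R = 1, V = 4, broken = TRUE)
  ab <- shoot_allocation(br, mean_s1_mass = 0.1)
  expect_true(is.na(ab$annV) && is.na(ab$turnover) && is.na(ab$annRA))
  expect_equal(ab$RE, 0.25)
})

test_that("annRA = RE / (RE + turnover) and is scale invariant", {
  set.seed(42)
  for (i in 1:50) {
    V <- runif(1, 0.5, 50); R <- runif(1, 0, 20)
    s1 <- runif(1, 0.01, 0.5); b1 <- sample(1:20, 1); b0 <- b1 + sample(0:10, 1)
    s <- make_test_shoot(b0 = b0, b1 = b1, V = V, R = R,
                         masses = rep(V / 10, 5))
    a <- shoot_allocation(s, mean_s1_mass = s1)
    expect_equal(a$annRA, a$RE / (a$RE + a$turnover), tolerance = 1e-13)
    # common mass rescaling leaves annRA unchanged
    k <- runif(1, 0.1, 10)
    s2 <- make_test_shoot(b0 = b0, b1 = b1, V = k * V, R = k * R,
                          masses = rep(k * V / 10, 5))
    a2 <- shoot_allocation(s2, mean_s1_mass = k * s1)
    expect_equal(a2$annRA, a$annRA, tolerance = 1e-12)
  }
})

test_that("annRA increases in R and decreases in annV", {
  R <- seq(0, 5, by = 0.5)
  expect_true(all(diff(annual_reproductive_allocation(R, 1)) > 0))
  annV <- seq(0.2, 5, by = 0.2)
  expect_true(all(diff(annual_reproductive_allocation(1, annV)) < 0))
})

test_that("tip-count choice brackets annV: b1 <= mean <= b0", {
  s <- make_test_shoot(b0 = 12, b1 = 7, V = 4, R = 1)
  a_b1 <- shoot_allocation(s, 0.1, tip_method = "b1")
  a_m <- shoot_allocation(s, 0.1, tip_method = "mean")
  a_b0 <- shoot_allocation(s, 0.1, tip_method = "b0")
  expect_lte(a_b1$annV, a_m$annV)
  expect_lte(a_m$annV, a_b0$annV)
})

test_that("site_summary reports mean and sd/sqrt(n), flagging n = 1", {
  alloc <- tibble::tibble(shoot_id = c("a", "b"), broken = FALSE,
                          n_tips = 2, annV = c(0.2, 0.4),
                          turnover = c(0.2, 0.4), RE = c(0.2, 0.4),
                          annRA = c(0.2, 0.4), annRA_C = NA_real_)
  s <- site_summary(alloc)
  expect_equal(s$mean[s$metric == "RE"], 0.3)
  expect_equal(s$se[s$metric == "RE"], 0.1)
  expect_true(is.na(s$se[s$metric == "annRA_C"]))

  one <- site_summary(alloc[1, ])
  expect_true(all(is.na(one$se[one$n == 1])))

  twin <- site_summary(alloc[c(1, 1), ])
  expect_equal(twin$se[twin$metric == "RE"], 0)
})

test_that("areal production is linear in biomass with total = veg + rep", {
  site <- site_record("x", latitude = 60, standing_biomass = 1000,
                      c_fraction_vegetative = 0.4, c_fraction_reproductive = 0.25)
  alloc <- tibble::tibble(RE = c(0.2, 0.3), turnover = c(0.3, 0.5))
  ap <- areal_production(site, alloc)
  expect_equal(ap$mean[ap$component == "reproductive"], 1000 * 0.25 * 0.25)
  expect_equal(ap$mean[ap$component == "total"],
               sum(ap$mean[ap$component %in% c("vegetative", "reproductive")]))

  site2 <- site; site2$standing_biomass <- 2000
  ap2 <- areal_production(site2, alloc)
  expect_equal(ap2$mean, 2 * ap$mean)

  expect_equal(areal_production(site, tibble::tibble(RE = 0:1 * 0, turnover = c(.3, .3)))$mean[
    ap$component == "reproductive"], 0)

  nosite <- site_record("y", latitude = 60)
  expect_error(areal_production(nosite, alloc), "biomass")
})
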