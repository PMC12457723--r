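# shared fixtures and independent oracles

make_test_shoot <- function(shoot_id = "s1", site_id = "demo",
                            ages = 0:4,
                            masses = NULL,
                            counts = NULL,
                            b0 = 4, b1 = 3,
                            V = NULL, R = 0.1, broken = FALSE) {
  if (is.null(masses)) masses <- 0.05 + 0.01 * ages
  if (is.null(counts)) counts <- pmax(0L, as.integer(round(2 * ages * exp(-0.2 * ages))))
  if (is.null(V)) V <- sum(masses) * 2
  shoot(shoot_id, site_id,
        tibble::tibble(age_years = as.integer(ages),
                       segment_dry_mass = masses,
                       receptacle_count = as.integer(counts)),
        b0_count = b0, b1_count = b1,
        vegetative_mass = V, reproductive_mass = R, broken = broken)
}

make_test_site <- function(n = 3, site_id = "demo", ...) {
  site <- site_record(site_id, latitude = 60, standing_biomass = 5000,
                      standing_biomass_se = 500,
                      c_fraction_vegetative = 0.40,
                      c_fraction_reproductive = 0.28)
  shoots <- lapply(seq_len(n), function(i) {
    make_test_shoot(shoot_id = paste0("s", i), site_id = site_id,
                    R = 0.05 * i, ...)
  })
  site_dataset(site, shoots)
}

# independent least-squares oracle: numeric minimization of the sum of
# squared errors, no use of lm()
brute_force_ols <- function(x, y) {
  sse <- function(par) sum((y - par[1] - par[2] * x)^2)
  fit <- stats::optim(c(mean(y), 0), sse, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  # polish with a derivative-free pass to squeeze out the last digits
  fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000,
                                     parscale = pmax(abs(fit$par), 1e-6)))
  c(intercept = fit$par[1], slope = fit$par[2])
}

# cumulative-sum oracle for the half-production age
half_age_oracle <- function(counts, ages = seq_along(counts) - 1) {
  o <- order(ages)
  cs <- cumsum(counts[o])
  ages[o][which(cs >= sum(counts) / 2)[1]]
}

# standard error of the site-mean estimator for metrics that multiply every
# shoot by the shared site-mean S1 mass: the within-shoot spread misses the
# shared factor, which is added back by the delta method
estimator_se <- function(dataset, metric) {
  summ <- site_summary(dataset)
  alloc <- attr(summ, "allocation")
  within <- summ$se[summ$metric == metric]
  s1 <- vapply(dataset$shoots, function(s) {
    s$segments$segment_dry_mass[s$segments$age_years == 1L][1]
  }, numeric(1))
  rel_se_s1 <- stats::sd(s1) / (mean(s1) * sqrt(length(s1)))
  v <- alloc[[metric]]
  shared <- switch(metric,
                   RE = 0,
                   turnover = mean(v, na.rm = TRUE) * rel_se_s1,
                   annV = mean(v, na.rm = TRUE) * rel_se_s1,
                   annRA = mean(v * (1 - v), na.rm = TRUE) * rel_se_s1,
                   annRA_C = mean(v * (1 - v), na.rm = TRUE) * rel_se_s1)
  sqrt(within^2 + shared^2)
}
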