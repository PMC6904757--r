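test_that("interval growth rates follow the log-ratio formula", {
  tc <- batch_time_course(c(0, 2), c(0.5, 1.0), c(10, 8))
  expect_equal(growth_rate_series(tc), log(2) / 2, tolerance = 1e-12)

  # constant biomass: mu = 0
  tc0 <- batch_time_course(c(0, 1, 2), c(0.5, 0.5, 0.5), c(10, 9, 8))
  expect_equal(growth_rate_series(tc0), c(0, 0))

  expect_error(batch_time_course(c(0, 0), c(1, 1), c(1, 1)), "increasing")
  expect_error(batch_time_course(c(0, 1), c(0, 1), c(1, 1)), "positive")
})

test_that("uptake fluxes follow the exponential-interval formula with the mu->0 limit", {
  # hand evaluation: mu = ln2/2, dC = -2, x = 0.5, exp(mu dt) - 1 = 1
  tc <- batch_time_course(c(0, 2), c(0.5, 1.0), c(10, 8))
  expect_equal(uptake_series(tc), log(2) / 2 * (-2) / (0.5 * 1), tolerance = 1e-12)

  # constant substrate: v = 0
  tcc <- batch_time_course(c(0, 1, 2), c(0.5, 1, 2), c(10, 10, 10))
  expect_equal(uptake_series(tcc), c(0, 0))

  # removable singularity at mu = 0: analytic limit dC/(x dt)
  tc0 <- batch_time_course(c(0, 2), c(0.5, 0.5), c(10, 8))
  expect_equal(uptake_series(tc0), -2 / (0.5 * 2), tolerance = 1e-12)
})

test_that("the batch simulator is inverted exactly by the interval formulas", {
  grid <- expand.grid(mu = c(0.1, 0.2, 0.45), v = c(-0.5, -2), x0 = c(0.05, 0.3))
  for (k in seq_len(nrow(grid))) {
    tc <- simulate_batch(mu = grid$mu[k], v_substrate = grid$v[k],
                         x0 = grid$x0[k], C0 = 200, times = seq(0, 5, by = 0.5))
    expect_equal(growth_rate_series(tc), rep(grid$mu[k], 10), tolerance = 1e-12)
    expect_equal(uptake_series(tc), rep(grid$v[k], 10), tolerance = 1e-10)
  }
  # zero consumption leaves substrate flat
  tcz <- simulate_batch(0.2, 0, 0.1, 50, 0:5)
  expect_equal(tcz$substrate, rep(50, 6))
  expect_true(all(diff(tcz$biomass) > 0))
  # running the tank dry is refused
  expect_error(simulate_batch(0.5, -10, 1, 5, 0:10), "exhausted")
})

test_that("through-origin fit matches its closed-form oracle", {
  expect_silent(r <- fit_through_origin(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(r$slope, 2)
  expect_equal(r$r, 1)

  # centred-orthogonal data: R = 0
  r0 <- fit_through_origin(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(r0$r, 0)

  # independent oracle: slope = sum(xy)/sum(x^2); p from the t transform
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- stats::runif(n, 0.5, 5)
    y <- 1.7 * x + stats::rnorm(n, sd = 0.3)
    r <- fit_through_origin(x, y)
    expect_equal(r$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
    rr <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r$r, rr, tolerance = 1e-12)
    tt <- rr * sqrt((n - 2) / (1 - rr^2))
    expect_equal(r$p_value, 2 * stats::pt(-abs(tt), n - 2), tolerance = 1e-9)
  }

  # scale equivariance: scaling y scales the slope, leaves R
  x <- c(1, 2, 3, 5); y <- c(1.2, 1.9, 3.4, 4.8)
  a <- fit_through_origin(x, y); b <- fit_through_origin(x, 3 * y)
  expect_equal(b$slope, 3 * a$slope, tolerance = 1e-12)
  expect_equal(b$r, a$r, tolerance = 1e-12)
})

test_that("predicted-vs-observed wiring: perfect model gives slope 1, R 1", {
  # toy yields growth = 2 * uptake; observe exactly that
  m <- make_toy_core()
  uptakes <- c(0.76, 0.81, 2.585, 0.655, 0.765)
  conds <- lapply(seq_along(uptakes), function(i)
    list(label = paste0("cond", i), medium = medium(EX_A = uptakes[i]),
         observed = 2 * uptakes[i]))
  pvo <- predicted_vs_observed(m, conds)
  expect_equal(pvo$report$slope, 1, tolerance = 1e-9)
  expect_equal(pvo$report$r, 1, tolerance = 1e-9)
  expect_equal(nrow(pvo$table), 5)
  expect_equal(pvo$table$predicted, 2 * uptakes, tolerance = 1e-9)

  # duplicating the conditions leaves the report unchanged
  pvo2 <- predicted_vs_observed(m, c(conds, conds))
  expect_equal(pvo2$report$slope, pvo$report$slope, tolerance = 1e-12)
  expect_equal(pvo2$report$r, pvo$report$r, tolerance = 1e-9)

  # the wide-table interface reaches the same numbers
  tab <- data.frame(label = paste0("cond", 1:5), observed = 2 * uptakes,
                    EX_A = uptakes, check.names = FALSE)
  pvo3 <- predicted_vs_observed(m, tab)
  expect_equal(pvo3$report$slope, 1, tolerance = 1e-9)
})
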