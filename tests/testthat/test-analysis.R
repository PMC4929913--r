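test_that("distinct_visited and revisit_distribution count visits correctly", {
  expect_equal(distinct_visited(make_log()), 0)

  log <- make_log(events = data.frame(step = 1:3, site_id = c(7L, 7L, 9L)),
                  n_steps = 3)
  expect_equal(distinct_visited(log), 2)
  rd <- revisit_distribution(log)
  expect_equal(rd$site_id, c(7L, 9L))
  expect_equal(rd$n_visits, c(2L, 1L))
  expect_equal(attr(rd, "n_data"), 2)

  cum <- cumulative_revisits(rd)
  expect_equal(cum$n_sites_ge, c(2L, 1L))  # >=1 visit: both; >=2: one
})

test_that("revisit counts conserve the total number of visit events", {
  log <- run_trial(tiny_config(), seed = 3)
  rd <- revisit_distribution(log)
  expect_equal(sum(rd$n_visits), nrow(log$events))
  expect_equal(attr(rd, "n_data"), distinct_visited(log))
})

test_that("akaike weights are normalised relative likelihoods", {
  w <- akaike_weights(c(10, 10))
  expect_equal(w, c(0.5, 0.5))
  set.seed(1)
  for (i in 1:20) {
    w <- akaike_weights(runif(3, 0, 100))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), 1)
  }
})

test_that("fit_tail recovers parameters from synthetic samples", {
  # discrete power-law data: exponent recovered, power law dominates
  set.seed(11)
  x <- rzeta(1e4, mu = 1.5)
  f <- fit_tail(x)
  expect_lt(abs(f$power_law$exponent - 1.5), 0.05)
  expect_gt(f$power_law$akaike_weight, 0.99)

  # geometric data: rate recovered, exponential dominates
  set.seed(12)
  lambda <- 0.2
  y <- rdexp1(1e4, lambda)
  g <- fit_tail(y)
  expect_lt(abs(g$exponential$exponent - lambda), 0.02)
  expect_gt(g$exponential$akaike_weight, 0.99)
  expect_equal(preferred_family(g), "exponential")
})

test_that("fit_tail is invariant to input order and guards its domain", {
  set.seed(2)
  x <- rzeta(500, 1.8)
  f1 <- fit_tail(x)
  f2 <- fit_tail(rev(x))
  expect_equal(f1$power_law$exponent, f2$power_law$exponent)
  expect_equal(f1$power_law$akaike_weight, f2$power_law$akaike_weight)

  expect_error(fit_tail(numeric(0)), "non-empty")
  expect_error(fit_tail(c(1, 0.5)), "integers")
  expect_warning(fit_tail(rep(3, 10)), "degenerate")
})

test_that("MSD is zero for a stationary walk and exactly t^2 for a ballistic one", {
  still <- make_log(positions = data.frame(step = 0:20, x = 50, y = 50,
                                           rule = "exploitation"),
                    config = sim_config(n_steps = 20))
  m <- mean_squared_displacement(still, bin_size = 5)
  expect_true(all(m$mean_R2 == 0))

  line <- make_log(positions = data.frame(step = 0:30, x = 50 + 0:30, y = 50,
                                          rule = "exploitation"),
                   config = sim_config(n_steps = 30, field_width = 100))
  m <- mean_squared_displacement(line, bin_size = 1)
  expect_equal(m$mean_R2, (1:30)^2)
  expect_equal(m$t2, (1:30)^2)
})

test_that("MSD rejects trials of mismatched length and averages across trials", {
  a <- make_log(n_steps = 10)
  b <- make_log(n_steps = 20)
  expect_error(mean_squared_displacement(list(a, b)), "same number of steps")

  logs <- lapply(1:3, function(s) run_trial(tiny_config(), seed = s))
  m <- mean_squared_displacement(logs, bin_size = 10)
  expect_equal(nrow(m), 20)
  expect_true(all(m$mean_R2 >= 0 & m$mean_R2 <= 2 * 100^2))
})

test_that("density maps are half-open occupancy histograms conserving mass", {
  one <- make_log(positions = data.frame(step = 0, x = 50, y = 50,
                                         rule = "exploitation"),
                  config = sim_config(n_steps = 0))
  d <- density_map(one, bin_width = 4)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$ix, d$iy, d$count), c(12, 12, 1))

  log <- run_trial(tiny_config(), seed = 6)
  d <- density_map(log, bin_width = 4)
  expect_equal(sum(d$count), nrow(log$positions))
  expect_true(all(d$count >= 1))
})
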