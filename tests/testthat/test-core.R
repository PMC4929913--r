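test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(switch_prob = 1.5), "switch_prob")
  expect_error(sim_config(visual_radius = 0), "visual_radius")
  expect_error(sim_config(start_x = 120), "start position")
  expect_error(sim_config(field_width = -1), "field dimensions")
  expect_error(spatial_memory_config(theta_reference = 5, theta_work = 5),
               "theta_work")
  expect_error(spatial_memory_config(prob = -0.1), "prob")
  expect_error(spatial_memory_config(n_locations = 0), "n_locations")
})

test_that("generate_site_field is uniform, in bounds and seed-deterministic", {
  cfg <- sim_config(n_sites = 0)
  expect_equal(nrow(generate_site_field(cfg, seed = 1)), 0)

  cfg <- sim_config(n_sites = 1000)
  f1 <- generate_site_field(cfg, seed = 42)
  f2 <- generate_site_field(cfg, seed = 42)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 1000)
  expect_true(all(f1$x >= 0 & f1$x <= 100 & f1$y >= 0 & f1$y <= 100))
  expect_false(identical(f1, generate_site_field(cfg, seed = 43)))

  # CLT check on the uniform sampler: mean x within 3 standard errors of 50
  cfg <- sim_config(n_sites = 10000)
  f <- generate_site_field(cfg, seed = 7)
  se <- (100 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(f$x) - 50), 3 * se)
  expect_lt(abs(mean(f$y) - 50), 3 * se)
})

test_that("site_field rejects duplicate ids and out-of-bounds coordinates", {
  expect_error(make_field(c(1, 2), c(1, 2))[0, ], NA)
  expect_error(site_field(data.frame(site_id = c(1, 1), x = 1:2, y = 1:2),
                          100, 100), "unique")
  expect_error(make_field(101, 50), "within the field")
})

test_that("local_sites is a closed ball excluding the occupied position", {
  f <- make_field(c(52, 55), c(53, 55))
  got <- local_sites(f, c(50, 50), 4)
  expect_equal(got$site_id, 1L)  # d = 3.606 <= 4 < 7.07

  expect_equal(nrow(local_sites(f, c(10, 10), 4)), 0)

  # boundary convention: distance exactly 4.00 is included
  f2 <- make_field(54, 50)
  expect_equal(nrow(local_sites(f2, c(50, 50), 4)), 1)

  # the occupied site (distance exactly 0) is excluded
  f3 <- make_field(c(50, 51), c(50, 50))
  expect_equal(local_sites(f3, c(50, 50), 4)$site_id, 2L)
})

test_that("local_sites output is invariant to site ordering", {
  set.seed(1)
  f <- make_field(runif(50, 40, 60), runif(50, 40, 60))
  shuffled <- site_field(f[sample(nrow(f)), ], 100, 100)
  expect_identical(local_sites(f, c(50, 50), 6),
                   local_sites(shuffled, c(50, 50), 6))
})

test_that("random cardinal steps move one step_size along an axis and stay in bounds", {
  set.seed(1)
  deltas <- t(replicate(200, random_cardinal_step(c(50, 50), 1, 100, 100) - c(50, 50)))
  expect_true(all(rowSums(abs(deltas)) == 1))
  expect_true(all(abs(deltas) %in% c(0, 1)))

  # direction frequencies ~ 1/4 within 3 binomial standard errors
  set.seed(2)
  n <- 1e5
  dirs <- replicate(n, {
    p <- random_cardinal_step(c(50, 50), 1, 100, 100)
    paste(p - c(50, 50), collapse = ",")
  })
  freq <- table(dirs) / n
  expect_equal(length(freq), 4)
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("boundary handling reflects or clamps as configured", {
  # a west step from x = 0.5 would land at -0.5: reflected back to 0.5
  set.seed(1)
  seen_reflect <- FALSE
  for (i in 1:60) {
    p <- random_cardinal_step(c(0.5, 50), 1, 100, 100, boundary = "reflect")
    expect_true(p[1] >= 0 && p[1] <= 100)
    if (p[1] == 0.5 && p[2] == 50) seen_reflect <- TRUE
  }
  expect_true(seen_reflect)
  expect_equal(sceneforage:::reflect_coord(-0.5, 100), 0.5)
  expect_equal(sceneforage:::reflect_coord(100.3, 100), 99.7)

  set.seed(1)
  for (i in 1:60) {
    p <- random_cardinal_step(c(0.5, 50), 1, 100, 100, boundary = "clamp")
    expect_true(p[1] >= 0)
    expect_false(p[1] == 0.5 && p[2] == 50)  # clamping stops at 0, not 0.5
  }
})
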