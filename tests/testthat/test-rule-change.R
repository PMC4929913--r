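test_that("select_site picks nearest under exploitation, farthest under exploration", {
  cand <- data.frame(site_id = 1:3, x = c(51, 52, 53), y = 50)
  expect_equal(select_site("exploitation", cand, c(50, 50))$site_id, 1L)
  expect_equal(select_site("exploration", cand, c(50, 50))$site_id, 3L)
  expect_error(select_site("exploitation", cand[0, ], c(50, 50)), "non-empty")
})

test_that("exact distance ties are broken uniformly at random", {
  cand <- data.frame(site_id = 1:2, x = c(52, 48), y = 50)  # both at d = 2
  set.seed(5)
  n <- 1e4
  picks <- replicate(n, select_site("exploitation", cand, c(50, 50))$site_id)
  p1 <- mean(picks == 1L)
  se <- sqrt(0.25 / n)
  expect_lt(abs(p1 - 0.5), 3 * se)
})

test_that("scene memory stores, compares, switches and expires as specified", {
  # empty memory: first perceiving step stores, never compares
  up <- update_scene_memory(scene_memory(), "exploitation", n_local = 3,
                            step = 1, theta = 5, switch_prob = 0.5)
  expect_equal(up$memory$sum, 3L)
  expect_equal(up$memory$stored_at, 1L)
  expect_false(up$switched)

  # match within the window flips the rule when the coin comes up heads;
  # seed chosen so the first uniform draw is below 0.5
  set.seed(1)
  stopifnot(runif(1) < 0.5)
  set.seed(1)
  m <- list(sum = 3L, stored_at = 1L)
  up <- update_scene_memory(m, "exploitation", n_local = 3, step = 3,
                            theta = 5, switch_prob = 0.5)
  expect_true(up$switched)
  expect_equal(up$rule, "exploration")
  expect_equal(up$memory$sum, 3L)       # memory retained after a match

  # a differing count changes nothing and consumes no randomness
  set.seed(1)
  before <- .Random.seed
  up <- update_scene_memory(m, "exploitation", n_local = 4, step = 3,
                            theta = 5, switch_prob = 0.5)
  expect_false(up$switched)
  expect_identical(.Random.seed, before)

  # expiry: stored 6 steps ago with theta = 5 -> re-stored, no comparison
  up <- update_scene_memory(list(sum = 3L, stored_at = 1L), "exploitation",
                            n_local = 4, step = 7, theta = 5, switch_prob = 0.5)
  expect_equal(up$memory$sum, 4L)
  expect_equal(up$memory$stored_at, 7L)
  expect_false(up$switched)

  # the comparison boundary: step - stored_at == theta still compares
  set.seed(1)
  up <- update_scene_memory(list(sum = 3L, stored_at = 1L), "exploitation",
                            n_local = 3, step = 6, theta = 5, switch_prob = 0.5)
  expect_true(up$switched)

  expect_error(update_scene_memory(scene_memory(), "exploitation", 0, 1, 5, 0.5),
               "no site")
})

test_that("one step moves onto the selected site and logs the visit", {
  cfg <- sim_config(n_sites = 1)
  f <- make_field(51, 50)
  out <- step_agent(agent_state(cfg), f, cfg)
  expect_equal(out$visit, 1L)
  expect_equal(out$state$position, c(51, 50))
  expect_equal(out$state$step, 1L)
})

test_that("with no visible site the agent takes one random cardinal step", {
  cfg <- sim_config(n_sites = 0)
  f <- make_field(numeric(0), numeric(0))
  set.seed(3)
  out <- step_agent(agent_state(cfg), f, cfg)
  expect_true(is.na(out$visit))
  expect_equal(sum(abs(out$state$position - c(50, 50))), 1)
})

test_that("fixed exploitation on a two-site world pins into a 2-cycle", {
  cfg <- sim_config(n_sites = 2)
  f <- make_field(c(51, 49), c(50, 50))
  st <- agent_state(cfg, "fixed_exploitation")
  visits <- integer(6)
  set.seed(1)
  for (i in 1:6) {
    out <- step_agent(st, f, cfg, "fixed_exploitation")
    st <- out$state
    visits[i] <- out$visit
  }
  # first move to the nearer site is a tie-free pick; thereafter strict alternation
  expect_true(all(visits[-1] == rep_len(c(visits[2], visits[1]), 5)))
  expect_equal(sort(unique(visits)), c(1L, 2L))
})

test_that("trials are deterministic given the seed and respect bounds", {
  cfg <- tiny_config()
  a <- run_trial(cfg, seed = 11)
  b <- run_trial(cfg, seed = 11)
  expect_identical(a$positions, b$positions)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, run_trial(cfg, seed = 12)$events))

  expect_equal(nrow(a$positions), cfg$n_steps + 1)
  expect_true(all(a$positions$x >= 0 & a$positions$x <= 100 &
                  a$positions$y >= 0 & a$positions$y <= 100))
  expect_lte(distinct_visited(a), cfg$n_sites)
  expect_true(all(a$events$site_id %in% a$field$site_id))
})

test_that("a zero-step trial has one logged position and no events", {
  log <- run_trial(sim_config(n_steps = 0), seed = 1)
  expect_equal(nrow(log$positions), 1)
  expect_equal(nrow(log$events), 0)
  expect_equal(distinct_visited(log), 0)
})

test_that("rule flips occur only on steps that perceive local sites", {
  log <- run_trial(tiny_config(), seed = 4)
  rules <- log$positions$rule
  changed <- which(rules[-1] != rules[-length(rules)])  # steps 1..n with a flip
  expect_true(all(changed %in% log$events$step))
  expect_gt(log$n_rule_switches, 0)
})

test_that("switch_prob = 0 reproduces fixed exploitation trajectory-for-trajectory", {
  cfg <- tiny_config(switch_prob = 0)
  for (s in 1:3) {
    a <- run_trial(cfg, seed = s)
    b <- run_control_trial(cfg, "fixed_exploitation", seed = s)
    expect_identical(a$positions[, c("step", "x", "y")],
                     b$positions[, c("step", "x", "y")])
    expect_identical(a$events, b$events)
    expect_equal(a$n_rule_switches, 0L)
  }
})

test_that("compiled and reference engines produce identical trajectories", {
  cfg <- sim_config(n_steps = 250, n_sites = 250)
  for (s in 1:3) {
    expect_engines_agree("rule_change", cfg, s)
    expect_engines_agree("random_choice", cfg, s)
  }
  expect_engines_agree("fixed_exploitation", cfg, 7)
  expect_engines_agree("fixed_exploration", cfg, 7)
  expect_engines_agree("spatial_memory", cfg, 7,
                       spatial_memory_config(prob = 0.5, n_locations = 2))
})
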