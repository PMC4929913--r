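# Small hand-traceable worlds and a bare-bones visit_log constructor used
# across the unit tests. All fixtures are built in code.

tiny_config <- function(...) {
  sim_config(n_steps = 200, n_sites = 200, ...)
}

make_field <- function(x, y, width = 100, height = 100) {
  site_field(data.frame(site_id = seq_along(x), x = x, y = y), width, height)
}

# visit_log with given events/positions, bypassing the simulators
make_log <- function(events = data.frame(step = integer(0), site_id = integer(0)),
                     positions = NULL, n_steps = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(n_steps)) n_steps <- if (is.null(positions)) 0L else nrow(positions) - 1L
    config <- sim_config(n_steps = n_steps)
  }
  if (is.null(positions)) {
    positions <- data.frame(step = 0:config$n_steps, x = config$start_x,
                            y = config$start_y, rule = "exploitation")
  }
  structure(list(positions = positions, events = events, field = NULL,
                 config = config, mem_config = NULL, model = "rule_change",
                 seed = 0L, n_rule_switches = 0L, final_rule = "exploitation"),
            class = "visit_log")
}

# run one model with both engines and expect identical trajectories
expect_engines_agree <- function(model, config, seed, mem_config = NULL) {
  a <- sceneforage:::run_model_trial(config, model, seed,
                                     mem_config = mem_config, engine = "cpp")
  b <- sceneforage:::run_model_trial(config, model, seed,
                                     mem_config = mem_config, engine = "r")
  expect_identical(a$positions, b$positions)
  expect_identical(a$events, b$events)
  expect_identical(a$n_rule_switches, b$n_rule_switches)
}
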