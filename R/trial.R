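# Shared trial driver: seeds the per-trial stream, draws the site field from
# it, then hands the remaining stream to the chosen engine.
run_model_trial <- function(config, model, seed, mem_config = NULL,
                            engine = c("cpp", "r")) {
  validate_sim_config(config)
  model <- match.arg(model, MODELS)
  engine <- match.arg(engine)
  if (model == "spatial_memory") {
    if (is.null(mem_config)) mem_config <- spatial_memory_config()
    stopifnot(inherits(mem_config, "spatial_memory_config"))
  }
  set.seed(as.integer(seed))
  field <- generate_site_field(config)

  if (engine == "cpp") {
    mc <- if (is.null(mem_config)) spatial_memory_config() else mem_config
    res <- sim_engine_cpp(field$x, field$y, field$site_id,
                          config$field_width, config$field_height,
                          config$visual_radius, config$step_size,
                          config$n_steps, config$start_x, config$start_y,
                          match(model, MODELS) - 1L,
                          config$theta, config$switch_prob,
                          mc$theta_reference, mc$theta_work, mc$prob,
                          mc$n_locations, config$boundary == "reflect")
  } else {
    res <- sim_engine_r(config, field, model, mem_config)
  }

  positions <- data.frame(step = 0:config$n_steps,
                          x = res$positions[, 1],
                          y = res$positions[, 2],
                          rule = rule_label(res$rule_codes))
  events <- data.frame(step = res$event_steps, site_id = res$event_sites)
  structure(list(positions = positions,
                 events = events,
                 field = field,
                 config = config,
                 mem_config = mem_config,
                 model = model,
                 seed = as.integer(seed),
                 n_rule_switches = res$n_rule_switches,
                 final_rule = rule_label(res$final_rule)),
            class = "visit_log")
}

#' Run one trial of the rule-change model
#'
#' Simulates a single trial of the focal model: starting from
#' `(start_x, start_y)` under the exploitation rule with empty scene memory,
#' the agent at each step (1) detects the sites within its visual radius;
#' (2) if none are visible it takes one random cardinal step; (3) otherwise
#' it updates/compares its scene memory (possibly swapping the active rule,
#' see [update_scene_memory()]), selects a site under the now-active rule
#' ([select_site()]) and moves onto it, which counts as a visit. Exactly one
#' time step elapses per iteration. The site field is drawn uniformly at
#' random from the trial's seeded stream, so the whole trial is a
#' deterministic function of `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this trial; the site field, cardinal steps,
#'   switch coins and tie-breaks are all drawn from this one stream.
#' @param engine `"cpp"` (default, compiled) or `"r"` (pure-R reference).
#'   Both produce identical output for the same seed.
#' @return A `"visit_log"`: list with `positions` (data frame
#'   `step`, `x`, `y`, `rule` with `n_steps + 1` rows including step 0),
#'   `events` (data frame `step`, `site_id`, one row per site visit),
#'   the generated `field`, the `config`, `model`, `seed`,
#'   `n_rule_switches` and `final_rule`.
#' @examples
#' log <- run_trial(sim_config(n_steps = 200), seed = 1)
#' distinct_visited(log)
#' @export
run_trial <- function(config, seed, engine = c("cpp", "r")) {
  run_model_trial(config, "rule_change", seed, engine = engine)
}

#' Run one trial of a memory-free control model
#'
#' Identical stepping skeleton to [run_trial()], but the selection policy is
#' fixed for the whole trial and no scene memory is consulted:
#' `"fixed_exploitation"` always moves to the nearest visible site,
#' `"fixed_exploration"` to the farthest, `"random_choice"` to one visible
#' site chosen uniformly at random.
#'
#' @inheritParams run_trial
#' @param policy One of `"fixed_exploitation"`, `"fixed_exploration"`,
#'   `"random_choice"`.
#' @return A `"visit_log"` (see [run_trial()]).
#' @examples
#' log <- run_control_trial(sim_config(n_steps = 200), "fixed_exploitation", seed = 1)
#' distinct_visited(log)
#' @export
run_control_trial <- function(config, policy = c("fixed_exploitation",
                                                 "fixed_exploration",
                                                 "random_choice"),
                              seed, engine = c("cpp", "r")) {
  policy <- match.arg(policy)
  run_model_trial(config, policy, seed, engine = engine)
}

#' Run one trial of the spatial-memory control model
#'
#' The agent remembers the locations of up to `n_locations` visited sites.
#' Each step it first considers a direct return: among remembered sites
#' whose working memory has lapsed (`> theta_work` steps since last visit)
#' but whose reference memory is alive (`<= theta_reference` steps), it
#' relocates to one (uniformly among ties) with probability `prob`.
#' Otherwise it falls back to the exploitation rule on visible sites, or a
#' random cardinal step when none are visible. Every visit inserts/refreshes
#' that site in memory; exceeding capacity evicts the entry with the oldest
#' last visit, and entries not revisited within `theta_reference` steps are
#' forgotten.
#'
#' @inheritParams run_trial
#' @param mem_config A [spatial_memory_config()].
#' @return A `"visit_log"` (see [run_trial()]).
#' @examples
#' cfg <- sim_config(n_steps = 200)
#' log <- run_spatial_memory_trial(cfg, spatial_memory_config(prob = 0.8), seed = 1)
#' distinct_visited(log)
#' @export
run_spatial_memory_trial <- function(config, mem_config = spatial_memory_config(),
                                     seed, engine = c("cpp", "r")) {
  run_model_trial(config, "spatial_memory", seed, mem_config = mem_config,
                  engine = engine)
}

#' @export
print.visit_log <- function(x, ...) {
  cat(sprintf("Visit log: model '%s', seed %d, %d steps\n",
              x$model, x$seed, x$config$n_steps))
  cat(sprintf("  %d visit events over %d distinct sites",
              nrow(x$events), length(unique(x$events$site_id))))
  if (x$model == "rule_change")
    cat(sprintf("; %d rule switches, final rule '%s'",
                x$n_rule_switches, x$final_rule))
  cat("\n")
  invisible(x)
}
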