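#' Initial agent state
#'
#' Builds the state an agent starts a trial with: the configured start
#' position, the default rule (exploitation, or exploration for the fixed
#' exploration control), an empty scene memory, an empty spatial site
#' memory, and the step counter at zero.
#'
#' @param config A [sim_config()].
#' @param model Model name (see [run_experiment()] for the list).
#' @return A list with fields `position`, `rule`, `memory`
#'   ([scene_memory()]), `smem_ids`/`smem_last` (spatial site memory),
#'   `step`, `n_switches` and `last_rule` (label of the rule that produced
#'   the most recent move).
#' @export
agent_state <- function(config, model = "rule_change") {
  model <- match.arg(model, MODELS)
  rule <- if (model == "fixed_exploration") "exploration" else "exploitation"
  list(position = c(config$start_x, config$start_y),
       rule = rule,
       memory = scene_memory(),
       smem_ids = integer(0),
       smem_last = integer(0),
       step = 0L,
       n_switches = 0L,
       last_rule = if (model == "random_choice") "random" else rule)
}

#' Advance the agent by one time step
#'
#' Executes one full time step of any of the five models and returns the
#' updated state together with the visited site (if any). For the
#' rule-change model the order within the step is: perceive local sites;
#' if none, take one random cardinal step; otherwise update/compare the
#' scene memory (a match may swap the rule), select a site under the
#' now-active rule and move onto it. Control models skip the memory block;
#' the spatial-memory model first considers a probabilistic return to a
#' remembered site (see [run_spatial_memory_trial()]) and otherwise falls
#' back to exploitation. Exactly one time step elapses per call.
#'
#' This is the reference implementation: the compiled trial engine used by
#' [run_trial()] replicates it draw-for-draw, which is asserted by the
#' package tests.
#'
#' @param state State list from [agent_state()] (or a previous call).
#' @param field A [site_field()].
#' @param config A [sim_config()].
#' @param model Model name.
#' @param mem_config A [spatial_memory_config()] (spatial-memory model).
#' @return A list with elements `state` (updated) and `visit` (the visited
#'   `site_id`, or `NA` if the step was a random walk step).
#' @examples
#' cfg <- sim_config(n_sites = 1)
#' f <- site_field(data.frame(site_id = 1L, x = 51, y = 50), 100, 100)
#' st <- agent_state(cfg)
#' out <- step_agent(st, f, cfg)
#' out$visit          # site 1 visited
#' out$state$position # now (51, 50)
#' @export
step_agent <- function(state, field, config, model = "rule_change",
                       mem_config = NULL) {
  model <- match.arg(model, MODELS)
  t <- state$step + 1L
  visit <- NA_integer_
  moved <- FALSE

  if (model == "spatial_memory") {
    if (is.null(mem_config)) mem_config <- spatial_memory_config()
    keep <- (t - state$smem_last) <= mem_config$theta_reference
    state$smem_ids <- state$smem_ids[keep]
    state$smem_last <- state$smem_last[keep]
    elig <- which((t - state$smem_last) > mem_config$theta_work)
    if (length(elig) > 0 && mem_config$prob > 0 && runif(1) < mem_config$prob) {
      j <- if (length(elig) > 1) elig[draw_index(length(elig))] else elig[1]
      sid <- state$smem_ids[j]
      k <- match(sid, field$site_id)
      state$position <- c(field$x[k], field$y[k])
      state$smem_last[j] <- t
      visit <- sid
      state$last_rule <- "return"
      moved <- TRUE
    }
  }

  if (!moved) {
    cand <- local_sites(field, state$position, config$visual_radius)
    nl <- nrow(cand)
    if (nl == 0) {
      state$position <- random_cardinal_step(
        state$position, config$step_size,
        config$field_width, config$field_height, config$boundary)
      state$last_rule <- if (model == "random_choice") "random" else state$rule
    } else {
      if (model == "rule_change") {
        up <- update_scene_memory(state$memory, state$rule, nl, t,
                                  config$theta, config$switch_prob)
        state$memory <- up$memory
        state$rule <- up$rule
        if (up$switched) state$n_switches <- state$n_switches + 1L
      }
      if (model == "random_choice") {
        chosen <- cand[draw_index(nl), , drop = FALSE]
        state$last_rule <- "random"
      } else {
        chosen <- select_site(state$rule, cand, state$position)
        state$last_rule <- state$rule
      }
      state$position <- c(chosen$x, chosen$y)
      visit <- chosen$site_id
      if (model == "spatial_memory") {
        k <- match(visit, state$smem_ids)
        if (!is.na(k)) {
          state$smem_last[k] <- t
        } else {
          state$smem_ids <- c(state$smem_ids, visit)
          state$smem_last <- c(state$smem_last, t)
          if (length(state$smem_ids) > mem_config$n_locations) {
            drop <- which.min(state$smem_last)
            state$smem_ids <- state$smem_ids[-drop]
            state$smem_last <- state$smem_last[-drop]
          }
        }
      }
    }
  }

  state$step <- t
  list(state = state, visit = visit)
}
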