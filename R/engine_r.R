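# Pure-R reference engine: a thin loop over step_agent(). The Rcpp engine
# (src/engine.cpp) mirrors it draw-for-draw on R's RNG stream, so both
# produce identical trajectories from the same seed (asserted by tests).
# Rule codes: 1 exploitation, 2 exploration, 3 random choice, 4 return.

MODELS <- c("rule_change", "fixed_exploitation", "fixed_exploration",
            "random_choice", "spatial_memory")

rule_code <- function(label) match(label, c("exploitation", "exploration", "random", "return"))
rule_label <- function(code) c("exploitation", "exploration", "random", "return")[code]

sim_engine_r <- function(config, field, model, mem_config = NULL) {
  if (model == "spatial_memory" && is.null(mem_config))
    mem_config <- spatial_memory_config()
  n_steps <- config$n_steps
  st <- agent_state(config, model)

  pos <- matrix(NA_real_, n_steps + 1, 2)
  codes <- integer(n_steps + 1)
  ev_step <- integer(n_steps)
  ev_site <- integer(n_steps)
  n_ev <- 0L

  pos[1, ] <- st$position
  codes[1] <- rule_code(st$last_rule)

  for (t in seq_len(n_steps)) {
    out <- step_agent(st, field, config, model, mem_config)
    st <- out$state
    if (!is.na(out$visit)) {
      n_ev <- n_ev + 1L
      ev_step[n_ev] <- t
      ev_site[n_ev] <- out$visit
    }
    pos[t + 1, ] <- st$position
    codes[t + 1] <- rule_code(st$last_rule)
  }

  list(positions = pos, rule_codes = codes,
       event_steps = ev_step[seq_len(n_ev)],
       event_sites = ev_site[seq_len(n_ev)],
       n_rule_switches = st$n_switches,
       final_rule = rule_code(st$rule))
}
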