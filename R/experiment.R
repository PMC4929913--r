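MEM_FIELDS <- c("theta_reference", "theta_work", "prob", "n_locations")

apply_overrides <- function(config, mem_config, overrides) {
  if (length(overrides) == 0) return(list(config = config, mem_config = mem_config))
  keys <- names(overrides)
  cfg_fields <- setdiff(names(unclass(config)), character(0))
  bad <- setdiff(keys, c(cfg_fields, MEM_FIELDS))
  if (length(bad) > 0)
    stop("unrecognized override field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- unclass(config)
  for (k in intersect(keys, cfg_fields)) cfg[[k]] <- overrides[[k]]
  config <- do.call(sim_config, cfg)
  mem_keys <- intersect(keys, MEM_FIELDS)
  if (length(mem_keys) > 0) {
    mc <- if (is.null(mem_config)) unclass(spatial_memory_config())
          else unclass(mem_config)
    for (k in mem_keys) mc[[k]] <- overrides[[k]]
    mem_config <- do.call(spatial_memory_config, mc)
  }
  list(config = config, mem_config = mem_config)
}

#' Run a seeded Monte Carlo experiment
#'
#' Runs `n_trials` independent trials of one model with per-trial seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_trials - 1` and returns a
#' per-trial summary table. Configuration fields may be overridden by name
#' (e.g. `overrides = list(theta = 10)` or `list(n_sites = 500)`); unknown
#' keys are rejected before any trial runs. When `out_dir` is given, the
#' summary table (`summary.csv`) and a manifest (`manifest.json`) recording
#' model, configuration, seeds and package version are written there;
#' identical inputs reproduce byte-identical files.
#'
#' @param model One of `"rule_change"`, `"fixed_exploitation"`,
#'   `"fixed_exploration"`, `"random_choice"`, `"spatial_memory"`.
#' @param n_trials Number of trials (default 100).
#' @param config Base [sim_config()].
#' @param mem_config [spatial_memory_config()] (spatial-memory model only;
#'   a default one is created if needed).
#' @param overrides Named list of configuration overrides, keyed by
#'   [sim_config()] or [spatial_memory_config()] field names.
#' @param base_seed First trial seed.
#' @param out_dir Optional output directory (created if missing).
#' @param engine `"cpp"` or `"r"`.
#' @param return_logs If `TRUE`, attach the full list of `"visit_log"`
#'   objects as attribute `"logs"` (memory-heavy for long experiments).
#' @return Data frame with one row per trial: `trial`, `seed`, `model`,
#'   `distinct_visited`, `n_visit_events`, `n_rule_switches`, `final_rule`,
#'   plus the configuration fields that define the run (self-describing
#'   rows).
#' @examples
#' s <- run_experiment("rule_change", n_trials = 3,
#'                     config = sim_config(n_steps = 200), base_seed = 1)
#' mean(s$distinct_visited)
#' @export
run_experiment <- function(model = MODELS, n_trials = 100,
                           config = sim_config(), mem_config = NULL,
                           overrides = list(), base_seed = 1,
                           out_dir = NULL, engine = c("cpp", "r"),
                           return_logs = FALSE) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(n_trials >= 1)
  oc <- apply_overrides(config, mem_config, overrides)
  config <- oc$config
  mem_config <- oc$mem_config
  if (model == "spatial_memory" && is.null(mem_config))
    mem_config <- spatial_memory_config()

  seeds <- as.integer(base_seed) + seq_len(n_trials) - 1L
  logs <- vector("list", n_trials)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    log <- run_model_trial(config, model, seeds[i], mem_config = mem_config,
                           engine = engine)
    rows[[i]] <- data.frame(
      trial = i, seed = seeds[i], model = model,
      distinct_visited = distinct_visited(log),
      n_visit_events = nrow(log$events),
      n_rule_switches = log$n_rule_switches,
      final_rule = log$final_rule,
      n_sites = config$n_sites, visual_radius = config$visual_radius,
      theta = config$theta, switch_prob = config$switch_prob,
      n_steps = config$n_steps,
      prob = if (model == "spatial_memory") mem_config$prob else NA_real_,
      n_locations = if (model == "spatial_memory") mem_config$n_locations else NA_integer_,
      theta_reference = if (model == "spatial_memory") mem_config$theta_reference else NA_integer_,
      theta_work = if (model == "spatial_memory") mem_config$theta_work else NA_integer_)
    if (return_logs) logs[[i]] <- log
  }
  summary <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    manifest <- list(model = model, n_trials = n_trials,
                     base_seed = as.integer(base_seed), seeds = seeds,
                     engine = engine, config = unclass(config),
                     mem_config = if (is.null(mem_config)) NULL else unclass(mem_config),
                     package = "sceneforage",
                     version = as.character(packageVersion("sceneforage")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (return_logs) attr(summary, "logs") <- logs
  summary
}

#' Compare two experiment summaries
#'
#' Compares the distinct-visited-site counts of two experiments by
#' difference of means and a Mann-Whitney (Wilcoxon rank-sum) test
#' (normal approximation, as is standard for tied counts).
#'
#' @param summary_a,summary_b Data frames from [run_experiment()] (at least
#'   two trials each).
#' @return One-row data frame: `model_a`, `model_b`, `mean_a`, `mean_b`,
#'   `mean_diff`, `statistic` (the rank-sum U), `p_value`, `direction`
#'   (`"a_greater"`, `"b_greater"` or `"equal"`, by mean).
#' @examples
#' cfg <- sim_config(n_steps = 200)
#' a <- run_experiment("rule_change", 5, cfg, base_seed = 1)
#' b <- run_experiment("fixed_exploitation", 5, cfg, base_seed = 1)
#' compare_models(a, b)
#' @export
compare_models <- function(summary_a, summary_b) {
  stopifnot(is.data.frame(summary_a), is.data.frame(summary_b))
  if (nrow(summary_a) < 2 || nrow(summary_b) < 2)
    stop("both summaries need at least 2 trials", call. = FALSE)
  a <- summary_a$distinct_visited
  b <- summary_b$distinct_visited
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
  ma <- mean(a)
  mb <- mean(b)
  data.frame(model_a = summary_a$model[1], model_b = summary_b$model[1],
             mean_a = ma, mean_b = mb, mean_diff = ma - mb,
             statistic = unname(wt$statistic), p_value = wt$p.value,
             direction = if (ma > mb) "a_greater"
                         else if (ma < mb) "b_greater" else "equal")
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x Numeric sample.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @return Named numeric vector `c(lower, mean, upper)`.
#' @export
bootstrap_mean_ci <- function(x, conf = 0.95, n_boot = 2000) {
  stopifnot(length(x) >= 2)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample(x, length(x), replace = TRUE)),
                  numeric(1))
  alpha <- (1 - conf) / 2
  q <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], mean = mean(x), upper = q[2])
}
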