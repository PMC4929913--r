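# Doubles are written with 17 significant digits so CSV round-trips are
# exact at IEEE double precision.
fmt_dbl <- function(x) sprintf("%.17g", x)

#' Read and write site-field CSV files
#'
#' The on-disk format is a plain CSV with header `site_id,x,y`. Coordinates
#' are written with enough digits that `write_site_field()` followed by
#' `read_site_field()` reproduces the field exactly.
#'
#' @param field A [site_field()].
#' @param path File path.
#' @param field_width,field_height Field extent to validate the coordinates
#'   against on read.
#' @return `read_site_field()` returns a [site_field()];
#'   `write_site_field()` returns `path` invisibly.
#' @export
write_site_field <- function(field, path) {
  stopifnot(inherits(field, "site_field"))
  lines <- c("site_id,x,y",
             sprintf("%d,%s,%s", field$site_id, fmt_dbl(field$x), fmt_dbl(field$y)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_site_field
#' @export
read_site_field <- function(path, field_width = 100, field_height = 100) {
  df <- read.csv(path, colClasses = c(site_id = "integer", x = "numeric",
                                      y = "numeric"))
  site_field(df, field_width, field_height)
}

#' Read and write simulation configurations as YAML
#'
#' Flat key-value files whose keys are the [sim_config()] field names.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_config()` returns a validated [sim_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  validate_sim_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unrecognized config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a trajectory CSV
#'
#' One row per logged position (`n_steps + 1` rows): columns `step`, `x`,
#' `y`, `rule` and `site_id`, the latter empty on steps without a site
#' visit.
#'
#' @param log A `"visit_log"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(log, path) {
  stopifnot(inherits(log, "visit_log"))
  df <- log$positions
  df$site_id <- NA_integer_
  if (nrow(log$events) > 0)
    df$site_id[match(log$events$step, df$step)] <- log$events$site_id
  lines <- c("step,x,y,rule,site_id",
             sprintf("%d,%s,%s,%s,%s", df$step, fmt_dbl(df$x), fmt_dbl(df$y),
                     df$rule, ifelse(is.na(df$site_id), "", df$site_id)))
  writeLines(lines, path)
  invisible(path)
}

#' Per-trial summary as JSON
#'
#' Writes the headline quantities of one trial (model, seed, distinct
#' sites visited, number of visit events, rule switches, final rule) as a
#' small JSON object.
#'
#' @param log A `"visit_log"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trial_summary <- function(log, path) {
  stopifnot(inherits(log, "visit_log"))
  jsonlite::write_json(list(
    model = log$model, seed = log$seed,
    distinct_visited = distinct_visited(log),
    n_visit_events = nrow(log$events),
    n_rule_switches = log$n_rule_switches,
    final_rule = log$final_rule), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Tail-fit report as JSON
#'
#' @param fit A `"tail_fit"` from [fit_tail()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "tail_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
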