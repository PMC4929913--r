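#' Simulation configuration
#'
#' Builds and validates the configuration shared by every model: a bounded
#' rectangular field scattered with point sites, an agent with a finite
#' visual radius that starts from a fixed position, and a discrete clock.
#' Defaults reproduce the reference setup: a 100.00 x 100.00 field holding
#' 1000 uniformly placed sites, visual radius 4.00, unit random-walk steps,
#' 10000-step trials starting at (50.00, 50.00), scene-memory lifetime
#' `theta = 5` and rule-switch probability 0.5.
#'
#' @param field_width,field_height Field extent (length units), both > 0.
#' @param n_sites Number of point sites scattered on the field (>= 0).
#' @param visual_radius Radius of the agent's visual field; sites within this
#'   distance (closed ball) of the agent are "local" and selectable.
#' @param step_size Displacement of one random cardinal step, taken only when
#'   no site is visible.
#' @param n_steps Number of time steps per trial (>= 0).
#' @param theta Scene-memory lifetime in steps (>= 1): a stored local-site
#'   count can be compared against the current scene for `theta` steps after
#'   storage, then it is forgotten.
#' @param switch_prob Probability of swapping the active selection rule when
#'   the current local-site count matches the remembered one.
#' @param start_x,start_y Initial agent position, strictly inside the field.
#' @param boundary Boundary handling for the random cardinal walk:
#'   `"reflect"` (default) mirrors an out-of-bounds coordinate back inside,
#'   `"clamp"` truncates it at the wall.
#'
#' @return An object of class `"sim_config"`: a named list of the validated
#'   fields above.
#' @examples
#' cfg <- sim_config(n_steps = 100)
#' cfg$theta
#' @export
sim_config <- function(field_width = 100, field_height = 100, n_sites = 1000,
                       visual_radius = 4, step_size = 1, n_steps = 10000,
                       theta = 5, switch_prob = 0.5,
                       start_x = 50, start_y = 50,
                       boundary = c("reflect", "clamp")) {
  boundary <- match.arg(boundary)
  cfg <- list(
    field_width = as.numeric(field_width),
    field_height = as.numeric(field_height),
    n_sites = as.integer(n_sites),
    visual_radius = as.numeric(visual_radius),
    step_size = as.numeric(step_size),
    n_steps = as.integer(n_steps),
    theta = as.integer(theta),
    switch_prob = as.numeric(switch_prob),
    start_x = as.numeric(start_x),
    start_y = as.numeric(start_y),
    boundary = boundary
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$field_width > 0) || !(cfg$field_height > 0))
    stop("field dimensions must be positive", call. = FALSE)
  if (cfg$n_sites < 0) stop("n_sites must be >= 0", call. = FALSE)
  if (!(cfg$visual_radius > 0)) stop("visual_radius must be > 0", call. = FALSE)
  if (!(cfg$step_size > 0)) stop("step_size must be > 0", call. = FALSE)
  if (cfg$n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (cfg$theta < 1) stop("theta must be >= 1", call. = FALSE)
  if (cfg$switch_prob < 0 || cfg$switch_prob > 1)
    stop("switch_prob must be in [0, 1]", call. = FALSE)
  if (cfg$start_x < 0 || cfg$start_x > cfg$field_width ||
      cfg$start_y < 0 || cfg$start_y > cfg$field_height)
    stop("start position must lie inside the field", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  field: %.2f x %.2f, %d sites, visual radius %.2f\n",
              x$field_width, x$field_height, x$n_sites, x$visual_radius))
  cat(sprintf("  trial: %d steps from (%.2f, %.2f), step size %g, boundary '%s'\n",
              x$n_steps, x$start_x, x$start_y, x$step_size, x$boundary))
  cat(sprintf("  scene memory: theta = %d, switch_prob = %.2f\n",
              x$theta, x$switch_prob))
  invisible(x)
}

#' Spatial-memory control configuration
#'
#' Parameters for the spatial-memory control model, in which the agent keeps
#' explicit locations of up to `n_locations` visited sites. Each memorised
#' site carries two clocks measured from its last visit: a short working
#' memory (`theta_work` steps) that blocks an immediate return, and a longer
#' reference memory (`theta_reference` steps) after which the site is
#' forgotten entirely. A site whose working memory has lapsed but whose
#' reference memory is still alive is a candidate for a direct return, taken
#' with probability `prob` each step.
#'
#' @param theta_reference Reference-memory lifetime in steps.
#' @param theta_work Working-memory lifetime in steps; must be strictly less
#'   than `theta_reference`.
#' @param prob Per-step probability of returning to an eligible memorised
#'   site when at least one exists.
#' @param n_locations Memory capacity (number of site locations retained);
#'   when exceeded, the entry with the oldest last visit is evicted.
#'
#' @return An object of class `"spatial_memory_config"`.
#' @examples
#' spatial_memory_config(prob = 0.8, n_locations = 5)
#' @export
spatial_memory_config <- function(theta_reference = 10, theta_work = 5,
                                  prob = 0.5, n_locations = 1) {
  mc <- list(
    theta_reference = as.integer(theta_reference),
    theta_work = as.integer(theta_work),
    prob = as.numeric(prob),
    n_locations = as.integer(n_locations)
  )
  class(mc) <- "spatial_memory_config"
  if (mc$theta_work >= mc$theta_reference)
    stop("theta_work must be < theta_reference", call. = FALSE)
  if (mc$prob < 0 || mc$prob > 1) stop("prob must be in [0, 1]", call. = FALSE)
  if (mc$n_locations < 1) stop("n_locations must be >= 1", call. = FALSE)
  mc
}

#' @export
print.spatial_memory_config <- function(x, ...) {
  cat(sprintf(
    "Spatial-memory config: theta_reference = %d, theta_work = %d, prob = %.2f, n_locations = %d\n",
    x$theta_reference, x$theta_work, x$prob, x$n_locations))
  invisible(x)
}
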