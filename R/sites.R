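#' Construct a site field
#'
#' A site field is an immutable set of point sites on a bounded planar field,
#' stored as a data frame with columns `site_id`, `x`, `y` plus the field
#' extent as attributes. Identifiers must be unique and coordinates in
#' bounds.
#'
#' @param sites Data frame with columns `site_id` (unique integers), `x`, `y`.
#' @param field_width,field_height Field extent the coordinates must respect.
#' @return The validated data frame with class `"site_field"` prepended and
#'   attributes `field_width`, `field_height`.
#' @export
site_field <- function(sites, field_width, field_height) {
  stopifnot(is.data.frame(sites), all(c("site_id", "x", "y") %in% names(sites)))
  sites <- as.data.frame(sites)[, c("site_id", "x", "y")]
  sites$site_id <- as.integer(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("site_id values must be unique", call. = FALSE)
  if (nrow(sites) > 0 &&
      (min(sites$x) < 0 || max(sites$x) > field_width ||
       min(sites$y) < 0 || max(sites$y) > field_height))
    stop("site coordinates must lie within the field", call. = FALSE)
  rownames(sites) <- NULL
  structure(sites,
            field_width = as.numeric(field_width),
            field_height = as.numeric(field_height),
            class = c("site_field", "data.frame"))
}

#' Generate a uniform random site field
#'
#' Scatters `config$n_sites` sites independently and uniformly over the
#' field. When `seed` is supplied the generator is seeded first; otherwise
#' draws come from the current RNG state (this is how trial runners embed
#' field generation into the per-trial random stream). Coordinates are drawn
#' as all x values followed by all y values.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for a self-contained, reproducible field.
#' @return A [site_field()] with `site_id` running `1:n_sites`.
#' @examples
#' f <- generate_site_field(sim_config(n_sites = 10), seed = 1)
#' nrow(f)
#' @export
generate_site_field <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_sites
  site_field(
    data.frame(site_id = seq_len(n),
               x = runif(n, 0, config$field_width),
               y = runif(n, 0, config$field_height)),
    config$field_width, config$field_height)
}

#' Sites visible from a position
#'
#' Returns all sites within Euclidean distance `radius` of `position`
#' (closed ball: distance exactly `radius` counts), excluding any site at
#' distance exactly zero — the site the agent currently occupies is not a
#' candidate, otherwise nearest-site selection would re-pick it forever.
#' The result is ordered by `site_id`, so it is invariant to the ordering of
#' the input field.
#'
#' @param field A [site_field()].
#' @param position Numeric length-2 vector `c(x, y)`.
#' @param radius Visual radius (> 0).
#' @return A data frame of the visible sites (possibly zero rows) with
#'   columns `site_id`, `x`, `y`, ordered by `site_id`.
#' @examples
#' f <- site_field(data.frame(site_id = 1:2, x = c(52, 55), y = c(53, 55)), 100, 100)
#' local_sites(f, c(50, 50), 4)
#' @export
local_sites <- function(field, position, radius) {
  stopifnot(radius > 0, length(position) == 2)
  d2 <- (field$x - position[1])^2 + (field$y - position[2])^2
  keep <- d2 <= radius^2 & d2 > 0
  out <- as.data.frame(field)[keep, c("site_id", "x", "y"), drop = FALSE]
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
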