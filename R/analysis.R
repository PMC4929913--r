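#' Number of distinct sites visited in a trial
#'
#' @param log A `"visit_log"` from one of the trial runners.
#' @return Integer count of unique site identifiers among the visit events.
#' @export
distinct_visited <- function(log) {
  stopifnot(inherits(log, "visit_log"))
  length(unique(log$events$site_id))
}

#' Per-site revisitation distribution
#'
#' Tallies how many times each site was visited during a trial. The counts
#' vector is the input to [fit_tail()]; [cumulative_revisits()] gives the
#' survival form used for plotting cumulative revisit distributions.
#'
#' @param log A `"visit_log"`.
#' @return Data frame with columns `site_id`, `n_visits`, ordered by
#'   `site_id`, with attribute `n_data` = number of distinct visited sites.
#'   `sum(n_visits)` equals the number of visit events.
#' @examples
#' log <- run_trial(sim_config(n_steps = 200), seed = 1)
#' head(revisit_distribution(log))
#' @export
revisit_distribution <- function(log) {
  stopifnot(inherits(log, "visit_log"))
  if (nrow(log$events) == 0) {
    out <- data.frame(site_id = integer(0), n_visits = integer(0))
  } else {
    tab <- table(log$events$site_id)
    out <- data.frame(site_id = as.integer(names(tab)),
                      n_visits = as.integer(tab))
    out <- out[order(out$site_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_data") <- nrow(out)
  out
}

#' Cumulative (survival) form of a revisit distribution
#'
#' @param dist A data frame from [revisit_distribution()], or any data frame
#'   with an `n_visits` column.
#' @return Data frame `n_visits`, `n_sites_ge`: for each observed visit
#'   count, the number of sites visited at least that many times.
#' @export
cumulative_revisits <- function(dist) {
  v <- sort(unique(dist$n_visits))
  data.frame(n_visits = v,
             n_sites_ge = vapply(v, function(k) sum(dist$n_visits >= k), integer(1)))
}

#' Mean-squared displacement curve
#'
#' Computes the squared Euclidean displacement from each trial's start
#' position at every step, averages it across trials, and then averages
#' within consecutive time bins of `bin_size` steps. Each bin is reported at
#' its midpoint `t` together with `t^2`, the abscissa used when displaying
#' MSD against squared time. Saturation of this curve (a plateau) indicates
#' confined, home-range-like movement; unconstrained diffusion keeps
#' growing.
#'
#' @param logs A single `"visit_log"` or a list of them; all trials must
#'   share the same number of steps.
#' @param bin_size Width of the time bins in steps (default 10).
#' @return Data frame with columns `t` (bin midpoint, steps), `t2` (its
#'   square) and `mean_R2` (trial- and bin-averaged squared displacement).
#' @examples
#' logs <- lapply(1:3, function(s) run_trial(sim_config(n_steps = 100), seed = s))
#' head(mean_squared_displacement(logs, bin_size = 10))
#' @export
mean_squared_displacement <- function(logs, bin_size = 10) {
  if (inherits(logs, "visit_log")) logs <- list(logs)
  stopifnot(length(logs) > 0, bin_size >= 1)
  n_steps <- vapply(logs, function(l) l$config$n_steps, integer(1))
  if (length(unique(n_steps)) != 1)
    stop("all trials must share the same number of steps", call. = FALSE)
  n <- n_steps[1]
  if (n == 0) stop("trials have no steps to average over", call. = FALSE)
  r2 <- vapply(logs, function(l) {
    p <- l$positions
    (p$x[-1] - p$x[1])^2 + (p$y[-1] - p$y[1])^2
  }, numeric(n))
  r2bar <- rowMeans(as.matrix(r2))
  t <- seq_len(n)
  bin <- (t - 1) %/% bin_size
  mid <- tapply(t, bin, mean)
  m <- tapply(r2bar, bin, mean)
  out <- data.frame(t = as.numeric(mid), t2 = as.numeric(mid)^2,
                    mean_R2 = as.numeric(m))
  rownames(out) <- NULL
  out
}

#' Trajectory density map
#'
#' Two-dimensional occupancy histogram of all logged agent positions
#' (including the start position), on a square grid of half-open bins
#' `[k*w, (k+1)*w)` per axis. The total count equals the number of logged
#' positions.
#'
#' @param log A `"visit_log"`.
#' @param bin_width Bin width on each axis (default 4.00).
#' @return Data frame in long form with columns `ix`, `iy` (zero-based bin
#'   indices) and `count`, containing only occupied cells; attributes
#'   `bin_width` and `n_positions`.
#' @examples
#' log <- run_trial(sim_config(n_steps = 100), seed = 1)
#' head(density_map(log))
#' @export
density_map <- function(log, bin_width = 4) {
  stopifnot(inherits(log, "visit_log"), bin_width > 0)
  ix <- floor(log$positions$x / bin_width)
  iy <- floor(log$positions$y / bin_width)
  key <- paste(ix, iy, sep = ",")
  tab <- table(key)
  parts <- strsplit(names(tab), ",", fixed = TRUE)
  out <- data.frame(ix = vapply(parts, function(p) as.integer(p[1]), integer(1)),
                    iy = vapply(parts, function(p) as.integer(p[2]), integer(1)),
                    count = as.integer(tab))
  out <- out[order(out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  attr(out, "n_positions") <- nrow(log$positions)
  out
}
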