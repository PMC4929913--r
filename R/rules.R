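RULES <- c("exploitation", "exploration")

other_rule <- function(rule) {
  if (rule == "exploitation") "exploration" else "exploitation"
}

#' Select a site under a selection rule
#'
#' Applies one of the two local selection rules to a non-empty candidate
#' set: `"exploitation"` picks a nearest candidate, `"exploration"` a
#' farthest one. Candidates tied exactly on distance are broken uniformly at
#' random (one uniform draw, consumed only when a tie actually occurs).
#'
#' @param rule `"exploitation"` or `"exploration"`.
#' @param candidates Non-empty data frame with columns `site_id`, `x`, `y`
#'   (typically from [local_sites()]).
#' @param position Agent position `c(x, y)`.
#' @return The chosen candidate as a one-row data frame.
#' @examples
#' cand <- data.frame(site_id = 1:3, x = c(51, 52, 53), y = 50)
#' select_site("exploitation", cand, c(50, 50))$site_id
#' select_site("exploration", cand, c(50, 50))$site_id
#' @export
select_site <- function(rule, candidates, position) {
  rule <- match.arg(rule, RULES)
  if (nrow(candidates) == 0)
    stop("select_site requires a non-empty candidate set; with no visible site the caller must take a random cardinal step",
         call. = FALSE)
  d2 <- (candidates$x - position[1])^2 + (candidates$y - position[2])^2
  target <- if (rule == "exploitation") min(d2) else max(d2)
  tied <- which(d2 == target)
  i <- if (length(tied) > 1) tied[draw_index(length(tied))] else tied[1]
  candidates[i, , drop = FALSE]
}

#' Create an empty scene memory
#'
#' The scene memory holds a single remembered count of visible sites
#' (`sum`) and the step at which it was stored (`stored_at`); both are `NA`
#' while empty.
#'
#' @return A list with fields `sum` and `stored_at`, class `"scene_memory"`.
#' @export
scene_memory <- function() {
  structure(list(sum = NA_integer_, stored_at = NA_integer_),
            class = "scene_memory")
}

#' Update the scene memory and possibly switch rules
#'
#' Implements the scene-memory step of the rule-change model, called only on
#' steps where at least one site is visible (`n_local >= 1`):
#'
#' * If the memory is empty, or expired (`step - stored_at > theta`), the
#'   current count is stored and no comparison is made this step.
#' * Otherwise, if `n_local` equals the remembered count, the active rule is
#'   swapped with probability `switch_prob` (one uniform draw, consumed only
#'   when a match occurs and `switch_prob > 0`). The memory is retained
#'   after a match; only expiry clears it.
#' * A differing count changes nothing.
#'
#' @param memory A [scene_memory()].
#' @param rule Active rule, `"exploitation"` or `"exploration"`.
#' @param n_local Number of currently visible sites (>= 1).
#' @param step Current step index.
#' @param theta Memory lifetime in steps.
#' @param switch_prob Rule-swap probability on a match.
#' @return A list with elements `memory` (updated), `rule` (possibly
#'   swapped) and `switched` (logical).
#' @examples
#' m <- scene_memory()
#' update_scene_memory(m, "exploitation", n_local = 3, step = 1,
#'                     theta = 5, switch_prob = 0.5)
#' @export
update_scene_memory <- function(memory, rule, n_local, step, theta, switch_prob) {
  if (n_local < 1)
    stop("scene memory is neither stored nor compared when no site is perceived",
         call. = FALSE)
  if (is.na(memory$sum) || (step - memory$stored_at) > theta) {
    memory$sum <- as.integer(n_local)
    memory$stored_at <- as.integer(step)
    return(list(memory = memory, rule = rule, switched = FALSE))
  }
  if (n_local == memory$sum && switch_prob > 0 && runif(1) < switch_prob) {
    return(list(memory = memory, rule = other_rule(rule), switched = TRUE))
  }
  list(memory = memory, rule = rule, switched = FALSE)
}
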