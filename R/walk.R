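# One uniform draw -> index in 1:k. Shared convention with the C++ engine
# (floor(u * k), clamped), so both consume the RNG stream identically.
draw_index <- function(k) {
  min(k, floor(runif(1) * k) + 1)
}

# Mirror a coordinate back inside [0, upper] (single reflection; valid while
# step_size <= upper, which validation guarantees for sane configs).
reflect_coord <- function(v, upper) {
  if (v < 0) return(-v)
  if (v > upper) return(2 * upper - v)
  v
}

#' Random cardinal step
#'
#' Moves the agent by `step_size` in one of the four cardinal directions
#' (north, east, south, west — in that draw order), each with probability
#' 1/4, consuming exactly one uniform draw. A coordinate that would leave
#' the field is reflected back inside (default) or clamped at the wall.
#' This is the fallback movement used on steps where no site is visible.
#'
#' @param position Numeric `c(x, y)` inside the field.
#' @param step_size Step length (> 0).
#' @param field_width,field_height Field extent.
#' @param boundary `"reflect"` or `"clamp"`.
#' @return The new position, guaranteed in bounds.
#' @examples
#' set.seed(1)
#' random_cardinal_step(c(50, 50), 1, 100, 100)
#' @export
random_cardinal_step <- function(position, step_size, field_width, field_height,
                                 boundary = c("reflect", "clamp")) {
  boundary <- match.arg(boundary)
  dir <- draw_index(4)
  x <- position[1]
  y <- position[2]
  if (dir == 1) y <- y + step_size
  else if (dir == 2) x <- x + step_size
  else if (dir == 3) y <- y - step_size
  else x <- x - step_size
  if (boundary == "reflect") {
    x <- reflect_coord(x, field_width)
    y <- reflect_coord(y, field_height)
  } else {
    x <- min(max(x, 0), field_width)
    y <- min(max(y, 0), field_height)
  }
  c(x, y)
}
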