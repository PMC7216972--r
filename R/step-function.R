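#' Right-continuous step functions
#'
#' Lightweight container for right-continuous piecewise-constant functions
#' over ordered knots, used throughout the package to carry hazard
#' increments, the censoring survival curve and reduction-factor estimates.
#' Unlike [stats::stepfun()], evaluation at the left limit `f(t-)` is a
#' first-class operation, which the censoring-weight construction needs.
#'
#' @param knots strictly increasing numeric vector of jump locations.
#' @param values function value at and after each knot (right-continuous).
#' @param left_value value before the first knot.
#' @return An object of class `"step_function"`.
#' @examples
#' G <- step_function(c(1, 3), c(2/3, 0))
#' eval_step(G, c(0.5, 1, 2, 3))
#' eval_step(G, 1, side = "left")  # left limit: 1
#' @export
step_function <- function(knots, values, left_value = 1) {
  stopifnot(is.numeric(knots), is.numeric(values),
            length(knots) == length(values))
  if (length(knots) > 1 && any(diff(knots) <= 0))
    stop("'knots' must be strictly increasing")
  structure(list(knots = as.numeric(knots), values = as.numeric(values),
                 left_value = as.numeric(left_value)),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t numeric vector of evaluation times.
#' @param side `"right"` for the right-continuous value `f(t)`, `"left"` for
#'   the left limit `f(t-)`.
#' @return Numeric vector of the same length as `t`.
#' @export
eval_step <- function(f, t, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(f, "step_function"))
  idx <- findInterval(t, f$knots,
                      left.open = (side == "left"))
  c(f$left_value, f$values)[idx + 1L]
}

#' @export
print.step_function <- function(x, ...) {
  cat("Step function with", length(x$knots), "knots\n")
  cat("  left value:", format(x$left_value), "\n")
  n <- min(6L, length(x$knots))
  if (n > 0)
    print(data.frame(knot = x$knots[seq_len(n)], value = x$values[seq_len(n)]))
  if (length(x$knots) > n) cat("  ...\n")
  invisible(x)
}

#' Cumulate step-function increments
#'
#' Turns a step function whose `values` are increments (e.g. hazard
#' increments at event times) into the corresponding cumulative step
#' function, starting at 0.
#'
#' @param f a [step_function()] carrying increments.
#' @return A [step_function()] carrying the running sum, with `left_value` 0.
#' @export
cumulate_step <- function(f) {
  stopifnot(inherits(f, "step_function"))
  step_function(f$knots, cumsum(f$values), left_value = 0)
}

#' Write a step function to CSV
#'
#' Two-column CSV (`time`, `value`), one row per knot, preceded by a row at
#' time 0 holding the left value (omitted when the first knot is 0).
#'
#' @param f a [step_function()].
#' @param path output file path.
#' @export
write_step_csv <- function(f, path) {
  stopifnot(inherits(f, "step_function"))
  d <- data.frame(time = f$knots, value = f$values)
  if (length(f$knots) == 0 || f$knots[1] > 0)
    d <- rbind(data.frame(time = 0, value = f$left_value), d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
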