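#' Construct a logarithmic size-class grid
#'
#' Builds the discrete carbon-quota grid on which the matrix population model
#' operates. Class boundaries are \eqn{v_i = v_1 2^{(i-1)\Delta v}} for
#' \eqn{i = 1, \dots, m+1}, cells in class \eqn{i} are assigned the geometric
#' mean size \eqn{\bar v_i = \sqrt{v_i v_{i+1}}}, and division shifts a cell
#' down by exactly \eqn{1/\Delta v} classes (a halving), so the smallest class
#' that can divide is \eqn{j = 1/\Delta v + 1} with \eqn{v_j = 2 v_1}.
#'
#' @param v1 minimum cell size (fg C), positive.
#' @param delta_v log2 class width; \code{1/delta_v} must be a positive integer.
#' @param m number of size classes; must be at least \code{1/delta_v + 1} so
#'   that at least one class can divide.
#' @return An object of class \code{"size_grid"}: a list with elements
#'   \code{v1}, \code{delta_v}, \code{m}, \code{j}, \code{boundaries}
#'   (length \code{m + 1}) and \code{midpoints} (length \code{m}).
#' @examples
#' g <- size_grid(16, 1 / 8, 27)
#' g$boundaries[g$j] # == 32, twice the minimum size
#' @export
size_grid <- function(v1 = 16, delta_v = 1 / 8, m = 27) {
  if (!is.numeric(v1) || length(v1) != 1L || v1 <= 0) {
    stop("`v1` must be a single positive size (fg C)", call. = FALSE)
  }
  inv <- 1 / delta_v
  if (!is.finite(inv) || abs(inv - round(inv)) > 1e-8 || inv < 1) {
    stop("1/delta_v must be a positive integer (division shifts 1/delta_v classes)",
      call. = FALSE
    )
  }
  inv <- round(inv)
  j <- inv + 1L
  if (m < j) {
    stop(sprintf(
      "m = %d is too small: need m >= 1/delta_v + 1 = %d so some class can divide",
      m, j
    ), call. = FALSE)
  }
  boundaries <- v1 * 2^((seq_len(m + 1L) - 1) * delta_v)
  midpoints <- sqrt(boundaries[-(m + 1L)] * boundaries[-1L])
  structure(
    list(
      v1 = v1, delta_v = delta_v, m = as.integer(m), j = as.integer(j),
      boundaries = boundaries, midpoints = midpoints
    ),
    class = "size_grid"
  )
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf(
    "Size-class grid: m = %d classes, v1 = %g fg C, delta_v = 1/%d\n",
    x$m, x$v1, round(1 / x$delta_v)
  ))
  cat(sprintf(
    "  boundaries %g .. %g fg C; smallest dividing class j = %d (v_j = %g fg C)\n",
    x$boundaries[1], x$boundaries[x$m + 1L], x$j, x$boundaries[x$j]
  ))
  invisible(x)
}

#' Map cell sizes to size-class indices
#'
#' Uses the half-open convention \eqn{v_i \le x < v_{i+1}}. Sizes below the
#' first boundary or at/above the last are counted into the end classes
#' (with a warning), since cells observed outside the grid still belong to
#' the population.
#'
#' @param grid a \code{\link{size_grid}}.
#' @param x numeric vector of cell sizes (fg C).
#' @return integer vector of 1-based class indices.
#' @export
class_of <- function(grid, x) {
  stopifnot(inherits(grid, "size_grid"))
  idx <- findInterval(x, grid$boundaries, left.open = FALSE)
  n_low <- sum(idx < 1L)
  n_high <- sum(idx > grid$m)
  if (n_low + n_high > 0L) {
    warning(sprintf(
      "%d size(s) below v_1 and %d at/above v_{m+1} assigned to end classes",
      n_low, n_high
    ), call. = FALSE)
  }
  pmin(pmax(idx, 1L), grid$m)
}
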