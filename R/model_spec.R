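#' Parse a three-letter model name into a model specification
#'
#' Models are named by three letters giving the carbon-fixation, division and
#' carbon-loss parameterizations, in that order:
#' \describe{
#'   \item{fixation}{\code{b} basic (size-independent), \code{p} power-law
#'     size dependence, \code{f} free per-class rates}
#'   \item{division}{\code{m} monotone in size and time-invariant, \code{t}
#'     monotone in size with a periodic time-of-day modulation}
#'   \item{loss}{\code{x} none, \code{b} basic (size-independent), \code{f}
#'     free per-class rates}
#' }
#' so e.g. \code{"bmx"} is the simplest model and \code{"ftf"} the richest.
#' All 18 combinations are valid.
#'
#' @param name three-letter model name, e.g. \code{"bmb"}.
#' @param dt projection step length in hours; \code{1/dt} must be a positive
#'   integer (steps tile whole hours).
#' @return An object of class \code{"mpm_spec"} with elements \code{fixation}
#'   (\code{"basic"}, \code{"power"}, \code{"free"}), \code{division}
#'   (\code{"monotone"}, \code{"timedep"}), \code{loss} (\code{"none"},
#'   \code{"basic"}, \code{"free"}), \code{dt} and \code{name}.
#' @examples
#' model_spec("ftf")
#' format(model_spec("pmb")) # round-trips to "pmb"
#' @export
model_spec <- function(name = "bmb", dt = 1 / 3) {
  if (!is.character(name) || length(name) != 1L || nchar(name) != 3L) {
    stop("model name must be a single three-letter string like \"bmb\"", call. = FALSE)
  }
  letters3 <- strsplit(name, "")[[1]]
  fixation <- switch(letters3[1],
    b = "basic", p = "power", f = "free",
    stop(sprintf("unknown fixation code '%s' (use b, p or f)", letters3[1]), call. = FALSE)
  )
  division <- switch(letters3[2],
    m = "monotone", t = "timedep",
    stop(sprintf("unknown division code '%s' (use m or t)", letters3[2]), call. = FALSE)
  )
  loss <- switch(letters3[3],
    x = "none", b = "basic", f = "free",
    stop(sprintf("unknown loss code '%s' (use x, b or f)", letters3[3]), call. = FALSE)
  )
  inv <- 1 / dt
  if (!is.finite(inv) || abs(inv - round(inv)) > 1e-8 || inv < 1) {
    stop("1/dt must be a positive integer (whole steps per hour)", call. = FALSE)
  }
  structure(
    list(
      fixation = fixation, division = division, loss = loss,
      dt = dt, name = name
    ),
    class = "mpm_spec"
  )
}

#' @export
format.mpm_spec <- function(x, ...) {
  paste0(
    substr(x$fixation, 1, 1),
    if (x$division == "monotone") "m" else "t",
    if (x$loss == "none") "x" else substr(x$loss, 1, 1)
  )
}

#' @export
print.mpm_spec <- function(x, ...) {
  cat(sprintf(
    "MPM specification m_%s: %s carbon fixation, %s division, %s carbon loss; dt = %s h\n",
    format(x), x$fixation, x$division,
    if (x$loss == "none") "no" else x$loss,
    format(x$dt)
  ))
  invisible(x)
}

#' All 18 model names of the fixation x division x loss grammar
#' @return character vector of the 18 three-letter model names.
#' @export
all_model_names <- function() {
  as.vector(outer(
    c("b", "p", "f"),
    as.vector(outer(c("m", "t"), c("x", "b", "f"), paste0)),
    paste0
  ))
}
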