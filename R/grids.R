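#' Temperature grids
#'
#' The LiP-MS thermal gradient and the derived prediction grids.
#'
#' `lip_grid()` returns the ten incubation temperatures of the thermal
#' gradient (37--76 degrees C).  `scoring_grid()` is the dense grid used to
#' integrate the area between condition curves (default 0.5 degree step);
#' `clustering_grid()` is the 20-point grid (2 degree increments, 37--75
#' degrees C) on which fitted profiles are clustered.
#'
#' @param step grid spacing in degrees C (scoring grid only).
#' @return numeric vector of temperatures in degrees C, strictly increasing.
#' @examples
#' lip_grid()
#' length(clustering_grid())
#' @export
lip_grid <- function() {
  c(37, 40.5, 44.4, 49.3, 54.1, 58.9, 63.8, 68.6, 72.5, 76)
}

#' @rdname lip_grid
#' @export
scoring_grid <- function(step = 0.5) {
  stopifnot(step > 0)
  seq(37, 76, by = step)
}

#' @rdname lip_grid
#' @export
clustering_grid <- function() {
  seq(37, 75, by = 2)
}

# Validate a temperature grid: numeric, strictly increasing, >= 4 points
# (minimum for any curve fit).
check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 4L) {
    stop("temperature grid must be numeric with at least 4 points")
  }
  if (any(diff(grid) <= 0)) stop("temperature grid must be strictly increasing")
  invisible(grid)
}
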