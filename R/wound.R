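#' Wound-healing time series
#'
#' @param times hours, strictly increasing, starting at 0
#' @param wound_area wound area in pixels at each time
#' @return object of class `wound_series`
#' @export
wound_series <- function(times, wound_area) {
  stopifnot(length(times) == length(wound_area),
            times[1] == 0, all(diff(times) > 0),
            wound_area[1] > 0, all(wound_area >= 0))
  structure(list(times = times, wound_area = wound_area,
                 initial_wound_area = wound_area[1]),
            class = "wound_series")
}

#' Relative wound density
#'
#' Percentage of the original wound area reclaimed by migrating cells:
#' `RWD(t) = 100 * (W0 - W(t)) / W0`, clamped to \[0, 100\]. Cell retraction
#' (`W(t) > W0`) clamps to 0 with a warning.
#'
#' @param series a [wound_series()]
#' @return numeric vector of RWD percentages, one per time point
#' @export
relative_wound_density <- function(series) {
  stopifnot(inherits(series, "wound_series"))
  w0 <- series$initial_wound_area
  rwd <- 100 * (w0 - series$wound_area) / w0
  if (any(rwd < 0))
    warning("wound area above initial (cell retraction): RWD clamped to 0")
  pmin(pmax(rwd, 0), 100)
}

#' Time to 50% wound closure
#'
#' First crossing of RWD = 50, by linear interpolation between the adjacent
#' time points; `NA` ("not reached") when RWD stays below 50 throughout.
#'
#' @param series a [wound_series()]
#' @param level crossing level in percent (default 50)
#' @return hours to the crossing, or `NA_real_`
#' @export
time_to_half <- function(series, level = 50) {
  rwd <- relative_wound_density(series)
  t <- series$times
  if (max(rwd) < level) return(NA_real_)
  i <- which(rwd >= level)[1]
  if (i == 1) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (level - rwd[i - 1]) / (rwd[i] - rwd[i - 1])
}

#' Anti-migratory effectiveness call
#'
#' A treatment is called effective when the treated culture's RWD at the
#' assay horizon is at or below the cut-off (boundary inclusive): migration
#' was held to no more than `cut` percent closure.
#'
#' @param series treated-condition [wound_series()]
#' @param cut RWD cut-off in percent (default 50)
#' @param horizon assay horizon in hours (must be within the series)
#' @return logical
#' @export
effectiveness_call <- function(series, cut = 50, horizon = max(series$times)) {
  stopifnot(horizon >= min(series$times), horizon <= max(series$times))
  rwd <- relative_wound_density(series)
  at <- stats::approx(series$times, rwd, xout = horizon)$y
  at <= cut
}
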