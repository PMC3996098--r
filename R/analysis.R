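# Diagnostic observables extracted from protocol runs: the recovery curve at
# the sub-lesion skin point P, temperature profiles along the heel periphery,
# and lesion-minus-healthy temperature differences.

#' Recovery curve at the sub-lesion skin point
#'
#' Temperature of the skin point P on the symmetry axis (directly below the
#' lesion centre) as a function of time, linearly interpolated along the
#' skin arc at the requested arc coordinate. Times are on the recovery
#' clock: cooling at negative times, `t = 0` at cooling removal.
#'
#' @param result a `recovery_result` from [run_protocol()]
#' @param l_mm arc coordinate of the probe point (default: the apex, i.e.
#'   half the total arc length)
#' @return data frame with columns `t_s` and `T_C`
#' @export
point_curve <- function(result, l_mm = NULL) {
  if (is.null(result$skin)) stop("result holds no transient snapshots")
  lv <- result$skin$l_mm
  if (is.null(l_mm)) l_mm <- (lv[1] + lv[length(lv)]) / 2
  if (l_mm < lv[1] || l_mm > lv[length(lv)])
    stop("probe point outside the skin arc")
  w <- .arc_weights(lv, l_mm)
  data.frame(t_s = result$skin$times,
             T_C = result$skin$T[, w$i] * (1 - w$f) + result$skin$T[, w$i + 1] * w$f)
}

.arc_weights <- function(lv, l) {
  i <- findInterval(l, lv, rightmost.closed = TRUE, all.inside = TRUE)
  list(i = i, f = (l - lv[i]) / (lv[i + 1] - lv[i]))
}

#' Skin-surface temperature profile
#'
#' Temperature along the heel periphery at a requested instant, sampled at
#' every skin boundary node and ordered by arc coordinate. `t = "steady"`
#' returns the pre-cooling steady profile; numeric times (recovery clock,
#' seconds) are linearly interpolated between stored snapshots.
#'
#' @param result a `recovery_result`
#' @param t `"steady"` or a time in seconds on the recovery clock
#' @return data frame with columns `l_mm` and `T_C`
#' @export
surface_profile <- function(result, t = "steady") {
  lv <- if (!is.null(result$skin)) result$skin$l_mm else
    result$mesh$skin_l * 1e3
  if (identical(t, "steady")) {
    return(data.frame(l_mm = lv, T_C = result$steady[result$mesh$skin_nodes]))
  }
  if (is.null(result$skin)) stop("result holds no transient snapshots")
  tv <- result$skin$times
  if (t < tv[1] || t > tv[length(tv)]) stop("t outside the simulated window")
  i <- findInterval(t, tv, rightmost.closed = TRUE, all.inside = TRUE)
  f <- if (tv[i + 1] > tv[i]) (t - tv[i]) / (tv[i + 1] - tv[i]) else 0
  data.frame(l_mm = lv, T_C = result$skin$T[i, ] * (1 - f) + result$skin$T[i + 1, ] * f)
}

#' Lesion-minus-healthy temperature difference
#'
#' Pointwise difference between two runs. With `at = "P"` (default) the
#' result is the time series of `T_dti - T_healthy` at the sub-lesion point;
#' with a numeric `at` it is the profile-wise difference along the skin arc
#' at that recovery time (or at steady state with `at = "steady"`).
#'
#' @param result_dti,result_healthy `recovery_result`s on the same mesh
#' @param at `"P"`, `"steady"`, or a recovery time in seconds
#' @param l_mm probe arc coordinate when `at = "P"`
#' @return data frame: `t_s`/`delta_C` for `at = "P"`, else `l_mm`/`delta_C`
#' @export
delta_series <- function(result_dti, result_healthy, at = "P", l_mm = NULL) {
  .check_same_arc(result_dti, result_healthy)
  if (identical(at, "P")) {
    a <- point_curve(result_dti, l_mm)
    b <- point_curve(result_healthy, l_mm)
    if (!isTRUE(all.equal(a$t_s, b$t_s))) {
      tt <- sort(intersect(a$t_s, b$t_s))
      a <- a[match(tt, a$t_s), ]; b <- b[match(tt, b$t_s), ]
    }
    return(data.frame(t_s = a$t_s, delta_C = a$T_C - b$T_C))
  }
  a <- surface_profile(result_dti, at)
  b <- surface_profile(result_healthy, at)
  data.frame(l_mm = a$l_mm, delta_C = a$T_C - b$T_C)
}

.check_same_arc <- function(a, b) {
  la <- if (!is.null(a$skin)) a$skin$l_mm else a$mesh$skin_l * 1e3
  lb <- if (!is.null(b$skin)) b$skin$l_mm else b$mesh$skin_l * 1e3
  if (length(la) != length(lb) || max(abs(la - lb)) > 1e-9 ||
      !identical(dim(a$mesh$nodes), dim(b$mesh$nodes)) ||
      max(abs(a$mesh$nodes - b$mesh$nodes)) > 0)
    stop("analysis error: results use different meshes")
  invisible(TRUE)
}

#' Extremum of a temperature-difference profile
#'
#' The signed value of largest magnitude along the profile and its arc
#' location; ties are broken toward the smaller arc coordinate.
#'
#' @param delta_profile data frame with `l_mm` and `delta_C`
#' @return list with `l_mm` and `delta_C`
#' @export
profile_extremum <- function(delta_profile) {
  i <- which.max(abs(delta_profile$delta_C))  # which.max returns first tie
  list(l_mm = delta_profile$l_mm[i], delta_C = delta_profile$delta_C[i])
}

#' Extreme skin temperature difference over a recovery window
#'
#' Scans the stored skin snapshots of two matched runs over a recovery-time
#' window and returns the most positive (or most negative) value of
#' `T_dti - T_healthy` over the whole skin arc, with its time and location.
#'
#' @param result_dti,result_healthy matched `recovery_result`s
#' @param t_min,t_max window on the recovery clock, s
#' @param sign `"max"` for the largest increase, `"min"` for the largest
#'   decrease
#' @return list with `delta_C`, `t_s`, `l_mm`
#' @export
window_extremum <- function(result_dti, result_healthy, t_min = 0, t_max = 300,
                            sign = c("max", "min")) {
  sign <- match.arg(sign)
  .check_same_arc(result_dti, result_healthy)
  ta <- result_dti$skin$times
  sel <- which(ta >= t_min & ta <= t_max)
  if (!length(sel)) stop("empty time window")
  D <- result_dti$skin$T[sel, , drop = FALSE] -
    result_healthy$skin$T[sel, , drop = FALSE]
  idx <- if (sign == "max") which.max(D) else which.min(D)
  rc <- arrayInd(idx, dim(D))
  list(delta_C = D[idx], t_s = ta[sel[rc[1]]],
       l_mm = result_dti$skin$l_mm[rc[2]])
}

#' Write analysis outputs as CSV
#'
#' Writes a recovery curve, profile or delta series with fixed column
#' headers (`t_s`, `T_C`, `l_mm`, `delta_C`) to `path`.
#'
#' @param x data frame produced by the analysis functions
#' @param path output file
#' @return `path`, invisibly
#' @export
write_analysis_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
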