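#' Inflow curve container
#'
#' A time series of one scalar inflow quantity per cardiac frame: maximum
#' through-plane velocity (cm/s), volumetric flow rate (mL/s), or maximum LV
#' speed (cm/s).
#'
#' @param times Frame times, ms, strictly increasing.
#' @param values Curve values; same length as `times`. Flow-rate curves may
#'   be negative.
#' @param kind One of `"max_velocity"`, `"flow_rate"`, `"lv_max_speed"`.
#' @return An object of class `inflow_curve`.
#' @export
inflow_curve <- function(times, values,
                         kind = c("max_velocity", "flow_rate", "lv_max_speed")) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) abort("times and values lengths differ")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (anyNA(values) || !all(is.finite(values))) abort("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind),
            class = "inflow_curve")
}

#' @export
print.inflow_curve <- function(x, ...) {
  cat(sprintf("<inflow_curve:%s> %d frames, range [%.2f, %.2f] %s\n",
              x$kind, length(x$times), min(x$values), max(x$values),
              curve_units(x$kind)))
  invisible(x)
}

curve_units <- function(kind) if (kind == "flow_rate") "mL/s" else "cm/s"

#' @describeIn inflow_curve Curve as a tibble with `time_ms` and `value`.
#' @param x An `inflow_curve`.
#' @param ... Unused.
#' @export
as_tibble.inflow_curve <- function(x, ...) {
  tibble(time_ms = x$times, value = x$values, kind = x$kind)
}

#' @export
tidy.inflow_curve <- function(x, ...) as_tibble.inflow_curve(x)

#' Write an inflow curve as CSV (`time_ms,value`)
#' @param curve An `inflow_curve`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_inflow_curve <- function(curve, path) {
  utils::write.csv(data.frame(time_ms = curve$times, value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

# base of the peak on one side: minimum between the peak and the nearest
# strictly higher sample (or the window edge)
peak_side_base <- function(v, i, step) {
  j <- i + step
  base <- v[i]
  while (j >= 1 && j <= length(v) && v[j] <= v[i]) {
    base <- min(base, v[j])
    j <- j + step
  }
  base
}

peak_prominence <- function(v, i) {
  v[i] - max(peak_side_base(v, i, -1L), peak_side_base(v, i, 1L))
}

# indices of local maxima, plateaus collapsed to their first sample; window
# edges are never maxima
local_maxima <- function(v) {
  r <- rle(v)
  n_runs <- length(r$values)
  if (n_runs < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-n_runs]))
  keep <- which(r$values[2:(n_runs - 1)] > r$values[1:(n_runs - 2)] &
                  r$values[2:(n_runs - 1)] > r$values[3:n_runs]) + 1L
  starts[keep]
}

#' Detect the E and A peaks of a diastolic inflow curve
#'
#' Restricts the curve to a diastolic window, finds local maxima (samples
#' strictly greater than both neighbours, plateaus collapsing to their first
#' sample), discards maxima whose prominence is below a fraction of the
#' window maximum, and selects the two largest remaining peaks: E is the
#' earlier, A the later. If fewer than two peaks survive, the inflow is
#' flagged as fused (monophasic) — the situation in which E and A cannot be
#' discerned, typically at high heart rate — and the peak fields are unset.
#'
#' Ties are resolved reproducibly: candidates are ranked by value, then by
#' prominence, then by earlier time.
#'
#' @param curve An [inflow_curve()].
#' @param diastole_window `"auto"` or a numeric `c(start_ms, end_ms)`. The
#'   automatic window runs from the first sample at or after cycle fraction
#'   `start_frac` at which the curve is positive, to the last frame.
#' @param min_prominence_frac Prominence floor as a fraction of the window
#'   maximum.
#' @param start_frac Cycle fraction at which diastole is assumed to begin for
#'   the automatic window.
#' @return A `peak_pair`: `e_value`, `a_value`, `e_time`, `a_time`,
#'   `ea_ratio`, `fused`, `diastole_window`, and the curve `kind`.
#' @export
detect_ea_peaks <- function(curve, diastole_window = "auto",
                            min_prominence_frac = 0.1, start_frac = 0.35) {
  times <- curve$times
  values <- curve$values
  if (identical(diastole_window, "auto")) {
    period <- infer_period(times)
    cand <- which(times >= start_frac * period & values > 0)
    if (length(cand) == 0) {
      warn("no positive inflow in the automatic diastole window; flagging fused")
      return(fused_pair(curve, c(NA_real_, NA_real_)))
    }
    idx <- cand[1]:length(times)
  } else {
    if (!is.numeric(diastole_window) || length(diastole_window) != 2)
      abort("diastole_window must be \"auto\" or c(start_ms, end_ms)")
    idx <- which(times >= diastole_window[1] & times <= diastole_window[2])
  }
  if (length(idx) < 5)
    abort("diastole window holds fewer than 5 samples")
  w <- values[idx]
  tw <- times[idx]
  window <- c(tw[1], tw[length(tw)])
  if (max(w) == min(w)) {
    warn("flat curve in the diastole window; flagging fused")
    return(fused_pair(curve, window))
  }
  peaks <- local_maxima(w)
  if (length(peaks) > 0) {
    prom <- vapply(peaks, function(i) peak_prominence(w, i), numeric(1))
    keep <- prom >= min_prominence_frac * max(w)
    peaks <- peaks[keep]; prom <- prom[keep]
  }
  if (length(peaks) < 2) return(fused_pair(curve, window))
  ord <- order(-w[peaks], -prom, tw[peaks])
  two <- peaks[ord[1:2]]
  e_i <- min(two); a_i <- max(two)
  structure(list(e_value = w[e_i], a_value = w[a_i],
                 e_time = tw[e_i], a_time = tw[a_i],
                 ea_ratio = w[e_i] / w[a_i],
                 fused = FALSE, diastole_window = window, kind = curve$kind),
            class = "peak_pair")
}

fused_pair <- function(curve, window) {
  structure(list(e_value = NA_real_, a_value = NA_real_,
                 e_time = NA_real_, a_time = NA_real_, ea_ratio = NA_real_,
                 fused = TRUE, diastole_window = window, kind = curve$kind),
            class = "peak_pair")
}

#' @export
print.peak_pair <- function(x, ...) {
  if (x$fused) {
    cat("<peak_pair> fused (monophasic inflow) - E/A not measurable\n")
  } else {
    cat(sprintf(
      "<peak_pair:%s> E %.2f @ %.0f ms, A %.2f @ %.0f ms, E/A %.3f\n",
      x$kind, x$e_value, x$e_time, x$a_value, x$a_time, x$ea_ratio))
  }
  invisible(x)
}

#' @export
tidy.peak_pair <- function(x, ...) {
  tibble(kind = x$kind, e_value = x$e_value, a_value = x$a_value,
         e_time = x$e_time, a_time = x$a_time, ea_ratio = x$ea_ratio,
         fused = x$fused,
         window_start = x$diastole_window[1],
         window_end = x$diastole_window[2])
}

#' Write a peak pair as JSON
#' @param pair A `peak_pair`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_peak_pair <- function(pair, path) {
  jsonlite::write_json(unclass(pair), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
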