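# CV-over-window steady-state flagging.
#
# The criterion: a window is steady when it spans at least `window_span`
# hydraulic retention times, holds at least three samples, and the
# coefficient of variation of every tracked broth compound over the window
# is at most `max_cv`. The rule is deliberately configurable because
# published steady-state definitions for these reactors vary.

#' Steady-state criteria
#'
#' @param window_span minimal window length in multiples of the HRT.
#' @param max_cv maximal relative standard deviation of each tracked
#'   compound over the window (0 < max_cv < 1).
#' @param tracked compounds whose stability is required.
#' @return An object of class `steady_state_criteria`.
#' @export
steady_state_criteria <- function(window_span = 3, max_cv = 0.10,
                                  tracked = c("n-caproate", "n-butyrate",
                                              "acetate", "ethanol",
                                              "hexanol", "butanol")) {
  if (window_span <= 0) stop("window_span must be positive", call. = FALSE)
  if (max_cv <= 0 || max_cv >= 1) stop("max_cv must lie in (0, 1)", call. = FALSE)
  structure(list(window_span = window_span, max_cv = max_cv,
                 tracked = tracked), class = "steady_state_criteria")
}

# CV with a guard for identically-zero signals (steady by definition)
.cv <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (m <= .Machine$double.eps) {
    if (s <= .Machine$double.eps) 0 else Inf
  } else {
    s / m
  }
}

#' Detect steady-state windows in a reactor time series
#'
#' Slides a trailing window over the samples: sample i is flagged steady
#' when the window `[t_i - window_span * HRT_i, t_i]` holds at least three
#' samples and every tracked compound's coefficient of variation within it
#' is at most `max_cv`. Consecutive flagged samples are merged into maximal
#' steady intervals. Detection is invariant to a uniform rescaling of all
#' concentrations, and tightening `max_cv` can only shrink the steady set.
#'
#' @param ts a [reactor_timeseries()] (needs feed and base flows to compute
#'   the HRT).
#' @param criteria a [steady_state_criteria()].
#' @return A list: `flags` (logical per sample) and `intervals` (data frame
#'   `start`, `end`, `n_samples` of maximal steady stretches).
#' @export
detect_steady_state <- function(ts, criteria = steady_state_criteria()) {
  t0 <- ts$broth$time
  flows <- ts$scalars$feed_flow + ts$scalars$base_flow
  if (anyNA(flows) || any(flows <= 0)) {
    stop("cannot compute the HRT: feed/base flows missing or non-positive",
         call. = FALSE)
  }
  hrt_d <- hydraulic_retention_time(ts$volume, ts$scalars$feed_flow,
                                    ts$scalars$base_flow) / 24
  tracked <- intersect(resolve_compound(criteria$tracked),
                       setdiff(names(ts$broth), "time"))
  conc <- as.matrix(ts$broth[tracked])

  flags <- vapply(seq_along(t0), function(i) {
    span <- criteria$window_span * hrt_d[i]
    if (t0[i] - t0[1] < span) return(FALSE)  # series cannot span the window yet
    win <- which(t0 >= t0[i] - span & t0 <= t0[i])
    if (length(win) < 3) return(FALSE)
    all(apply(conc[win, , drop = FALSE], 2, .cv) <= criteria$max_cv)
  }, logical(1))

  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  intervals <- data.frame(start = t0[starts[keep]], end = t0[ends[keep]],
                          n_samples = runs$lengths[keep])
  list(flags = flags, intervals = intervals)
}
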