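#' Construct a lick session
#'
#' A lick session is the behavioral substrate of the analysis: a sorted
#' vector of lick timestamps from one recording session, plus metadata
#' identifying the mouse, the recorded region and the behavioral condition.
#'
#' @param lick_times_s Numeric vector of lick times in seconds, strictly
#'   increasing, all within `[0, session_duration_s]`.
#' @param session_duration_s Session length in seconds (default 1800, a
#'   30-min session).
#' @param mouse_id Identifier for the animal.
#' @param region Recording target, one of `"PVH"`, `"VMH"` or `"none"`
#'   (behavior-only sessions).
#' @param condition Behavioral condition, one of `"Restricted"`, `"Light"`,
#'   `"Dark"`, `"Sucralose"`.
#' @return An object of class `lick_session`.
#' @export
lick_session <- function(lick_times_s, session_duration_s = 1800,
                         mouse_id = "m1", region = "none",
                         condition = "Restricted") {
  region <- match.arg(region, c("PVH", "VMH", "none"))
  condition <- match.arg(condition,
                         c("Restricted", "Light", "Dark", "Sucralose"))
  lick_times_s <- as.numeric(lick_times_s)
  if (!is.numeric(session_duration_s) || session_duration_s <= 0)
    stop("session_duration_s must be a positive number", call. = FALSE)
  if (length(lick_times_s)) {
    if (any(!is.finite(lick_times_s)))
      stop("lick times must be finite", call. = FALSE)
    if (any(diff(lick_times_s) <= 0))
      stop("lick times must be strictly increasing", call. = FALSE)
    if (lick_times_s[1] < 0 ||
        lick_times_s[length(lick_times_s)] > session_duration_s)
      stop("lick times must lie within [0, session_duration_s]",
           call. = FALSE)
  }
  structure(list(mouse_id = as.character(mouse_id), region = region,
                 condition = condition,
                 session_duration_s = as.numeric(session_duration_s),
                 lick_times_s = lick_times_s),
            class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf("<lick_session> mouse %s | %s | %s | %d licks in %.0f s\n",
              x$mouse_id, x$region, x$condition,
              length(x$lick_times_s), x$session_duration_s))
  invisible(x)
}

#' Detect lick bouts
#'
#' Partitions the lick train into maximal clusters whose internal
#' inter-lick intervals are all strictly below `gap_s`; an interval of
#' `gap_s` or more ("at least 10 s separating one bout from another")
#' splits clusters. Clusters with at least `min_licks` licks are returned
#' as bouts in time order; smaller clusters are discarded outright, never
#' merged into a neighbor.
#'
#' @param session A `lick_session`.
#' @param min_licks Minimum licks for a cluster to count as a bout
#'   (default 3).
#' @param gap_s Inter-lick interval that separates bouts, seconds
#'   (default 10).
#' @return A data.frame with one row per bout and columns `start_s`,
#'   `end_s`, `n_licks`, `duration_s`, of class `bout_table`.
#' @export
detect_bouts <- function(session, min_licks = 3, gap_s = 10) {
  stopifnot(inherits(session, "lick_session"))
  if (min_licks < 1 || gap_s <= 0)
    stop("min_licks must be >= 1 and gap_s > 0", call. = FALSE)
  t <- session$lick_times_s
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_licks = integer(0), duration_s = numeric(0))
  if (!length(t)) return(structure(empty, class = c("bout_table",
                                                    "data.frame")))
  # cluster ids advance at every inter-lick interval >= gap_s
  cl <- cumsum(c(1, as.integer(diff(t) >= gap_s)))
  starts <- tapply(t, cl, min)
  ends <- tapply(t, cl, max)
  n <- as.integer(tapply(t, cl, length))
  keep <- n >= min_licks
  out <- data.frame(start_s = as.numeric(starts[keep]),
                    end_s = as.numeric(ends[keep]),
                    n_licks = n[keep])
  out$duration_s <- out$end_s - out$start_s
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bout_table", "data.frame"))
}

#' Session-level lick microstructure summary
#'
#' Totals and means used for the behavior comparison across conditions:
#' total licks, bout count, mean bout length, and the intra-bout lick
#' frequency. Frequency is the number of inter-lick intervals inside bouts
#' divided by total bout duration, i.e.
#' `sum(n_licks - 1) / sum(duration_s)` over bouts, and 0 when the session
#' has no bouts.
#'
#' @param session A `lick_session`.
#' @param bouts Bout table from [detect_bouts()] on the same session.
#' @return A one-row data.frame with `total_licks`, `n_bouts`,
#'   `mean_bout_duration_s`, `lick_frequency_hz`.
#' @export
summarize_session <- function(session, bouts) {
  stopifnot(inherits(session, "lick_session"), is.data.frame(bouts))
  n_bouts <- nrow(bouts)
  if (n_bouts == 0) {
    return(data.frame(total_licks = length(session$lick_times_s),
                      n_bouts = 0L, mean_bout_duration_s = NA_real_,
                      lick_frequency_hz = 0))
  }
  multi <- bouts$n_licks >= 2
  tot_dur <- sum(bouts$duration_s[multi])
  freq <- if (tot_dur > 0) sum(bouts$n_licks[multi] - 1) / tot_dur else 0
  data.frame(total_licks = length(session$lick_times_s),
             n_bouts = n_bouts,
             mean_bout_duration_s = mean(bouts$duration_s),
             lick_frequency_hz = freq)
}
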