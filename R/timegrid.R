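#' Construct a longitudinal sampling grid
#'
#' A time grid describes when samples were drawn relative to the liver
#' resection: one preoperative baseline (hour 0, pre-resection), optionally
#' further pre-resection samples (e.g. a post-incision draw), and a strictly
#' increasing sequence of post-resection time points in hours.
#'
#' @param labels character vector of time-point names; the first entry is the
#'   baseline.
#' @param hours numeric vector of the same length, hours post-resection
#'   (baseline coded as 0 with a pre-resection flag).
#' @param pre_resection logical vector marking samples drawn before the
#'   resection itself; defaults to baseline only.
#' @return An object of class `time_grid` with fields `labels`, `hours`,
#'   `pre_resection`.
#' @examples
#' g <- time_grid(c("Before Surgery", "1 hour", "1 day"), c(0, 1, 24))
#' g$hours
#' @export
time_grid <- function(labels, hours, pre_resection = NULL) {
  if (length(labels) != length(hours))
    stop("labels and hours must have equal length")
  if (length(hours) < 3) stop("a time grid needs at least 3 points")
  if (is.null(pre_resection))
    pre_resection <- c(TRUE, rep(FALSE, length(hours) - 1L))
  if (!pre_resection[1L] || hours[1L] != 0)
    stop("the first grid point must be the hour-0 preoperative baseline")
  post <- hours[!pre_resection]
  if (length(post) < 2 || any(diff(post) <= 0) || any(post <= 0))
    stop("post-resection hours must be positive and strictly increasing")
  structure(list(labels = as.character(labels), hours = as.numeric(hours),
                 pre_resection = as.logical(pre_resection)),
            class = "time_grid")
}

#' The one-year follow-up grid used throughout the package
#'
#' Baseline plus 14 post-operative points: 5 and 30 minutes; 1--4 hours;
#' 1--4 and 10 days; 3, 6 and 12 months (one month = 730 h).
#'
#' @return A [time_grid()].
#' @export
default_time_grid <- function() {
  time_grid(
    labels = c("Before Surgery", "5 min", "30 min", "1 hour", "2 hours",
               "3 hours", "4 hours", "1 day", "2 days", "3 days", "4 days",
               "10 days", "3 months", "6 months", "12 months"),
    hours = c(0, 5 / 60, 0.5, 1, 2, 3, 4, 24, 48, 72, 96, 240,
              3 * 730, 6 * 730, 12 * 730))
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points (%d pre-resection), %s h to %s h\n",
              length(x$hours), sum(x$pre_resection),
              format(min(x$hours)), format(max(x$hours))))
  invisible(x)
}

# indices of post-resection samples
post_op_idx <- function(grid) which(!grid$pre_resection)

baseline_idx <- function(grid) 1L
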