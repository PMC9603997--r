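#' Construct a frame schedule
#'
#' @param starts numeric, frame start times in seconds (ascending, first 0).
#' @param durations numeric, frame durations in seconds (> 0).
#' @return A [FrameSchedule-class].
#' @examples
#' FrameSchedule(c(0, 30, 60), c(30, 30, 60))
#' @export
FrameSchedule <- function(starts, durations) {
  new("FrameSchedule", starts = as.numeric(starts),
      durations = as.numeric(durations))
}

#' The default 60-minute, 24-frame dynamic schedule
#'
#' Expands the acquisition protocol used throughout the package: frame
#' durations of 3 x 30, 5 x 60, 5 x 120, 3 x 180, 3 x 240, 4 x 300 and
#' 1 x 150 s — 24 contiguous frames totalling 3600 s (60 min).
#'
#' @return A [FrameSchedule-class] with 24 frames.
#' @examples
#' sched <- defaultFrameSchedule()
#' nFrames(sched)                 # 24
#' sum(frameDurations(sched))     # 3600 s
#' @export
defaultFrameSchedule <- function() {
  durations <- rep(c(30, 60, 120, 180, 240, 300, 150),
                   times = c(3L, 5L, 5L, 3L, 3L, 4L, 1L))
  starts <- c(0, cumsum(durations)[-length(durations)])
  FrameSchedule(starts, durations)
}

#' @describeIn FrameSchedule Number of frames.
#' @param x,object a `FrameSchedule`.
#' @export
nFrames <- function(x) length(x@starts)

#' @describeIn FrameSchedule Frame start times (seconds).
#' @export
frameStarts <- function(x) x@starts

#' @describeIn FrameSchedule Frame durations (seconds).
#' @export
frameDurations <- function(x) x@durations

#' @describeIn FrameSchedule Frame mid-times, `starts + durations/2`.
#' @param unit `"s"` or `"min"`.
#' @export
frameMidTimes <- function(x, unit = c("s", "min")) {
  unit <- match.arg(unit)
  mid <- x@starts + x@durations / 2
  if (unit == "min") mid / 60 else mid
}

#' @describeIn FrameSchedule Total scan duration (seconds).
#' @export
totalDuration <- function(x) sum(x@durations)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.1f min total\n",
              nFrames(object), totalDuration(object) / 60))
  rl <- rle(object@durations)
  cat("  durations:",
      paste(sprintf("%dx%gs", rl$lengths, rl$values), collapse = ", "), "\n")
})
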