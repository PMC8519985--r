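# Acquisition schedules of the two dynamic scans.

#' The 22-minute dynamic PET frame schedule
#'
#' 28 frames starting at injection: 11 of 10 s, 5 of 20 s, 4 of 40 s, 4 of
#' 60 s and 4 of 180 s, ending at 1330 s (22 min 10 s).
#'
#' @return A [FrameSchedule-class] with 28 contiguous frames.
#' @examples
#' nFrames(petFrameSchedule())
#' @export
petFrameSchedule <- function() {
    dur <- c(rep(10, 11), rep(20, 5), rep(40, 4), rep(60, 4), rep(180, 4))
    e <- cumsum(dur)
    FrameSchedule(c(0, e[-length(e)]), e)
}

#' The two-phase CT-perfusion sampling schedule
#'
#' Phase 1 samples every 2.8 s over the first minute (21 frames of 2.8 s,
#' ending 58.8 s); phase 2 every 15 s for the next two minutes (8 frames of
#' 15 s on (60, 180] s). A short gap separates the phases.
#'
#' @return A [FrameSchedule-class] with 29 frames, all ending by 180 s.
#' @export
ctpFrameSchedule <- function() {
    s1 <- seq(0, by = 2.8, length.out = 21)
    s2 <- seq(60, by = 15, length.out = 8)
    FrameSchedule(c(s1, s2), c(s1 + 2.8, s2 + 15))
}
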