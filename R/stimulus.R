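#' Construct a stimulus specification
#'
#' The default animation is the standard assay sequence: 5 s of solid
#' white (to score initial positions), 30 s of black-and-white bars moving
#' right-to-left, and a final 5 s of solid white (to score final
#' positions).  Bars have soft sinusoidal edges spanning 60 degrees of
#' spatial phase by default; a hard square-wave profile is available.
#' Defaults give 8 bar pairs across a 960 px canvas, comfortably more than
#' the 6 needed to span a 48-well plate footprint.
#'
#' @param barWidth bar width in px (spatial period = 2 * barWidth).
#' @param frameRate frames per second.
#' @param leadWhiteS,gratingS,tailWhiteS segment durations in seconds.
#' @param speed pattern speed in px/s; positive moves right-to-left.
#' @param profile \code{"sine"} (soft edges) or \code{"square"}.
#' @param edgeDeg transition width in degrees of phase (sine profile).
#' @return a \linkS4class{StimulusSpec}.
#' @export
stimulusSpec <- function(barWidth = 60, frameRate = 30, leadWhiteS = 5,
                         gratingS = 30, tailWhiteS = 5, speed = 120,
                         profile = c("sine", "square"), edgeDeg = 60) {
  new("StimulusSpec", barWidth = barWidth, frameRate = frameRate,
      leadWhiteS = leadWhiteS, gratingS = gratingS, tailWhiteS = tailWhiteS,
      speed = speed, profile = match.arg(profile), edgeDeg = edgeDeg)
}

#' Total duration and frame count of a stimulus
#'
#' @param spec a \linkS4class{StimulusSpec}.
#' @return \code{totalDuration}: seconds; \code{nFrames}: total frame
#'   count, \code{round(frameRate * total seconds)}.
#' @export
totalDuration <- function(spec) {
  spec@leadWhiteS + spec@gratingS + spec@tailWhiteS
}

#' @rdname totalDuration
#' @export
nFrames <- function(spec) {
  as.integer(round(spec@frameRate * totalDuration(spec)))
}

#' Segment of the animation at a given time
#'
#' @param spec a \linkS4class{StimulusSpec}.
#' @param t time(s) in seconds.
#' @return character vector: \code{"lead"}, \code{"grating"} or
#'   \code{"tail"}.
#' @export
segmentAt <- function(spec, t) {
  if (any(t < 0 | t > totalDuration(spec)))
    stop("t outside the animation (0..", totalDuration(spec), " s)")
  ifelse(t < spec@leadWhiteS, "lead",
         ifelse(t < spec@leadWhiteS + spec@gratingS, "grating", "tail"))
}

#' Grating phase at a given time
#'
#' The spatial phase of the bar pattern, in [0, 2pi).  During the grating
#' segment the phase decreases linearly with slope
#' \code{-2*pi*speed / (2*barWidth)} (one full cycle per spatial period
#' travelled); it is constant before and after, so pixel content can be
#' verified against a closed form without image diffing.
#'
#' @param spec a \linkS4class{StimulusSpec}.
#' @param t time(s) in seconds, within [0, totalDuration].
#' @return phase(s) in [0, 2pi).
#' @export
phaseAt <- function(spec, t) {
  if (any(t < 0 | t > totalDuration(spec)))
    stop("t outside the animation (0..", totalDuration(spec), " s)")
  period <- 2 * spec@barWidth
  tg <- pmin(pmax(t - spec@leadWhiteS, 0), spec@gratingS)
  (-2 * pi * spec@speed * tg / period) %% (2 * pi)
}

## luminance profile over spatial phase theta, in [0, 1]
gratingProfile <- function(theta, profile, edgeDeg) {
  s <- sin(theta)
  if (profile == "square" || edgeDeg <= 0) {
    as.numeric(s >= 0)
  } else {
    half <- sin(edgeDeg * pi / 360)  # sin(edge/2)
    pmin(pmax(s / half, -1), 1) / 2 + 0.5
  }
}

#' Render one frame of the stimulus
#'
#' Frames are matrices in [0, 1] (black = 0, white = 1) with
#' \code{height} rows and \code{width} columns; pixel column j is sampled
#' at x = j - 0.5.  Grating frames are constant down each column
#' (the bars are vertical and motion is horizontal).
#'
#' @param spec a \linkS4class{StimulusSpec}.
#' @param width,height canvas size in px.
#' @param t frame time in seconds.
#' @return a height x width numeric matrix in [0, 1].
#' @export
stimulusFrame <- function(spec, width, height, t) {
  stopifnot(width >= 1, height >= 1)
  if (segmentAt(spec, t) != "grating")
    return(matrix(1, nrow = height, ncol = width))
  x <- seq_len(width) - 0.5
  theta <- 2 * pi * x / (2 * spec@barWidth) - phaseAt(spec, t)
  row <- gratingProfile(theta, spec@profile, spec@edgeDeg)
  matrix(row, nrow = height, ncol = width, byrow = TRUE)
}

#' Render the full stimulus animation
#'
#' Generates every frame of the animation.  With \code{outDir} set, frames
#' are written as 8-bit grayscale PNGs (\code{frame_000001.png}, ...) with
#' a JSON manifest of per-frame timestamps and segments; otherwise the
#' frames are returned in memory.  Frame i (1-based) is rendered at time
#' \code{(i - 1) / frameRate}.
#'
#' @param spec a \linkS4class{StimulusSpec}.
#' @param width,height canvas size in px.
#' @param outDir optional output directory for the PNG sequence.
#' @return invisibly, a list with \code{manifest} (data.frame: frame,
#'   time, segment) and either \code{frames} (list of matrices) or
#'   \code{dir}.
#' @export
renderStimulus <- function(spec, width = 960, height = 640, outDir = NULL) {
  stopifnot(is(spec, "StimulusSpec"), width >= 1, height >= 1)
  if (spec@gratingS == 0 && spec@speed != 0)
    warning("zero-duration grating with nonzero speed: no bars will be shown")
  n <- nFrames(spec)
  times <- (seq_len(n) - 1) / spec@frameRate
  manifest <- data.frame(frame = seq_len(n), time = times,
                         segment = segmentAt(spec, times))
  if (is.null(outDir)) {
    frames <- lapply(times, function(t) stimulusFrame(spec, width, height, t))
    return(invisible(list(frames = frames, manifest = manifest)))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    png::writePNG(stimulusFrame(spec, width, height, times[i]),
                  file.path(outDir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(dir = outDir, manifest = manifest))
}
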