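#' @import methods
NULL

#' WellGeometry: the four-area partition of a circular well
#'
#' A circular well partitioned into four regions by three chords
#' perpendicular to the stimulus-alignment axis.  Area 4 is the most-aligned
#' region (the direction the grating moves towards, leftmost by default) and
#' Area 1 the least aligned.  With the default area fractions
#' (0.10, 0.20, 0.20, 0.50) for Areas 4, 3, 2, 1, Area 1 is exactly the
#' half of the well away from the stimulus direction and the boundary
#' between Areas 2 and 1 lies on the vertical diameter.
#'
#' @slot center numeric(2), well centre (x, y) in the coordinate frame of
#'   the positions being classified (pixels or unitless).
#' @slot radius positive number, well radius in the same units.
#' @slot chordXs numeric(3), strictly increasing chord abscissae as
#'   fractions of the radius along the anti-alignment axis; they separate
#'   Area 4|3, 3|2 and 2|1.
#' @slot fractions numeric(4), target area fractions for Areas 4, 3, 2, 1
#'   (left to right along the alignment axis), summing to 1.
#' @slot direction numeric(2), unit vector giving the direction the
#'   stimulus moves towards (default leftward, \code{c(-1, 0)} in image
#'   coordinates).
#'
#' @seealso [computeAreaPartition()], [classifyPosition()]
#' @export
setClass("WellGeometry",
  representation(
    center = "numeric",
    radius = "numeric",
    chordXs = "numeric",
    fractions = "numeric",
    direction = "numeric"
  ),
  prototype(
    center = c(0, 0),
    radius = 1,
    direction = c(-1, 0)
  )
)

setValidity("WellGeometry", function(object) {
  msgs <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msgs <- c(msgs, "center must be a finite numeric of length 2")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    msgs <- c(msgs, "radius must be a single positive number")
  if (length(object@chordXs) != 3L || any(!is.finite(object@chordXs)))
    msgs <- c(msgs, "chordXs must be a finite numeric of length 3")
  else {
    if (any(diff(object@chordXs) <= 0))
      msgs <- c(msgs, "chordXs must be strictly increasing")
    if (any(object@chordXs <= -1) || any(object@chordXs >= 1))
      msgs <- c(msgs, "chordXs must lie strictly inside (-1, 1)")
  }
  if (length(object@fractions) != 4L || any(object@fractions <= 0))
    msgs <- c(msgs, "fractions must be 4 positive numbers")
  else if (abs(sum(object@fractions) - 1) > 1e-9)
    msgs <- c(msgs, "fractions must sum to 1 (within 1e-9)")
  if (length(object@direction) != 2L ||
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    msgs <- c(msgs, "direction must be a unit vector of length 2")
  if (length(msgs)) msgs else TRUE
})

#' StimulusSpec: timing and geometry of the moving-grating animation
#'
#' The optomotor stimulus is an animation of alternating black and white
#' bars moving right-to-left, flanked by solid-white segments used to score
#' larval positions: 5 s of white, 30 s of grating, 5 s of white by
#' default.
#'
#' @slot barWidth width of one bar in px (one spatial period is two bars).
#' @slot frameRate frames per second.
#' @slot leadWhiteS,gratingS,tailWhiteS segment durations in seconds.
#' @slot speed pattern speed in px/s; positive values move the pattern
#'   right-to-left (the default assay direction).
#' @slot profile \code{"sine"} for bars with soft sinusoidal edges or
#'   \code{"square"} for a hard square wave.
#' @slot edgeDeg width of the luminance transition between bars, in degrees
#'   of spatial phase (default 60); ignored for the square profile.
#'
#' @seealso [stimulusSpec()], [renderStimulus()], [phaseAt()]
#' @export
setClass("StimulusSpec",
  representation(
    barWidth = "numeric",
    frameRate = "numeric",
    leadWhiteS = "numeric",
    gratingS = "numeric",
    tailWhiteS = "numeric",
    speed = "numeric",
    profile = "character",
    edgeDeg = "numeric"
  ),
  prototype(
    barWidth = 60, frameRate = 30, leadWhiteS = 5, gratingS = 30,
    tailWhiteS = 5, speed = 120, profile = "sine", edgeDeg = 60
  )
)

setValidity("StimulusSpec", function(object) {
  msgs <- character()
  if (object@barWidth <= 0) msgs <- c(msgs, "barWidth must be > 0")
  if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
  if (object@leadWhiteS < 0 || object@gratingS < 0 || object@tailWhiteS < 0)
    msgs <- c(msgs, "segment durations must be >= 0")
  if (!object@profile %in% c("sine", "square"))
    msgs <- c(msgs, "profile must be 'sine' or 'square'")
  if (object@edgeDeg < 0 || object@edgeDeg > 180)
    msgs <- c(msgs, "edgeDeg must be in [0, 180]")
  if (length(msgs)) msgs else TRUE
})

#' PlateLayout: geometry of a multi-well plate image
#'
#' Describes the grid of circular wells in a rendered (or photographed)
#' top-down plate image.  The default is a 48-well plate, 6 rows by 8
#' columns.  Image coordinates have the origin at the top-left corner, x
#' rightward and y downward; pixel (row i, col j) is centred at
#' (j - 0.5, i - 0.5).
#'
#' @slot rows,cols number of well rows and columns.
#' @slot wellRadius well radius in px.
#' @slot pitch centre-to-centre well spacing in px.
#' @slot margin distance from the image border to the centre of the first
#'   well, in px.
#'
#' @seealso [plateLayout()], [renderPlate()], [detectWells()]
#' @export
setClass("PlateLayout",
  representation(
    rows = "integer",
    cols = "integer",
    wellRadius = "numeric",
    pitch = "numeric",
    margin = "numeric"
  ),
  prototype(
    rows = 6L, cols = 8L, wellRadius = 20, pitch = 50, margin = 30
  )
)

setValidity("PlateLayout", function(object) {
  msgs <- character()
  if (object@rows < 1L || object@cols < 1L)
    msgs <- c(msgs, "rows and cols must be >= 1")
  if (object@wellRadius <= 0) msgs <- c(msgs, "wellRadius must be > 0")
  if (object@pitch < 2 * object@wellRadius + 2)
    msgs <- c(msgs, "pitch too small: wells would overlap")
  if (object@margin < object@wellRadius + 1)
    msgs <- c(msgs, "margin too small: wells would clip the image border")
  if (length(msgs)) msgs else TRUE
})

#' BehaviorParams: phenotype parameters of the larval simulator
#'
#' The simulator draws a responder flag once per larva with probability
#' \code{pAlign}; responders drift towards the stimulus direction while the
#' grating is on, all larvae take isotropic noise steps, and positions are
#' reflected at the well wall.
#'
#' @slot pAlign probability in [0, 1] that a larva perceives and responds
#'   to the grating.
#' @slot driftGain mean drift speed of responders towards the alignment
#'   direction, in well radii per second.
#' @slot noiseSd isotropic positional diffusion, in well radii per square
#'   root second (a step of duration dt has per-axis sd
#'   \code{noiseSd * sqrt(dt)}).
#' @slot phenotype free-text label, e.g. \code{"control"} or
#'   \code{"mbl-like"}.
#'
#' @seealso [behaviorParams()], [phenotypePreset()], [runTrial()]
#' @export
setClass("BehaviorParams",
  representation(
    pAlign = "numeric",
    driftGain = "numeric",
    noiseSd = "numeric",
    phenotype = "character"
  ),
  prototype(
    pAlign = 0.7, driftGain = 0.06, noiseSd = 0.15, phenotype = "control"
  )
)

setValidity("BehaviorParams", function(object) {
  msgs <- character()
  if (object@pAlign < 0 || object@pAlign > 1)
    msgs <- c(msgs, "pAlign must be in [0, 1]")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@driftGain < 0) msgs <- c(msgs, "driftGain must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' ActivityTrace: a startle-assay motion time series
#'
#' Per-bin motion magnitude over a baseline period in constant light
#' followed by five regularly spaced light interruptions (the visual
#' startle stimulus).
#'
#' @slot time numeric, uniform time grid in seconds (bin centres).
#' @slot motion numeric, non-negative motion magnitude per bin (arbitrary
#'   units).
#' @slot baselineS duration of the baseline period in seconds (default
#'   1800 s = 30 min).
#' @slot interruptions numeric(5), times of the light interruptions in
#'   seconds; all after the baseline, regularly spaced.
#'
#' @seealso [activityTrace()], [simulateTrace()], [countResponses()]
#' @export
setClass("ActivityTrace",
  representation(
    time = "numeric",
    motion = "numeric",
    baselineS = "numeric",
    interruptions = "numeric"
  )
)

setValidity("ActivityTrace", function(object) {
  msgs <- character()
  if (length(object@time) != length(object@motion))
    msgs <- c(msgs, "time and motion must have the same length")
  if (length(object@time) > 1) {
    dt <- diff(object@time)
    if (any(abs(dt - dt[1]) > 1e-8 * max(1, dt[1])))
      msgs <- c(msgs, "time grid must be uniform")
  }
  if (any(object@motion < 0)) msgs <- c(msgs, "motion must be >= 0")
  if (length(object@interruptions) != 5L)
    msgs <- c(msgs, "exactly five interruption times are required")
  else {
    if (any(object@interruptions <= object@baselineS))
      msgs <- c(msgs, "interruptions must fall after the baseline period")
    sp <- diff(sort(object@interruptions))
    if (length(sp) && any(abs(sp - sp[1]) > 1e-6 * max(1, sp[1])))
      msgs <- c(msgs, "interruptions must be regularly spaced")
  }
  if (length(msgs)) msgs else TRUE
})
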