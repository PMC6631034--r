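#' Construct behaviour parameters / phenotype presets
#'
#' `behaviorParams()` builds a parameter set directly; `phenotypePreset()`
#' returns one of the named presets used throughout the package:
#' \describe{
#'   \item{control}{visually responsive larvae; `pAlign = 0.7` so that
#'     roughly three quarters of a cohort finishes in Areas 3+4 after a
#'     30 s grating, the qualitative behaviour of wild-type cohorts.}
#'   \item{mbl}{eyeless, fully non-responsive (`pAlign = 0`); final
#'     positions stay uniform over the well.}
#'   \item{rbm24a}{severely visually impaired (`pAlign = 0.15`); change
#'     scores centre close to 0.}
#'   \item{crim1}{mildly affected but still responsive (`pAlign = 0.55`);
#'     change scores trend positive.}
#' }
#' Presets share the motility defaults `driftGain = 0.06` well radii/s and
#' `noiseSd = 0.15` well radii per sqrt(s): the phenotypes differ in
#' vision, not motility.
#'
#' @param pAlign probability a larva responds to the grating.
#' @param driftGain responder drift towards the stimulus direction, in
#'   well radii per second.
#' @param noiseSd positional diffusion, well radii per sqrt second.
#' @param phenotype label.
#' @param name preset name.
#' @return a \linkS4class{BehaviorParams}.
#' @export
behaviorParams <- function(pAlign = 0.7, driftGain = 0.06, noiseSd = 0.15,
                           phenotype = "custom") {
  new("BehaviorParams", pAlign = pAlign, driftGain = driftGain,
      noiseSd = noiseSd, phenotype = phenotype)
}

#' @rdname behaviorParams
#' @export
phenotypePreset <- function(name = c("control", "mbl", "rbm24a", "crim1")) {
  name <- match.arg(name)
  p <- switch(name, control = 0.7, mbl = 0, rbm24a = 0.15, crim1 = 0.55)
  behaviorParams(pAlign = p, phenotype = name)
}

#' Initialise a cohort of larvae
#'
#' Positions are i.i.d. uniform over the well disk and headings i.i.d.
#' uniform on [0, 2pi) -- larvae start randomly oriented within their
#' wells.  With a \linkS4class{PlateLayout} supplied, larvae are assigned
#' one per well in row-major order and `n` may not exceed the number of
#' wells.
#'
#' @param n number of larvae.
#' @param geometry a \linkS4class{WellGeometry} (well-local frame).
#' @param seed optional integer seed (deterministic states for a given
#'   seed).
#' @param layout optional \linkS4class{PlateLayout} for well assignment.
#' @return data.frame with columns `larva_id`, `well`, `row`, `col`, `x`,
#'   `y`, `heading`, `time` (positions in the geometry's frame).
#' @export
initCohort <- function(n, geometry = computeAreaPartition(), seed = NULL,
                       layout = NULL) {
  stopifnot(n >= 1)
  if (!is.null(layout)) {
    nw <- layout@rows * layout@cols
    if (n > nw)
      stop("n = ", n, " exceeds the ", nw, " wells on the configured plate")
  }
  if (!is.null(seed)) set.seed(seed)
  R <- geometry@radius
  th <- stats::runif(n, 0, 2 * pi)
  rr <- R * sqrt(stats::runif(n))
  if (!is.null(layout)) {
    idx <- seq_len(n) - 1L
    row <- idx %/% layout@cols + 1L
    col <- idx %% layout@cols + 1L
    well <- paste0(LETTERS[row], col)
  } else {
    row <- col <- rep(NA_integer_, n)
    well <- paste0("W", seq_len(n))
  }
  data.frame(larva_id = paste0("L", seq_len(n)), well = well,
             row = row, col = col,
             x = geometry@center[1] + rr * cos(th),
             y = geometry@center[2] + rr * sin(th),
             heading = stats::runif(n, 0, 2 * pi),
             time = 0, stringsAsFactors = FALSE)
}

## reflect positions at the well wall (radial reflection, repeated until
## inside; a step larger than the diameter is clamped to the rim)
reflectIntoWell <- function(x, y, geometry) {
  cx <- geometry@center[1]; cy <- geometry@center[2]; R <- geometry@radius
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  for (it in 1:8) {
    out <- which(r > R)
    if (!length(out)) break
    scale <- (2 * R - r[out]) / r[out]
    neg <- scale < 0           # overshoot beyond the far wall: clamp to rim
    scale[neg] <- R / r[out][neg] * 0.999
    dx[out] <- dx[out] * scale
    dy[out] <- dy[out] * scale
    r[out] <- abs(2 * R - r[out])
    r[out][neg] <- R * 0.999
  }
  list(x = cx + dx, y = cy + dy)
}

#' Advance a cohort by one time step
#'
#' Responders (drawn once per larva with probability `pAlign`; the
#' `responder` column is added on first use) drift towards the alignment
#' direction while the stimulus is on; all larvae take isotropic Gaussian
#' noise steps with per-axis sd `noiseSd * sqrt(dt)` (in well radii), and
#' positions are reflected at the well wall.  Responder headings lock onto
#' the stimulus direction while it is on; other headings random-walk.
#'
#' @param states cohort data.frame from [initCohort()].
#' @param params a \linkS4class{BehaviorParams}.
#' @param geometry a \linkS4class{WellGeometry}.
#' @param stimulusOn logical: is the grating on during this step?
#' @param dt step duration in seconds (> 0).
#' @return updated states data.frame.
#' @export
stepCohort <- function(states, params, geometry = computeAreaPartition(),
                       stimulusOn = TRUE, dt = 0.1) {
  stopifnot(dt > 0, is(params, "BehaviorParams"))
  n <- nrow(states)
  if (is.null(states$responder))
    states$responder <- stats::runif(n) < params@pAlign
  R <- geometry@radius
  dir <- geometry@direction
  sd_step <- params@noiseSd * sqrt(dt) * R
  dx <- stats::rnorm(n, 0, sd_step)
  dy <- stats::rnorm(n, 0, sd_step)
  if (stimulusOn) {
    drift <- params@driftGain * dt * R
    dx <- dx + drift * dir[1] * states$responder
    dy <- dy + drift * dir[2] * states$responder
  }
  pos <- reflectIntoWell(states$x + dx, states$y + dy, geometry)
  states$x <- pos$x
  states$y <- pos$y
  locked <- stimulusOn & states$responder
  wander <- states$heading + stats::rnorm(n, 0, sqrt(dt))
  states$heading <- ifelse(locked, atan2(dir[2], dir[1]) %% (2 * pi),
                           wander %% (2 * pi))
  states$time <- states$time + dt
  states
}

#' Run a simulated optomotor trial
#'
#' Simulates a cohort under the grating from t = 0 to the last timeline
#' point, records a state snapshot at every timeline time (default every
#' 15 s over a 60 s exposure) and builds trial records from the initial
#' (0 s) and `finalTime` snapshots.  The default `finalTime` of 30 s is
#' the assay's standard exposure.
#'
#' @param params a \linkS4class{BehaviorParams}.
#' @param n cohort size.
#' @param geometry a \linkS4class{WellGeometry}.
#' @param timeline sorted sample times in seconds; must start at 0 and
#'   contain `finalTime`.
#' @param finalTime time point used as the final position (seconds).
#' @param dt integration step in seconds.
#' @param seed optional integer seed.
#' @param layout optional \linkS4class{PlateLayout}.
#' @return list with `records` (see [trialRecords()]), `states` (snapshot
#'   rows for every timeline time, with an `area` column) and `params`.
#' @export
runTrial <- function(params, n, geometry = computeAreaPartition(),
                     timeline = c(0, 15, 30, 45, 60), finalTime = 30,
                     dt = 0.1, seed = NULL, layout = NULL) {
  if (is.unsorted(timeline, strictly = TRUE))
    stop("timeline must be strictly increasing")
  if (timeline[1] != 0)
    stop("timeline must start at 0")
  if (!finalTime %in% timeline)
    stop("finalTime (", finalTime, ") must be one of the timeline points")
  if (!is.null(seed)) set.seed(seed)
  states <- initCohort(n, geometry, seed = NULL, layout = layout)
  states$responder <- stats::runif(n) < params@pAlign
  snaps <- vector("list", length(timeline))
  snaps[[1]] <- states
  for (k in seq_along(timeline)[-1]) {
    span <- timeline[k] - timeline[k - 1]
    nstep <- max(1L, ceiling(span / dt))
    h <- span / nstep
    for (s in seq_len(nstep))
      states <- stepCohort(states, params, geometry,
                           stimulusOn = TRUE, dt = h)
    states$time <- timeline[k]   # absorb float accumulation
    snaps[[k]] <- states
  }
  snapdf <- do.call(rbind, snaps)
  snapdf$area <- classifyPosition(cbind(snapdf$x, snapdf$y), geometry)
  ini <- snapdf[snapdf$time == 0, ]
  fin <- snapdf[snapdf$time == finalTime, ]
  rec <- trialRecords(ini$area, fin$area, larva_id = ini$larva_id,
                      well = ini$well)
  list(records = rec, states = snapdf, params = params)
}

#' Estimate cohort responsiveness from trial records
#'
#' Method-of-moments estimate of `pAlign` from the excess of final
#' occupancy in Areas 3+4 over its baseline under uniform positions
#' (30% with the default partition):
#' `(observed - baseline) / (responder - baseline)`, clipped to [0, 1].
#' The responder occupancy (final Areas 3+4 probability of a fully
#' responsive cohort) is calibrated by simulating a reference cohort with
#' `pAlign = 1` under the supplied dynamics, unless given directly.
#'
#' @param records trial-record data.frame.
#' @param geometry the \linkS4class{WellGeometry} used for scoring.
#' @param params \linkS4class{BehaviorParams} describing the cohort's
#'   dynamics (used only to calibrate the responder occupancy).
#' @param responderOccupancy optional known responder occupancy in [0, 1];
#'   overrides the calibration run.
#' @param nRef reference-cohort size for the calibration.
#' @param finalTime exposure used for the records, seconds.
#' @param refSeed internal seed of the calibration run (the caller's RNG
#'   state is preserved).
#' @return estimated `pAlign` in [0, 1].
#' @export
estimateResponsiveness <- function(records, geometry = computeAreaPartition(),
                                   params = behaviorParams(),
                                   responderOccupancy = NULL, nRef = 2000,
                                   finalTime = 30, refSeed = 76543) {
  n <- nrow(records)
  if (n < 20)
    warning("fewer than 20 records: the responsiveness estimate is ",
            "very imprecise")
  frac <- areaFractions(geometry)
  base <- unname(frac["area3"] + frac["area4"])
  if (is.null(responderOccupancy)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    ref <- behaviorParams(pAlign = 1, driftGain = params@driftGain,
                          noiseSd = params@noiseSd, phenotype = "reference")
    tr <- runTrial(ref, nRef, geometry, timeline = c(0, finalTime),
                   finalTime = finalTime, seed = refSeed)
    responderOccupancy <- mean(tr$records$final_area >= 3)
  }
  if (responderOccupancy <= base)
    stop("responder occupancy must exceed the uniform baseline (",
         round(base, 3), ")")
  f <- mean(records$final_area >= 3)
  min(1, max(0, (f - base) / (responderOccupancy - base)))
}
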