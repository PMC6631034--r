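#' Construct an activity trace
#'
#' @param time uniform time grid (s, bin centres).
#' @param motion non-negative motion magnitude per bin.
#' @param baselineS baseline duration in seconds (default 1800 = 30 min).
#' @param interruptions five light-interruption times (s); default five
#'   interruptions 30 s apart starting 30 s after the baseline, giving a
#'   total assay of about 33 minutes.
#' @return an \linkS4class{ActivityTrace}.
#' @export
activityTrace <- function(time, motion, baselineS = 1800,
                          interruptions = baselineS + 30 * (1:5)) {
  new("ActivityTrace", time = time, motion = motion,
      baselineS = baselineS, interruptions = interruptions)
}

#' Count startle responses to the five light interruptions
#'
#' Baseline mean and SD of the motion signal are estimated over the
#' constant-light period; a response to interruption i is scored when the
#' maximum motion within `windowS` seconds after it exceeds
#' `baseline mean + kSd * baseline SD`.  If the baseline SD is zero the
#' threshold falls back to the baseline mean plus a small epsilon and a
#' flag is set.
#'
#' @param trace an \linkS4class{ActivityTrace} covering every
#'   interruption plus the response window.
#' @param kSd threshold multiplier (default 3 baseline SDs).
#' @param windowS response window after each interruption, seconds
#'   (default 5).
#' @return list with `responses` (0-5), `perInterruption` (logical(5)),
#'   `baselineMean`, `baselineSd`, `threshold`, `flags`.
#' @export
countResponses <- function(trace, kSd = 3, windowS = 5) {
  stopifnot(is(trace, "ActivityTrace"))
  if (max(trace@time) < max(trace@interruptions) + windowS)
    stop("trace does not cover the last interruption plus the response window")
  base <- trace@motion[trace@time <= trace@baselineS]
  if (length(base) < 2) stop("baseline period contains fewer than 2 bins")
  bm <- mean(base); bs <- stats::sd(base)
  flags <- character()
  if (bs == 0) {
    thr <- bm + 1e-8
    flags <- "zero_baseline_sd"
  } else {
    thr <- bm + kSd * bs
  }
  hit <- vapply(trace@interruptions, function(ti) {
    w <- trace@time > ti & trace@time <= ti + windowS
    any(trace@motion[w] > thr)
  }, logical(1))
  list(responses = sum(hit), perInterruption = hit,
       baselineMean = bm, baselineSd = bs, threshold = thr, flags = flags)
}

#' Simulate a startle-assay activity trace
#'
#' Baseline motion is positive noise (Gaussian, clipped at zero) over a
#' 30 min constant-light period followed by five light interruptions.
#' Responders add an exponentially decaying motion burst of height
#' `spikeGain` baseline SDs immediately after each interruption;
#' non-responders (e.g. the eyeless preset) produce noise throughout, so
#' their expected response count at the default threshold is below 1 in 5.
#'
#' @param responder logical: does this larva react to the interruptions?
#' @param spikeGain burst height in units of the baseline SD (default 8).
#' @param baselineS baseline duration (s).
#' @param interruptions five interruption times (s); default as in
#'   [activityTrace()].
#' @param binS bin width (s, default 1).
#' @param noiseMean,noiseSd baseline noise parameters (arbitrary motion
#'   units).
#' @param decayS burst decay time constant (s).
#' @param seed optional integer seed (identical seeds give identical
#'   traces).
#' @return an \linkS4class{ActivityTrace}.
#' @export
simulateTrace <- function(responder = TRUE, spikeGain = 8,
                          baselineS = 1800,
                          interruptions = baselineS + 30 * (1:5),
                          binS = 1, noiseMean = 1, noiseSd = 0.2,
                          decayS = 1.5, seed = NULL) {
  stopifnot(spikeGain >= 0, binS > 0)
  if (!is.null(seed)) set.seed(seed)
  total <- max(interruptions) + 30
  time <- seq(binS / 2, total, by = binS)
  motion <- pmax(0, stats::rnorm(length(time), noiseMean, noiseSd))
  if (responder && spikeGain > 0) {
    for (ti in interruptions) {
      w <- which(time > ti & time <= ti + 6 * decayS)
      motion[w] <- motion[w] +
        spikeGain * noiseSd * exp(-(time[w] - ti) / decayS)
    }
  }
  activityTrace(time, motion, baselineS = baselineS,
                interruptions = interruptions)
}

#' Summarise startle scores for a cohort
#'
#' @param scores integer vector of per-larva response counts (0-5).
#' @return data.frame with n, mean, sd of the counts.
#' @export
summarizeVizn <- function(scores) {
  stopifnot(all(scores >= 0 & scores <= 5))
  data.frame(n = length(scores), mean = mean(scores), sd = stats::sd(scores))
}
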