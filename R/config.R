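#' Default run configuration
#'
#' The resolved configuration drives every pipeline stage: plate layout,
#' area-partition fractions, stimulus timing, behaviour presets, trial
#' timeline, statistics options and the startle-counter settings.  All
#' fields can be overridden from a YAML file via [readRunConfig()].
#'
#' @return a named list (class `omrRunConfig`).
#' @export
defaultRunConfig <- function() {
  cfg <- list(
    plate = list(rows = 6, cols = 8, well_radius = 20, pitch = 50,
                 margin = 30),
    geometry = list(fractions = c(0.10, 0.20, 0.20, 0.50),
                    direction = c(-1, 0)),
    stimulus = list(bar_width = 60, frame_rate = 30, lead_white_s = 5,
                    grating_s = 30, tail_white_s = 5, speed = 120,
                    profile = "sine", edge_deg = 60),
    behavior = list(presets = c("control", "mbl"), dt = 0.1),
    trial = list(timeline = c(0, 15, 30, 45, 60), final_time = 30),
    stats = list(bonferroni = FALSE),
    vizn = list(k_sd = 3, window_s = 5, baseline_s = 1800),
    seed = 1
  )
  class(cfg) <- c("omrRunConfig", "list")
  cfg
}

#' Read, validate and write run configurations
#'
#' `readRunConfig()` loads a YAML file, overlays it on the defaults and
#' validates the result; `validateRunConfig()` raises an error naming the
#' offending field; `writeRunConfig()` writes the resolved configuration
#' back to YAML (every pipeline run stores its resolved configuration
#' beside its outputs).
#'
#' @param path YAML file path.
#' @param cfg a configuration list.
#' @return `readRunConfig`: validated config; `validateRunConfig`: the
#'   config, invisibly.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), user)
  class(cfg) <- c("omrRunConfig", "list")
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(cfg) {
  fail <- function(field, why)
    stop("invalid configuration: field '", field, "' ", why, call. = FALSE)
  fr <- cfg$geometry$fractions
  if (length(fr) != 4 || any(fr <= 0))
    fail("geometry.fractions", "must be 4 positive numbers")
  if (abs(sum(fr) - 1) > 1e-9)
    fail("geometry.fractions",
         paste0("must sum to 1 (got ", format(sum(fr)), ")"))
  dirv <- cfg$geometry$direction
  if (length(dirv) != 2 || sqrt(sum(dirv^2)) < 1e-9)
    fail("geometry.direction", "must be a nonzero vector of length 2")
  p <- cfg$plate
  if (p$rows < 1 || p$cols < 1) fail("plate.rows/cols", "must be >= 1")
  if (p$pitch < 2 * p$well_radius + 2)
    fail("plate.pitch", "is too small: wells would overlap")
  s <- cfg$stimulus
  if (s$bar_width <= 0) fail("stimulus.bar_width", "must be > 0")
  if (s$frame_rate <= 0) fail("stimulus.frame_rate", "must be > 0")
  if (any(c(s$lead_white_s, s$grating_s, s$tail_white_s) < 0))
    fail("stimulus.*_s", "durations must be >= 0")
  if (!s$profile %in% c("sine", "square"))
    fail("stimulus.profile", "must be 'sine' or 'square'")
  tl <- cfg$trial$timeline
  if (is.unsorted(tl, strictly = TRUE) || tl[1] != 0)
    fail("trial.timeline", "must be strictly increasing and start at 0")
  if (!cfg$trial$final_time %in% tl)
    fail("trial.final_time", "must be one of the timeline points")
  known <- c("control", "mbl", "rbm24a", "crim1")
  if (!all(cfg$behavior$presets %in% known))
    fail("behavior.presets",
         paste0("must be among: ", paste(known, collapse = ", ")))
  invisible(cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a configuration (polynomial rolling hash of its serialised form)
#'
#' Every pipeline output is tagged with this hash so results can be traced
#' back to the exact resolved configuration.
#'
#' @param cfg a configuration list.
#' @return 8-hex-digit character hash.
#' @export
configHash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## helpers mapping config sections onto the S4 objects
layoutFromConfig <- function(cfg) {
  plateLayout(cfg$plate$rows, cfg$plate$cols, cfg$plate$well_radius,
              cfg$plate$pitch, cfg$plate$margin)
}

geometryFromConfig <- function(cfg) {
  computeAreaPartition(cfg$geometry$fractions,
                       direction = cfg$geometry$direction)
}

stimulusFromConfig <- function(cfg) {
  s <- cfg$stimulus
  stimulusSpec(barWidth = s$bar_width, frameRate = s$frame_rate,
               leadWhiteS = s$lead_white_s, gratingS = s$grating_s,
               tailWhiteS = s$tail_white_s, speed = s$speed,
               profile = s$profile, edgeDeg = s$edge_deg)
}
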