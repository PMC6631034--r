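#' Area of the circular segment left of a vertical chord
#'
#' For the unit disk, the area of the region left of the chord at abscissa
#' \code{x} is \code{x * sqrt(1 - x^2) + asin(x) + pi/2}.  Used internally
#' by the partition solver and exported for verification by numerical
#' integration.
#'
#' @param x chord abscissa (fraction of the radius), in [-1, 1].
#' @return segment area (unit-disk units; multiply by radius^2 for a
#'   general well).
#' @export
circularSegmentArea <- function(x) {
  stopifnot(all(x >= -1 & x <= 1))
  x * sqrt(pmax(0, 1 - x^2)) + asin(x) + pi / 2
}

#' Compute the four-area partition of a circular well
#'
#' Places three chords perpendicular to the stimulus-alignment axis so
#' that the four regions have the requested area fractions.  Fractions are
#' given left to right along the alignment axis, i.e. for Areas 4, 3, 2, 1
#' (most to least aligned).  The defaults (0.10, 0.20, 0.20, 0.50)
#' reproduce the standard scoring partition: Area 4 is the leftmost 10% of
#' the well area, Areas 3 and 2 each 20%, Area 1 the right half.
#'
#' Chord abscissae solve the circular-segment area equation
#' A(x)/pi = cumulative fraction by safeguarded root-finding to 1e-12,
#' so each recovered segment area is within 1e-9 of its target.
#'
#' @param fractions numeric(4), positive area fractions for Areas 4, 3, 2,
#'   1, summing to 1 (within 1e-9).
#' @param radius well radius (default 1).
#' @param center numeric(2), well centre (default the origin).
#' @param direction unit vector the stimulus moves towards (default
#'   leftward, \code{c(-1, 0)}).
#' @return a \linkS4class{WellGeometry}.
#' @examples
#' geom <- computeAreaPartition()
#' chordXs(geom)        # -0.687, -0.320, 0
#' areaFractions(geom)
#' @export
computeAreaPartition <- function(fractions = c(0.10, 0.20, 0.20, 0.50),
                                 radius = 1, center = c(0, 0),
                                 direction = c(-1, 0)) {
  if (length(fractions) != 4L || any(!is.finite(fractions)) ||
      any(fractions <= 0))
    stop("fractions must be 4 positive finite numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (within 1e-9); got sum = ",
         format(sum(fractions), digits = 12))
  cum <- cumsum(fractions)[1:3]
  chords <- vapply(cum, function(f) {
    stats::uniroot(function(x) circularSegmentArea(x) / pi - f,
                   interval = c(-1, 1), tol = 1e-13)$root
  }, numeric(1))
  ## snap the half-disk chord onto the diameter exactly
  chords[abs(chords) < 1e-9] <- 0
  new("WellGeometry", center = as.numeric(center), radius = radius,
      chordXs = chords, fractions = as.numeric(fractions),
      direction = direction / sqrt(sum(direction^2)))
}

#' Classify larva head positions into Areas 1-4
#'
#' Projects each point onto the anti-alignment axis of the well and
#' assigns the area whose chord interval contains it.  Points exactly on a
#' chord are assigned to the more-aligned (higher-numbered) side.
#'
#' @param points numeric(2) or an n x 2 matrix/data.frame of (x, y)
#'   positions in the same frame as the geometry.
#' @param geometry a \linkS4class{WellGeometry}.
#' @param tol tolerance (fraction of radius) for the in-well check.
#' @return integer vector of area labels in 1..4 (4 = most aligned).
#' @examples
#' geom <- computeAreaPartition()
#' classifyPosition(c(0.9, 0), geom)    # Area 1
#' classifyPosition(c(-0.99, 0), geom)  # Area 4
#' @export
classifyPosition <- function(points, geometry, tol = 1e-9) {
  stopifnot(is(geometry, "WellGeometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)")
  rel <- sweep(points, 2, geometry@center) / geometry@radius
  r2 <- rowSums(rel^2)
  if (any(r2 > (1 + tol)^2)) {
    bad <- which(r2 > (1 + tol)^2)
    stop(structure(class = c("omrplate_out_of_well", "error", "condition"),
      list(message = sprintf(
             "%d point(s) outside the well (first at index %d, r/R = %.3f)",
             length(bad), bad[1], sqrt(r2[bad[1]])),
           call = sys.call(-1), index = bad)))
  }
  ## signed coordinate along the anti-alignment axis: +1 at the
  ## least-aligned rim, -1 at the most-aligned rim
  s <- as.vector(rel %*% (-geometry@direction))
  ## boundary points (s == chord) go to the higher-numbered area
  as.integer(1L + rowSums(outer(s, geometry@chordXs, "<=")))
}

#' Post-stimulus change score
#'
#' The change score is the final position score minus the initial position
#' score (the area label doubles as the position score), an integer in
#' -3..+3.  Positive scores denote improved alignment.
#'
#' @param initial,final integer area labels in 1..4 (vectorised).
#' @return integer change scores.
#' @examples
#' changeScore(1, 4)  # +3
#' changeScore(4, 1)  # -3
#' @export
changeScore <- function(initial, final) {
  initial <- as.integer(initial); final <- as.integer(final)
  if (any(is.na(initial) | initial < 1L | initial > 4L) ||
      any(is.na(final) | final < 1L | final > 4L))
    stop("area labels must be integers in 1..4")
  final - initial
}

#' Classify a change score as improved / no_change / decreased
#'
#' @param score integer change score(s) in -3..+3.
#' @return factor with levels \code{improved}, \code{no_change},
#'   \code{decreased}.
#' @export
classifyChange <- function(score) {
  score <- as.integer(score)
  if (any(is.na(score) | abs(score) > 3L))
    stop("change scores must be integers in -3..+3")
  factor(ifelse(score > 0L, "improved",
         ifelse(score < 0L, "decreased", "no_change")),
         levels = c("improved", "no_change", "decreased"))
}

#' Population distribution over the four areas
#'
#' Counts and percentages of larvae in each area at one time point, the
#' quantity plotted as before/after bar graphs in the population analysis.
#'
#' @param labels integer area labels in 1..4.
#' @return data.frame with columns \code{area}, \code{count}, \code{pct}.
#' @export
populationDistribution <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  labels <- as.integer(labels)
  if (any(is.na(labels) | labels < 1L | labels > 4L))
    stop("area labels must be integers in 1..4")
  counts <- tabulate(labels, nbins = 4L)
  data.frame(area = 1:4, count = counts,
             pct = 100 * counts / length(labels))
}

#' Build trial records from initial and final area labels
#'
#' One row per larva with its initial/final area, change score and change
#' class -- the per-larva unit of the post-stimulus analysis.
#'
#' @param initial,final integer area labels in 1..4.
#' @param larva_id optional identifiers (default \code{"L1"..}).
#' @param well optional well names.
#' @return data.frame with columns \code{larva_id}, \code{well},
#'   \code{initial_area}, \code{final_area}, \code{change_score},
#'   \code{change_class}.
#' @export
trialRecords <- function(initial, final, larva_id = NULL, well = NA_character_) {
  stopifnot(length(initial) == length(final))
  n <- length(initial)
  if (is.null(larva_id)) larva_id <- paste0("L", seq_len(n))
  sc <- changeScore(initial, final)
  data.frame(larva_id = as.character(larva_id),
             well = rep_len(as.character(well), n),
             initial_area = as.integer(initial),
             final_area = as.integer(final),
             change_score = sc,
             change_class = classifyChange(sc),
             stringsAsFactors = FALSE)
}

#' 4x4 transition table of initial vs final areas
#'
#' Entry (i, j) counts larvae that started in Area i and finished in Area
#' j; the input of Bowker's symmetry test.
#'
#' @param records a trial-record data.frame from [trialRecords()] (or any
#'   data.frame with \code{initial_area} and \code{final_area} columns).
#' @return a 4 x 4 integer matrix with dimnames \code{initial}/\code{final}.
#' @export
transitionTable <- function(records) {
  stopifnot(all(c("initial_area", "final_area") %in% names(records)))
  tab <- table(factor(records$initial_area, levels = 1:4),
               factor(records$final_area, levels = 1:4))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(initial = 1:4, final = 1:4))
  m
}

#' Read / write trial records as delimited text
#'
#' @param records trial-record data.frame.
#' @param path file path.
#' @return \code{readTrialRecords} returns the records data.frame with
#'   \code{change_class} restored as a factor.
#' @export
writeTrialRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialRecords
#' @export
readTrialRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "initial_area", "final_area")
  if (!all(need %in% names(rec)))
    stop("trial-record file must contain columns: ",
         paste(need, collapse = ", "))
  if (is.null(rec$change_score))
    rec$change_score <- changeScore(rec$initial_area, rec$final_area)
  rec$change_class <- classifyChange(rec$change_score)
  rec
}
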