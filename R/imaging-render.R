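#' Construct a plate layout
#'
#' @param rows,cols well grid (default 6 x 8, a 48-well plate).
#' @param wellRadius well radius in px.
#' @param pitch well centre spacing in px.
#' @param margin image border to first well centre, px.
#' @return a \linkS4class{PlateLayout}.
#' @export
plateLayout <- function(rows = 6, cols = 8, wellRadius = 20, pitch = 50,
                        margin = 30) {
  new("PlateLayout", rows = as.integer(rows), cols = as.integer(cols),
      wellRadius = wellRadius, pitch = pitch, margin = margin)
}

#' Pixel positions of well centres and image size
#'
#' Image coordinates: origin at the top-left corner, x rightward, y
#' downward; pixel (row i, col j) is centred at (j - 0.5, i - 0.5).
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @return `wellCenters`: data.frame (row, col, well, cx, cy);
#'   `imageSize`: c(width, height) in px.
#' @export
wellCenters <- function(layout) {
  g <- expand.grid(col = seq_len(layout@cols), row = seq_len(layout@rows))
  data.frame(row = g$row, col = g$col,
             well = paste0(LETTERS[g$row], g$col),
             cx = layout@margin + (g$col - 1) * layout@pitch,
             cy = layout@margin + (g$row - 1) * layout@pitch)
}

#' @rdname wellCenters
#' @export
imageSize <- function(layout) {
  c(width = ceiling(2 * layout@margin + (layout@cols - 1) * layout@pitch),
    height = ceiling(2 * layout@margin + (layout@rows - 1) * layout@pitch))
}

## grayscale levels of the rendered scene
.RIM_GRAY <- 0.15
.BODY_GRAY <- 0.45
.HEAD_GRAY <- 0.08

#' Render a synthetic top-down plate image
#'
#' Draws every well rim as a dark circle and every larva as an elongated
#' grey body with a darker head blob at its head position, onto a white
#' canvas or a supplied grating frame.  All edges are softened over about
#' one pixel so detected centroids are sub-pixel accurate.  The head is
#' always the darkest part of the larva, which makes head-calling
#' well-posed for the detector.  Rendering is deterministic: identical
#' states and layout give a byte-identical image.
#'
#' Simulator positions (in units of the geometry radius) are mapped into
#' the well with a wall clearance: the reachable disk has radius
#' `wellRadius - wallClearance` px, reflecting that a larva's head cannot
#' overlap the wall.  [scoreFrames()] uses the same convention.
#'
#' @param states cohort data.frame from [initCohort()]/[runTrial()] with
#'   well assignments (`row`, `col`) and positions in the geometry frame.
#' @param layout a \linkS4class{PlateLayout}.
#' @param geometry the \linkS4class{WellGeometry} the positions live in.
#' @param background `"white"` or `"grating"` (then `gratingFrame` must be
#'   an image-size matrix, e.g. from [stimulusFrame()]).
#' @param gratingFrame optional background matrix in [0, 1].
#' @param wallClearance px kept free between a head and the wall.
#' @return a height x width matrix in [0, 1].
#' @export
renderPlate <- function(states, layout, geometry = computeAreaPartition(),
                        background = c("white", "grating"),
                        gratingFrame = NULL, wallClearance = 3.5) {
  background <- match.arg(background)
  sz <- imageSize(layout)
  if (background == "grating") {
    if (is.null(gratingFrame) || !all(dim(gratingFrame) == c(sz[2], sz[1])))
      stop("gratingFrame must be a ", sz[2], " x ", sz[1], " matrix")
    img <- gratingFrame
  } else {
    img <- matrix(1, nrow = sz[2], ncol = sz[1])
  }
  wc <- wellCenters(layout)
  Rpx <- layout@wellRadius
  ## well rims
  for (w in seq_len(nrow(wc))) {
    img <- .drawRing(img, wc$cx[w], wc$cy[w], Rpx, .RIM_GRAY)
  }
  if (nrow(states) == 0) return(img)
  if (any(is.na(states$row)) || any(is.na(states$col)))
    stop("states must carry well assignments (row, col); ",
         "initialise the cohort with a plate layout")
  rel <- cbind(states$x - geometry@center[1],
               states$y - geometry@center[2]) / geometry@radius
  if (any(rowSums(rel^2) > 1 + 1e-6))
    stop("state position outside its well")
  reach <- Rpx - wallClearance
  for (i in seq_len(nrow(states))) {
    wi <- which(wc$row == states$row[i] & wc$col == states$col[i])
    if (!length(wi)) stop("state ", i, " maps to no well in the layout")
    hx <- wc$cx[wi] + rel[i, 1] * reach
    hy <- wc$cy[wi] + rel[i, 2] * reach
    img <- .drawLarva(img, hx, hy, states$heading[i], Rpx)
  }
  img
}

.pixelGrid <- function(img, x0, x1, y0, y1) {
  j0 <- max(1L, floor(x0)); j1 <- min(ncol(img), ceiling(x1) + 1L)
  i0 <- max(1L, floor(y0)); i1 <- min(nrow(img), ceiling(y1) + 1L)
  list(i = i0:i1, j = j0:j1,
       px = matrix((j0:j1) - 0.5, nrow = i1 - i0 + 1,
                   ncol = j1 - j0 + 1, byrow = TRUE),
       py = matrix((i0:i1) - 0.5, nrow = i1 - i0 + 1, ncol = j1 - j0 + 1))
}

.drawRing <- function(img, cx, cy, R, gray) {
  g <- .pixelGrid(img, cx - R - 2, cx + R + 2, cy - R - 2, cy + R + 2)
  r <- sqrt((g$px - cx)^2 + (g$py - cy)^2)
  a <- pmin(pmax(1.5 - abs(r - R), 0), 1)
  img[g$i, g$j] <- img[g$i, g$j] * (1 - a) + gray * a
  img
}

.drawLarva <- function(img, hx, hy, heading, Rpx) {
  hl <- 0.32 * Rpx              # body semi-length
  hw <- max(1.5, 0.09 * Rpx)    # body semi-width
  hr <- max(1.8, 0.11 * Rpx)    # head radius
  u <- c(cos(heading), sin(heading))
  bc <- c(hx, hy) - hl * u      # body centre; body tip sits at the head
  ext <- hl + hr + 2
  g <- .pixelGrid(img, bc[1] - ext, bc[1] + ext, bc[2] - ext, bc[2] + ext)
  dxp <- g$px - bc[1]; dyp <- g$py - bc[2]
  lu <- dxp * u[1] + dyp * u[2]
  lv <- -dxp * u[2] + dyp * u[1]
  e <- sqrt((lu / hl)^2 + (lv / hw)^2)
  aB <- pmin(pmax((1 - e) * hw, 0), 1)
  patch <- img[g$i, g$j]
  patch <- patch * (1 - aB) + .BODY_GRAY * aB
  d <- sqrt((g$px - hx)^2 + (g$py - hy)^2)
  aH <- pmin(pmax(hr - d, 0), 1)
  patch <- patch * (1 - aH) + .HEAD_GRAY * aH
  img[g$i, g$j] <- patch
  img
}

#' Write / read a plate image as PNG
#'
#' @param img matrix in [0, 1].
#' @param path file path.
#' @return `readPlateImage` returns the image matrix.
#' @export
writePlateImage <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname writePlateImage
#' @export
readPlateImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
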