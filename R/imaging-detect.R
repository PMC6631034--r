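## Automated plate reading: recover well circles from a frame, find the
## larva and its head inside each well, and score trials from the solid
## white lead-in and tail frames (the grating frames are deliberately not
## used for tracking).

## Kasa algebraic least-squares circle fit
.fitCircle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  c(cx = sol[1], cy = sol[2],
    r = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
}

## 8-connected components of a binary matrix -> list of data.frames
## (x, y, linear index).  EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged with a union-find pass.
.components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (sh[2] > 0) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] > 0) 2:nc else seq_len(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (t in touch) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  idx <- which(lab > 0)
  ij <- arrayInd(idx, dim(mask))
  split(data.frame(x = ij[, 2] - 0.5, y = ij[, 1] - 0.5, idx = idx),
        root[lab[idx]])
}

#' Detect well circles in a plate frame
#'
#' Thresholds the dark well rims, labels connected components, keeps
#' ring-shaped ones (hollow, with a narrow radius band) and refines each
#' centre with an algebraic circle fit on the annulus pixels.  With a
#' \linkS4class{PlateLayout} hint, detected circles are registered to the
#' hinted grid (a global translation is estimated, then wells are matched
#' by nearest centre); an error listing the missing wells is raised if any
#' hinted well has no detected circle.
#'
#' @param image plate frame, matrix in [0, 1].
#' @param layout optional \linkS4class{PlateLayout} hint.
#' @param darkThresh rim intensity threshold.
#' @return data.frame with columns `cx`, `cy`, `r` (and `row`, `col`,
#'   `well` when a layout hint is given), one row per well.  Raises a
#'   condition of class `omrplate_missing_wells` if no circle is found or
#'   hinted wells are unmatched.
#' @export
detectWells <- function(image, layout = NULL, darkThresh = 0.3) {
  comps <- .components(image < darkThresh)
  rings <- list()
  for (cp in comps) {
    if (nrow(cp) < 20) next
    cx0 <- mean(cp$x); cy0 <- mean(cp$y)
    d <- sqrt((cp$x - cx0)^2 + (cp$y - cy0)^2)
    med <- stats::median(d)
    if (med < 4) next
    if (mean(d < 0.5 * med) > 0.05) next       # not hollow
    keep <- abs(d - med) <= 2.5
    if (sum(keep) < 10) next
    fit <- .fitCircle(cp$x[keep], cp$y[keep])
    rings[[length(rings) + 1]] <- fit
  }
  det <- if (length(rings))
    as.data.frame(do.call(rbind, rings)) else
    data.frame(cx = numeric(), cy = numeric(), r = numeric())
  if (!is.null(layout)) {
    det <- det[abs(det$r - layout@wellRadius) <= 0.3 * layout@wellRadius, ,
               drop = FALSE]
  }
  if (nrow(det) == 0) {
    stop(structure(class = c("omrplate_missing_wells", "error", "condition"),
         list(message = "no wells detected in the image",
              call = sys.call(-1), detected = 0L,
              missing = if (is.null(layout)) character() else
                wellCenters(layout)$well)))
  }
  if (is.null(layout)) {
    return(det[order(det$cy, det$cx), , drop = FALSE])
  }
  wc <- wellCenters(layout)
  ## robust global translation, then nearest-centre matching
  off <- t(vapply(seq_len(nrow(det)), function(i) {
    k <- which.min((wc$cx - det$cx[i])^2 + (wc$cy - det$cy[i])^2)
    c(det$cx[i] - wc$cx[k], det$cy[i] - wc$cy[k])
  }, numeric(2)))
  dx <- stats::median(off[, 1]); dy <- stats::median(off[, 2])
  match_i <- integer(nrow(wc))
  for (k in seq_len(nrow(wc))) {
    d2 <- (det$cx - (wc$cx[k] + dx))^2 + (det$cy - (wc$cy[k] + dy))^2
    i <- which.min(d2)
    match_i[k] <- if (d2[i] <= (layout@pitch / 3)^2) i else NA_integer_
  }
  if (anyNA(match_i) || anyDuplicated(stats::na.omit(match_i))) {
    missing <- wc$well[is.na(match_i)]
    stop(structure(class = c("omrplate_missing_wells", "error", "condition"),
         list(message = paste0("detected ", nrow(det), " wells but ",
                length(missing), " hinted wells are unmatched: ",
                paste(missing, collapse = ", ")),
              call = sys.call(-1), detected = nrow(det), missing = missing)))
  }
  data.frame(row = wc$row, col = wc$col, well = wc$well,
             cx = det$cx[match_i], cy = det$cy[match_i],
             r = det$r[match_i])
}

#' Detect the larva and its head position inside one well
#'
#' On a solid-white frame, dark pixels inside the well (excluding the rim)
#' are thresholded and the largest connected component taken as the larva.
#' The component's intensity-weighted principal axis gives the body
#' orientation; the darker end is called the head.  The head point itself
#' is the darkness-weighted centroid of the head-blob pixels (the larva's
#' darkest cluster), which localises to sub-pixel accuracy; if no such
#' cluster exists the extreme pixels of the darker end are used and the
#' confidence lowered.  Two same-size components lower the confidence and
#' set an ambiguity flag.
#'
#' @param image plate frame, matrix in [0, 1].
#' @param cx,cy,r well circle in px (e.g. from [detectWells()]).
#' @param darkThresh larva intensity threshold.
#' @param minSize minimum component size in px.
#' @return `NULL` if no larva is found, else a list with `head` (x, y px),
#'   `orientation` (unit vector towards the head), `confidence`,
#'   `nPixels`, `flags`.
#' @export
detectLarva <- function(image, cx, cy, r, darkThresh = 0.75, minSize = 6) {
  g <- .pixelGrid(image, cx - r, cx + r, cy - r, cy + r)
  sub <- image[g$i, g$j]
  rr <- sqrt((g$px - cx)^2 + (g$py - cy)^2)
  mask <- sub < darkThresh & rr <= r - 1.5
  comps <- .components(mask)
  ## component coordinates are local to the subimage; shift to the frame
  comps <- lapply(comps, function(cp) {
    cp$x <- cp$x + (g$j[1] - 1L)
    cp$y <- cp$y + (g$i[1] - 1L)
    cp
  })
  sizes <- vapply(comps, nrow, 1L)
  if (!length(sizes) || max(sizes) < minSize) return(NULL)
  ord <- order(sizes, decreasing = TRUE)
  cp <- comps[[ord[1]]]
  flags <- character(); conf <- 1
  if (length(sizes) > 1 && sizes[ord[2]] >= 0.8 * sizes[ord[1]]) {
    flags <- c(flags, "ambiguous_components"); conf <- 0.5
  }
  ii <- sub[cp$idx]
  w <- pmax(0.9 - ii, 0)
  mx <- sum(w * cp$x) / sum(w); my <- sum(w * cp$y) / sum(w)
  X <- cbind(cp$x - mx, cp$y - my)
  cv <- crossprod(X * sqrt(w)) / sum(w)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- X %*% v
  if (mean(ii[proj > 0]) > mean(ii[proj <= 0])) v <- -v
  proj <- X %*% v
  headPix <- ii < 0.30
  if (sum(headPix) >= 3) {
    wh <- pmax(0.35 - ii[headPix], 0)
    head <- c(sum(wh * cp$x[headPix]) / sum(wh),
              sum(wh * cp$y[headPix]) / sum(wh))
  } else {
    top <- proj >= stats::quantile(proj, 0.7)
    head <- c(mean(cp$x[top]), mean(cp$y[top]))
    conf <- conf * 0.7
    flags <- c(flags, "no_head_blob")
  }
  list(head = unname(head), orientation = as.numeric(v),
       confidence = conf, nPixels = nrow(cp), flags = flags)
}

#' Score a trial from the first and last solid-white frames
#'
#' Runs well detection on the first frame, detects the larva head in each
#' well on both frames, maps heads to area labels with the well's
#' partition geometry and emits trial records.  Wells where either
#' detection fails are emitted with `missing = TRUE`, never silently
#' dropped.  Only the solid-white lead-in and tail frames are suitable:
#' the moving grating defeats simple dark-blob tracking.
#'
#' @param firstFrame,lastFrame plate frames (matrices in [0, 1]) of equal
#'   size, registered to the same plate position.
#' @param layout the \linkS4class{PlateLayout}.
#' @param fractions area fractions for the partition (Areas 4, 3, 2, 1).
#' @param direction stimulus direction unit vector.
#' @param wallClearance the renderer's wall clearance in px; the
#'   reachable-disk radius used for area mapping is the detected well
#'   radius minus this value.
#' @return data.frame with one row per well: `well`, `row`, `col`,
#'   `initial_area`, `final_area`, `change_score`, `change_class`,
#'   `missing`, `confidence`.
#' @export
scoreFrames <- function(firstFrame, lastFrame, layout,
                        fractions = c(0.10, 0.20, 0.20, 0.50),
                        direction = c(-1, 0), wallClearance = 3.5) {
  if (!all(dim(firstFrame) == dim(lastFrame)))
    stop("first and last frames must have identical dimensions")
  wells <- detectWells(firstFrame, layout)
  out <- vector("list", nrow(wells))
  for (k in seq_len(nrow(wells))) {
    wk <- wells[k, ]
    geom <- computeAreaPartition(fractions,
                                 radius = wk$r - wallClearance,
                                 center = c(wk$cx, wk$cy),
                                 direction = direction)
    d0 <- detectLarva(firstFrame, wk$cx, wk$cy, wk$r)
    d1 <- detectLarva(lastFrame, wk$cx, wk$cy, wk$r)
    if (is.null(d0) || is.null(d1)) {
      out[[k]] <- data.frame(well = wk$well, row = wk$row, col = wk$col,
                             initial_area = NA_integer_,
                             final_area = NA_integer_,
                             change_score = NA_integer_,
                             change_class = NA_character_,
                             missing = TRUE, confidence = NA_real_)
      next
    }
    a0 <- classifyPosition(d0$head, geom, tol = 0.5)
    a1 <- classifyPosition(d1$head, geom, tol = 0.5)
    sc <- changeScore(a0, a1)
    out[[k]] <- data.frame(well = wk$well, row = wk$row, col = wk$col,
                           initial_area = a0, final_area = a1,
                           change_score = sc,
                           change_class = as.character(classifyChange(sc)),
                           missing = FALSE,
                           confidence = min(d0$confidence, d1$confidence))
  }
  do.call(rbind, out)
}
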