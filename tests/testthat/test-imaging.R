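test_that("layouts validate well spacing and report centres and size", {
  expect_error(plateLayout(pitch = 30, wellRadius = 20), "overlap")
  expect_error(plateLayout(margin = 5, wellRadius = 20), "clip")
  lay <- plateLayout()
  wc <- wellCenters(lay)
  expect_identical(nrow(wc), 48L)
  expect_identical(wc$well[1], "A1")
  expect_identical(wc$well[48], "F8")
  expect_identical(unname(imageSize(lay)), c(410, 310))
})

test_that("an empty scene renders only well rims, deterministically", {
  lay <- plateLayout(rows = 1, cols = 2)
  img <- renderPlate(initCohort(1, defaultGeom, seed = 1, layout = lay)[0, ],
                     lay, defaultGeom)
  expect_identical(dim(img), as.integer(rev(imageSize(lay))))
  expect_equal(min(img), 0.15)                   # rim gray, nothing darker
  img2 <- renderPlate(initCohort(1, defaultGeom, seed = 2, layout = lay)[0, ],
                      lay, defaultGeom)
  expect_identical(img, img2)                    # byte-identical
})

test_that("a larva at the well centre renders its darkest blob there", {
  lay <- plateLayout(rows = 1, cols = 1)
  st <- initCohort(1, defaultGeom, seed = 1, layout = lay)
  st$x <- 0; st$y <- 0; st$heading <- 0
  img <- renderPlate(st, lay, defaultGeom)
  dark <- which(img == min(img), arr.ind = TRUE)
  cx <- mean(dark[, 2] - 0.5); cy <- mean(dark[, 1] - 0.5)
  ctr <- wellCenters(lay)
  expect_lt(sqrt((cx - ctr$cx)^2 + (cy - ctr$cy)^2), 1)
})

test_that("states outside the well or layout are rejected", {
  lay <- plateLayout(rows = 1, cols = 1)
  st <- initCohort(1, defaultGeom, seed = 1, layout = lay)
  st$x <- 1.5
  expect_error(renderPlate(st, lay, defaultGeom), "outside")
  st2 <- initCohort(1, defaultGeom, seed = 1)    # no well assignment
  expect_error(renderPlate(st2, lay, defaultGeom), "well assignments")
})

test_that("well detection recovers all centres to sub-pixel accuracy", {
  lay <- plateLayout()
  st <- initCohort(48, defaultGeom, seed = 2, layout = lay)
  img <- renderPlate(st, lay, defaultGeom)
  det <- detectWells(img, lay)
  wc <- wellCenters(lay)
  expect_identical(nrow(det), 48L)
  expect_lt(max(abs(det$cx - wc$cx)), 2)
  expect_lt(max(abs(det$cy - wc$cy)), 2)
  expect_lt(max(abs(det$r - lay@wellRadius)), 2)
})

test_that("detection is equivariant under image translation", {
  lay <- plateLayout(rows = 2, cols = 2)
  img <- renderPlate(initCohort(4, defaultGeom, seed = 3, layout = lay),
                     lay, defaultGeom)
  base <- detectWells(img)
  shifted <- matrix(1, nrow(img) + 7, ncol(img) + 5)
  shifted[7 + seq_len(nrow(img)), 5 + seq_len(ncol(img))] <- img
  det <- detectWells(shifted)
  expect_identical(nrow(det), nrow(base))
  base <- base[order(round(base$cy), round(base$cx)), ]
  det <- det[order(round(det$cy), round(det$cx)), ]
  expect_true(all(abs(det$cx - (base$cx + 5)) <= 1))
  expect_true(all(abs(det$cy - (base$cy + 7)) <= 1))
})

test_that("blank images and occluded wells raise structured errors", {
  err <- tryCatch(detectWells(matrix(1, 80, 80)), error = identity)
  expect_s3_class(err, "omrplate_missing_wells")
  expect_identical(err$detected, 0L)
  lay <- plateLayout(rows = 2, cols = 3)
  img <- renderPlate(initCohort(6, defaultGeom, seed = 4, layout = lay),
                     lay, defaultGeom)
  img[10:52, 10:52] <- 1                          # erase well A1
  err2 <- tryCatch(detectWells(img, lay), error = identity)
  expect_s3_class(err2, "omrplate_missing_wells")
  expect_identical(err2$missing, "A1")
})

test_that("larva heads are detected within 2 px of ground truth", {
  lay <- plateLayout(rows = 1, cols = 1)
  reach <- lay@wellRadius - 3.5
  for (case in list(c(0.4, -0.2, 0.7), c(-0.5, 0.3, 2.5), c(0, 0, 4))) {
    st <- initCohort(1, defaultGeom, seed = 1, layout = lay)
    st$x <- case[1]; st$y <- case[2]; st$heading <- case[3]
    img <- renderPlate(st, lay, defaultGeom)
    d <- detectLarva(img, 30, 30, lay@wellRadius)
    expect_false(is.null(d))
    truth <- c(30 + case[1] * reach, 30 + case[2] * reach)
    expect_lt(sqrt(sum((d$head - truth)^2)), 2)
  }
})

test_that("an empty well yields no detection", {
  lay <- plateLayout(rows = 1, cols = 1)
  img <- renderPlate(initCohort(1, defaultGeom, seed = 1, layout = lay)[0, ],
                     lay, defaultGeom)
  expect_null(detectLarva(img, 30, 30, lay@wellRadius))
})

test_that("rotating a well image 180 degrees mirrors the detected head", {
  lay <- plateLayout(rows = 1, cols = 1)
  st <- initCohort(1, defaultGeom, seed = 5, layout = lay)
  st$x <- 0.35; st$y <- 0.15; st$heading <- 1.1
  img <- renderPlate(st, lay, defaultGeom)
  d <- detectLarva(img, 30, 30, lay@wellRadius)
  rot <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img)))]
  W <- ncol(img); H <- nrow(img)
  d2 <- detectLarva(rot, W - 30, H - 30, lay@wellRadius)
  expect_lt(sqrt(sum((d2$head - c(W - d$head[1], H - d$head[2]))^2)), 2)
})

test_that("detected area labels agree with ground-truth classification near a chord", {
  lay <- plateLayout(rows = 1, cols = 1)
  cx2 <- chordXs(defaultGeom)[2]
  for (off in c(-0.06, 0.06)) {
    st <- initCohort(1, defaultGeom, seed = 6, layout = lay)
    st$x <- cx2 + off; st$y <- 0.1; st$heading <- pi
    img <- renderPlate(st, lay, defaultGeom)
    rec <- scoreFrames(img, img, lay)
    truth <- classifyPosition(c(st$x, st$y), defaultGeom)
    expect_identical(rec$initial_area, truth)
  }
})

test_that("identical frames score zero change everywhere", {
  lay <- plateLayout(rows = 2, cols = 3)
  img <- renderPlate(initCohort(6, defaultGeom, seed = 7, layout = lay),
                     lay, defaultGeom)
  rec <- scoreFrames(img, img, lay)
  expect_identical(nrow(rec), 6L)
  expect_true(all(!rec$missing))
  expect_true(all(rec$change_score == 0L))
})

test_that("wells with a missing larva are flagged, not dropped", {
  lay <- plateLayout(rows = 2, cols = 3)
  st <- initCohort(6, defaultGeom, seed = 8, layout = lay)[-1, ]
  img <- renderPlate(st, lay, defaultGeom)
  rec <- scoreFrames(img, img, lay)
  expect_identical(nrow(rec), 6L)
  expect_identical(sum(rec$missing), 1L)
  expect_identical(rec$well[rec$missing], "A1")
  expect_true(all(rec$change_score[!rec$missing] == 0L))
})

test_that("frame size mismatches are rejected", {
  lay <- plateLayout(rows = 1, cols = 1)
  img <- renderPlate(initCohort(1, defaultGeom, seed = 9, layout = lay),
                     lay, defaultGeom)
  expect_error(scoreFrames(img, img[-1, ], lay), "identical dimensions")
})

test_that("simulate-render-detect-score reproduces the simulator exactly", {
  lay <- plateLayout(rows = 2, cols = 3)
  tr <- runTrial(phenotypePreset("control"), 6, defaultGeom,
                 timeline = c(0, 30), seed = 10, layout = lay)
  s0 <- tr$states[tr$states$time == 0, ]
  s1 <- tr$states[tr$states$time == 30, ]
  rec <- scoreFrames(renderPlate(s0, lay, defaultGeom),
                     renderPlate(s1, lay, defaultGeom), lay)
  expect_true(all(!rec$missing))
  ord <- match(rec$well, s0$well)
  expect_identical(rec$initial_area, s0$area[ord])
  expect_identical(rec$final_area, s1$area[ord])
})

test_that("plate images round-trip through PNG", {
  lay <- plateLayout(rows = 1, cols = 2)
  img <- renderPlate(initCohort(2, defaultGeom, seed = 11, layout = lay),
                     lay, defaultGeom)
  path <- withr::local_tempfile(fileext = ".png")
  writePlateImage(img, path)
  back <- readPlateImage(path)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
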