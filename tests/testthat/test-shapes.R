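test_that("TPS round-trip preserves coordinates and ids", {
  set.seed(11)
  sc <- simulationScenario(nTaxa = 4, seed = 11, noiseSd = 0)
  ds <- simulateShapeDataset(sc)
  f <- tempfile(fileext = ".tps")
  writeTPS(ds$landmarks, f)
  back <- readTPS(f)
  expect_equal(landmarkCoords(back), landmarkCoords(ds$landmarks),
               tolerance = 1e-10)
  expect_equal(back@specimenID, ds$landmarks@specimenID)
  f2 <- tempfile(fileext = ".tps")
  writeTPS(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("TPS reader applies SCALE and rejects malformed records", {
  f <- tempfile(fileext = ".tps")
  writeLines(c("LM=3", "1 2", "3 4", "5 6", "SCALE=0.5", "ID=sp1"), f)
  d <- readTPS(f)
  expect_equal(landmarkCoords(d)[, , 1],
               matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE) * 0.5)
  bad <- tempfile(fileext = ".tps")
  writeLines(c("LM=3", "1 2", "3 4", "ID=sp1"), bad)
  expect_error(readTPS(bad), "malformed TPS record 1")
  mixed <- tempfile(fileext = ".tps")
  writeLines(c("LM=3", "1 2", "3 4", "5 6", "ID=a",
               "LM=4", "1 2", "3 4", "5 6", "7 8", "ID=b"), mixed)
  expect_error(readTPS(mixed), "inconsistent landmark counts")
})

test_that("landmark CSV round-trips through the reader", {
  set.seed(3)
  lm <- landmarkSet(array(rnorm(18 * 2 * 3), c(18, 2, 3)),
                    taxon = c("x", "y", "z"))
  f <- tempfile(fileext = ".csv")
  writeLandmarkCSV(lm, f)
  back <- readLandmarkCSV(f)
  expect_equal(landmarkCoords(back), landmarkCoords(lm), tolerance = 1e-12)
  expect_equal(taxa(back), taxa(lm))
})

test_that("centroid size follows its definition", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(centroidSize(sq), sqrt(2))
  set.seed(5)
  cfg <- matrix(rnorm(36), 18, 2)
  expect_equal(centroidSize(3.7 * cfg), 3.7 * centroidSize(cfg))
  ctr <- colMeans(cfg)
  expect_equal(centroidSize(cfg),
               sqrt(sum((cfg[, 1] - ctr[1])^2 + (cfg[, 2] - ctr[2])^2)))
})

test_that("averaging replicate specimens is the coordinate-wise mean", {
  set.seed(7)
  base <- matrix(rnorm(12), 6, 2)
  one <- landmarkSet(base, specimenID = "a", taxon = "sp",
                     roles = rep("fixed", 6))
  expect_equal(landmarkCoords(averageSpecimens(one))[, , 1], base)
  two <- landmarkSet(array(c(base, base), c(6, 2, 2)),
                     specimenID = c("a", "b"), taxon = c("sp", "sp"),
                     roles = rep("fixed", 6))
  expect_equal(landmarkCoords(averageSpecimens(two))[, , 1], base)
  off <- base
  off[3, 2] <- off[3, 2] + 2e-3
  shift <- landmarkSet(array(c(base, off), c(6, 2, 2)),
                       specimenID = c("a", "b"), taxon = c("sp", "sp"),
                       roles = rep("fixed", 6))
  avg <- landmarkCoords(averageSpecimens(shift))[, , 1]
  expect_equal(avg[3, 2], base[3, 2] + 1e-3)
  expect_equal(avg[-3, ], base[-3, ])
  mixed <- landmarkSet(array(c(base, off), c(6, 2, 2)),
                       specimenID = c("a", "b"), taxon = c("sp1", "sp2"),
                       roles = rep("fixed", 6))
  expect_error(averageSpecimens(mixed), "single taxon")
})

test_that("GPA is invariant to similarity transforms of the inputs", {
  set.seed(21)
  shp <- matrix(rnorm(36), 18, 2)
  copies <- array(0, c(18, 2, 4))
  copies[, , 1] <- shp
  copies[, , 2] <- shp %*% rotMat(37 * pi / 180)
  copies[, , 3] <- sweep(shp, 2, c(4, -2), "+")
  copies[, , 4] <- 3 * shp
  al <- gpa(landmarkSet(copies))
  cc <- landmarkCoords(al)
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_lt(procrustesDistance(cc[, , i], cc[, , j]), 1e-10)
  expect_true(al@converged)
})

test_that("reflection is only removed when allowed", {
  set.seed(22)
  shp <- matrix(rnorm(36), 18, 2)
  mir <- shp %*% diag(c(-1, 1))
  arr <- array(c(shp, mir), c(18, 2, 2))
  alNo <- gpa(landmarkSet(arr), allowReflection = FALSE)
  dNo <- procrustesDistance(landmarkCoords(alNo)[, , 1],
                            landmarkCoords(alNo)[, , 2])
  expect_gt(dNo, 0.1)
  alYes <- gpa(landmarkSet(arr), allowReflection = TRUE)
  dYes <- procrustesDistance(landmarkCoords(alYes)[, , 1],
                             landmarkCoords(alYes)[, , 2],
                             allowReflection = TRUE)
  expect_lt(dYes, 1e-10)
})

test_that("fitted rotation matches a brute-force grid search", {
  set.seed(23)
  for (rep in 1:5) {
    a <- matrix(rnorm(6), 3, 2)
    b <- matrix(rnorm(6), 3, 2)
    ca <- opershape:::centerScale(a)$coords
    cb <- opershape:::centerScale(b)$coords
    expect_equal(procrustesDistance(ca, cb),
                 gridProcrustesDistance(ca, cb), tolerance = 1e-4)
    expect_equal(procrustesDistance(ca, cb, allowReflection = TRUE),
                 gridProcrustesDistance(ca, cb, allowReflection = TRUE),
                 tolerance = 1e-4)
  }
})

test_that("procrustesDistance is a symmetric premetric on shapes", {
  set.seed(31)
  a <- opershape:::centerScale(matrix(rnorm(16), 8, 2))$coords
  b <- opershape:::centerScale(matrix(rnorm(16), 8, 2))$coords
  expect_equal(procrustesDistance(a, a), 0)
  expect_equal(procrustesDistance(a, b), procrustesDistance(b, a),
               tolerance = 1e-12)
  expect_error(procrustesDistance(a, b[1:5, ]), "mismatched")
})

test_that("GPA output is order-invariant and residuals centre on zero", {
  set.seed(41)
  arr <- array(rnorm(18 * 2 * 6), c(18, 2, 6))
  al1 <- gpa(landmarkSet(arr))
  perm <- c(4, 2, 6, 1, 3, 5)
  al2 <- gpa(landmarkSet(arr[, , perm]))
  d1 <- procrustesDistance(landmarkCoords(al1)[, , 1],
                           landmarkCoords(al1)[, , 2])
  d2 <- procrustesDistance(landmarkCoords(al2)[, , which(perm == 1)],
                           landmarkCoords(al2)[, , which(perm == 2)])
  expect_equal(d1, d2, tolerance = 1e-8)
  resid <- sweep(landmarkCoords(al1), c(1, 2), consensusShape(al1))
  expect_equal(apply(resid, c(1, 2), sum), matrix(0, 18, 2),
               tolerance = 1e-10)
  ## each aligned configuration is centred with unit centroid size
  for (i in 1:6) {
    ci <- landmarkCoords(al1)[, , i]
    expect_equal(colMeans(ci), c(0, 0), tolerance = 1e-12)
    expect_equal(sum(ci^2), 1, tolerance = 1e-12)
  }
})

test_that("left-side configurations are mirrored without changing shape", {
  set.seed(43)
  shp <- matrix(rnorm(36), 18, 2)
  other <- shp + 0.1 * matrix(rnorm(36), 18, 2)
  arrR <- array(c(shp, other), c(18, 2, 2))
  alR <- gpa(landmarkSet(arrR))
  arrL <- arrR
  arrL[, 1, 1] <- -arrL[, 1, 1]   # present the first specimen as left side
  lmL <- landmarkSet(arrL, side = c("left", "right"))
  alL <- gpa(lmL)
  dR <- procrustesDistance(landmarkCoords(alR)[, , 1],
                           landmarkCoords(alR)[, , 2])
  dL <- procrustesDistance(landmarkCoords(alL)[, , 1],
                           landmarkCoords(alL)[, , 2])
  expect_equal(dR, dL, tolerance = 1e-10)
})

test_that("degenerate configurations are rejected by name", {
  arr <- array(rnorm(12), c(3, 2, 2))
  arr[, , 2] <- 1   # all landmarks coincident
  lm <- landmarkSet(arr, specimenID = c("ok", "flat"))
  expect_error(gpa(lm), "flat")
})
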