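# exhaustive assignment oracle: maximize matched pairs, then minimize the
# total distance, by brute-force recursion (test-sized problems only)
bruteMatch <- function(D, tol) {
  nd <- nrow(D); nt <- ncol(D)
  best <- list(count = -1L, dist = Inf)
  rec <- function(i, used, count, dist) {
    if (i > nd) {
      if (count > best$count ||
          (count == best$count && dist < best$dist - 1e-12)) {
        best <<- list(count = count, dist = dist)
      }
      return(invisible())
    }
    rec(i + 1L, used, count, dist)
    for (j in seq_len(nt)) {
      if (!used[j] && D[i, j] <= tol) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L, dist + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L, 0)
  best
}

asDet <- function(rc) data.frame(id = seq_len(nrow(rc)), centroid_row = rc[, 1],
                                 centroid_col = rc[, 2])

test_that("perfect detections match with zero distance", {
  tru <- asDet(cbind(c(40, 80, 120), c(50, 60, 70)))
  m <- matchDetections(tru, tru, tolerance_px = 5)
  expect_identical(nrow(matchedPairs(m)), 3L)
  expect_equal(matchedPairs(m)$distance_px, rep(0, 3))
  expect_equal(detectionFraction(m), 1)
  expect_equal(detectionAccuracy(m), 1)
})

test_that("an equidistant detection matches the lower truth id", {
  det <- asDet(cbind(50, 50))
  tru <- asDet(cbind(c(50, 50), c(45, 55)))  # both 5 px away
  m <- matchDetections(det, tru, tolerance_px = 10)
  expect_identical(matchedPairs(m)$truth_id, 1L)
  expect_identical(m@unmatched_truth, 2L)
})

test_that("the assignment is optimal (brute-force oracle, random configs)", {
  withr::with_seed(99, {
    for (trial in 1:20) {
      nd <- sample(1:5, 1); nt <- sample(1:5, 1)
      det <- asDet(cbind(runif(nd, 0, 10), runif(nd, 0, 10)))
      tru <- asDet(cbind(runif(nt, 0, 10), runif(nt, 0, 10)))
      tol <- runif(1, 2, 8)
      D <- sqrt(outer(det$centroid_row, tru$centroid_row, "-")^2 +
                outer(det$centroid_col, tru$centroid_col, "-")^2)
      oracle <- bruteMatch(D, tol)
      m <- matchDetections(det, tru, tolerance_px = tol)
      expect_identical(nrow(matchedPairs(m)), oracle$count)
      if (oracle$count > 0) {
        expect_equal(sum(matchedPairs(m)$distance_px), oracle$dist,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("detection fraction and accuracy are the two caption ratios", {
  # 33 of 40 annotated neurons found: fraction 33/40 = 0.825
  tru <- asDet(cbind(seq(10, 400, 10), 50))
  det33 <- tru[1:33, ]
  m <- matchDetections(det33, tru, tolerance_px = 2)
  expect_equal(detectionFraction(m), 0.825)
  expect_equal(detectionAccuracy(m), 1)
  # 13 correct of 14 detections: accuracy 13/14 = 0.9286
  det14 <- rbind(tru[1:13, ], data.frame(id = 99, centroid_row = 500,
                                         centroid_col = 500))
  m2 <- matchDetections(det14, tru, tolerance_px = 2)
  expect_equal(round(detectionAccuracy(m2), 4), 0.9286)
  expect_equal(detectionFraction(m2), 13 / 40)
  # all spurious
  far <- asDet(cbind(c(500, 600), c(500, 600)))
  expect_equal(detectionAccuracy(matchDetections(far, tru, 2)), 0)
  # undefined denominators are absent, not zero
  none <- asDet(matrix(numeric(0), ncol = 2))
  expect_true(is.na(detectionFraction(matchDetections(det33, none, 2))))
  expect_true(is.na(detectionAccuracy(matchDetections(none, tru, 2))))
})

test_that("metrics are invariant under id relabeling", {
  withr::with_seed(7, {
    det <- asDet(cbind(runif(6, 0, 100), runif(6, 0, 100)))
    tru <- asDet(cbind(runif(8, 0, 100), runif(8, 0, 100)))
  })
  m1 <- matchDetections(det, tru, tolerance_px = 30)
  det2 <- det; det2$id <- rev(seq_len(nrow(det)) * 10L)
  tru2 <- tru; tru2$id <- seq_len(nrow(tru)) + 100L
  m2 <- matchDetections(det2, tru2, tolerance_px = 30)
  expect_equal(detectionFraction(m1), detectionFraction(m2))
  expect_equal(detectionAccuracy(m1), detectionAccuracy(m2))
})
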