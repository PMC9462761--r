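test_that("LDI handles the absence, single-category and partial cases", {
  g <- matrix("0", 11, 5)
  expect_equal(compute_ldi(disturbance_tally(g)), 0)

  g1 <- g; g1[3, ] <- "B"
  expect_equal(compute_ldi(disturbance_tally(g1)), 1.5)

  g2 <- g; g2[7, 2] <- "P"
  expect_equal(compute_ldi(disturbance_tally(g2)), 0.667 / 5)
})

test_that("LDI equals an independently coded double-loop accumulation", {
  set.seed(401)
  for (i in 1:50) {
    g <- random_tally_grid()
    expect_equal(compute_ldi(disturbance_tally(g)), oracle_ldi(g))
  }
})

test_that("LDI respects custom weights and rejects bad input", {
  g <- matrix("0", 11, 5); g[1, ] <- "C"
  w <- proximity_weights(w_B = 3, w_C = 2, w_P = 1)
  expect_equal(compute_ldi(disturbance_tally(g), w), 2)

  gbad <- g; gbad[2, 3] <- "X"
  expect_error(disturbance_tally(gbad), "category 2.*transect 3")
  expect_error(disturbance_tally(matrix("0", 10, 5)), "11 rows")
  expect_error(disturbance_tally(matrix("0", 11, 0)), "at least one transect")
  expect_error(proximity_weights(w_B = 1, w_C = 2, w_P = 0.5), "w_B >= w_C")

  gna <- g; gna[4, 1] <- NA
  expect_warning(t_na <- disturbance_tally(gna), "treated as absent")
  expect_equal(compute_ldi(t_na), 1)
})

test_that("CDI reproduces the published range and is linear", {
  expect_identical(compute_cdi(100, 0), 400)
  expect_identical(compute_cdi(0, 0), 0)
  expect_identical(compute_cdi(20, 30), 140)

  set.seed(402)
  for (i in 1:20) {
    a <- runif(2, 0, 25); b <- runif(2, 0, 25)
    expect_equal(compute_cdi(a[1] + a[2], b[1] + b[2]),
                 compute_cdi(a[1], b[1]) + compute_cdi(a[2], b[2]))
  }
  expect_error(compute_cdi(101, 0), "\\[0, 100\\]")
  expect_error(compute_cdi(-1, 5), "\\[0, 100\\]")
  expect_error(compute_cdi(60, 50), "exceeds 100")
})

test_that("IDI follows the Euclidean formula and both normalisations", {
  expect_equal(compute_idi(0, 0)$idi, 0)
  expect_equal(compute_idi(5, 0)$idi, 1)
  expect_equal(compute_idi(3, 150)$idi, sqrt(0.36 + 0.25))
  expect_equal(compute_idi(3, 150)$idi, 0.7810, tolerance = 1e-4)

  # raw value can exceed 1 under the printed formula; clamp reported
  r <- compute_idi(5, 400)
  expect_gt(r$idi, 1)
  expect_equal(r$idi_clamped, 1)

  # cdi400 variant is bounded at 1 on its design range
  r4 <- compute_idi(5, 400, normalization = "cdi400")
  expect_equal(r4$idi, 1)
  expect_equal(compute_idi(2, 100, normalization = "cdi400")$idi,
               sqrt(((2 / 5)^2 + (100 / 400)^2) / 2))

  expect_error(compute_idi(-1, 0), "non-negative")
  expect_error(compute_idi(0, 500), "\\[0, 400\\]")
})

test_that("IDI is monotone in each argument", {
  set.seed(403)
  for (i in 1:20) {
    l <- sort(runif(2, 0, 10)); c <- sort(runif(2, 0, 400))
    expect_lt(compute_idi(l[1], c[1])$idi, compute_idi(l[2], c[1])$idi)
    expect_lt(compute_idi(l[1], c[1])$idi, compute_idi(l[1], c[2])$idi)
  }
})

test_that("classification reproduces the three published levels", {
  expect_equal(as.character(classify_disturbance(c(0.049, 0.175, 0.814))),
               c("LOW", "MEDIUM", "HIGH"))
  # gap closure: the unassigned bands resolve to the lower level
  expect_equal(as.character(classify_disturbance(c(0.095, 0.10, 0.195, 0.20))),
               c("LOW", "MEDIUM", "MEDIUM", "HIGH"))
  expect_error(classify_disturbance(-0.1), "non-negative")
  # overridable thresholds
  expect_equal(as.character(
    classify_disturbance(0.15, thresholds = c(low = 0.2, high = 0.4))), "LOW")
})

test_that("every printed fixture IDI is classifiable and partitions 11/7/7", {
  t1 <- table1_streams()
  lev <- classify_disturbance(t1$idi)
  expect_false(anyNA(lev))
  expect_equal(as.vector(table(lev)), c(11, 7, 7))
  # the stream identified as most disturbed is in HIGH, the least in LOW
  expect_equal(as.character(lev[which.max(t1$idi)]), "HIGH")
  expect_equal(as.character(lev[which.min(t1$idi)]), "LOW")
})

test_that("score_disturbance assembles per-site scores", {
  lu <- data.frame(site_id = c("a", "b"),
                   urban_pct = c(0, 50), agri_pasture_pct = c(10, 30))
  g <- matrix("0", 11, 5); g[1, ] <- "B"
  tl <- list(a = disturbance_tally(matrix("0", 11, 5)),
             b = disturbance_tally(g))
  sc <- score_disturbance(lu, tl)
  expect_equal(sc$ldi, c(0, 1.5))
  expect_equal(sc$cdi, c(20, 260))
  expect_equal(sc$idi, sqrt((sc$ldi / 5)^2 + (sc$cdi / 300)^2))
  expect_error(score_disturbance(lu, tl[1]), "no tally for site")
  expect_error(
    score_disturbance(rbind(lu, lu)[c(1, 3, 2), ], NULL),
    "duplicate site_id")
})
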