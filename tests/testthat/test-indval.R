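test_that("specificity and fidelity components match direct formulas", {
  # equal counts in every site of one group, absent elsewhere
  m <- matrix(c(5, 5, 5, 0, 0, 0), 6, 1, dimnames = list(NULL, "sp"))
  g <- rep(c("g1", "g2"), each = 3)
  ab <- indval_components(m, g, "sp", "g1")
  expect_equal(unname(ab), c(1, 1))
  ab2 <- indval_components(m, g, "sp", "g2")
  expect_equal(unname(ab2), c(0, 0))

  # 2 groups of 2 sites, abundances (4,4 | 0,4)
  m2 <- matrix(c(4, 4, 0, 4), 4, 1, dimnames = list(NULL, "sp"))
  g2 <- rep(c("a", "b"), each = 2)
  ab3 <- indval_components(m2, g2, "sp", "a")
  expect_equal(unname(ab3["A"]), 2 / 3)
  expect_equal(unname(ab3["B"]), 1)

  # group totals instead of means when the size correction is off
  m3 <- matrix(c(2, 2, 2, 6), 4, 1, dimnames = list(NULL, "sp"))
  g3 <- c("a", "a", "a", "b")
  expect_equal(unname(indval_components(m3, g3, "sp", "a")["A"]), 0.25)
  expect_equal(
    unname(indval_components(m3, g3, "sp", "a",
                             size_corrected = FALSE)["A"]), 0.5)
  expect_equal(
    unname(indval_components(m3, g3, "sp", "b",
                             size_corrected = FALSE)["A"]), 0.5)

  expect_warning(
    z <- indval_components(cbind(sp = rep(0, 4)), g2, "sp", "a"),
    "zero total abundance")
  expect_equal(unname(z), c(0, 0))
})

test_that("components agree with the brute-force oracle on random data", {
  set.seed(409)
  for (i in 1:25) {
    m <- matrix(rpois(8 * 4, 2), 8, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    m[1, ] <- m[1, ] + 1   # avoid all-zero species warnings
    g <- sample(rep(c("x", "y"), 4))
    sp <- sample(colnames(m), 1)
    tg <- sample(c("x", "y"), 1)
    got <- indval_components(m, g, sp, tg)
    expect_equal(got, oracle_indval_AB(m, g, sp, tg))
  }
})

test_that("the statistic follows the chosen convention and its bounds", {
  expect_equal(indval_stat(1, 1), 1)
  expect_equal(indval_stat(0, 0.7), 0)
  expect_equal(indval_stat(2 / 3, 1), sqrt(2 / 3))
  expect_equal(indval_stat(2 / 3, 1), 0.8165, tolerance = 1e-4)
  expect_equal(indval_stat(0.5, 0.5, convention = "raw"), 0.25)
  expect_error(indval_stat(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the statistic is invariant to rescaling all abundances", {
  set.seed(410)
  m <- matrix(rpois(12 * 6, 3) + 1, 12, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  g <- rep(c("a", "b", "c"), each = 4)
  r1 <- indval_test(m, g, n_perm = 9, seed = 1)
  r2 <- indval_test(m * 7, g, n_perm = 9, seed = 1)
  expect_equal(r1$stat, r2$stat)
  expect_equal(r1$group, r2$group)
})

test_that("permutation p-values behave at the exchangeable extremes", {
  g <- rep(c("a", "b", "c"), each = 4)
  # identical abundance everywhere: no group structure, p = 1
  flat <- matrix(3, 12, 2, dimnames = list(NULL, c("s1", "s2")))
  r <- indval_test(flat, g, n_perm = 99, seed = 2)
  expect_true(all(r$p == 1))
  expect_true(all(abs(r$stat - max(r$stat)) < 1e-12))

  # planted perfect indicator attains the minimum p of 1/(n_perm+1);
  # 30 sites make tying relabellings (group 'a' landing exactly on the
  # occupied sites) vanishingly rare
  g30 <- rep(c("a", "b", "c"), each = 10)
  m <- matrix(rpois(30 * 5, 2), 30, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[, 1] <- 0; m[g30 == "a", 1] <- 6
  r2 <- indval_test(m, g30, n_perm = 999, seed = 3)
  ind <- r2[r2$species == "s1", ]
  expect_equal(ind$group, "a")
  expect_equal(ind$stat, 1)
  expect_equal(ind$p, 1 / 1000)
})

test_that("Monte-Carlo p matches full enumeration on a 6-site problem", {
  # 2 groups of 3 sites: only choose(6,3) = 20 distinct labellings
  set.seed(411)
  m <- matrix(rpois(6 * 3, 2), 6, 3, dimnames = list(NULL, paste0("s", 1:3)))
  m[, 1] <- c(5, 4, 6, 1, 0, 0)
  g <- rep(c("a", "b"), each = 3)

  cand <- rbind(c(1, 0), c(0, 1))
  stat_for <- function(labels, sp) {
    mu <- rbind(a = colMeans(m[labels == "a", , drop = FALSE]),
                b = colMeans(m[labels == "b", , drop = FALSE]))
    pres <- rbind(a = colMeans(m[labels == "a", , drop = FALSE] > 0),
                  b = colMeans(m[labels == "b", , drop = FALSE] > 0))
    A <- t(t(mu) / colSums(mu))
    max(sqrt(A[, sp] * pres[, sp]))
  }
  combs <- utils::combn(6, 3)
  exact_p <- function(sp) {
    obs <- stat_for(g, sp)
    hits <- 0
    for (k in seq_len(ncol(combs))) {
      lab <- rep("b", 6); lab[combs[, k]] <- "a"
      if (stat_for(lab, sp) >= obs - 1e-12) hits <- hits + 1
    }
    hits / ncol(combs)
  }
  r <- indval_test(m, g, n_perm = 1999, seed = 5)
  for (sp in colnames(m)) {
    pe <- exact_p(sp)
    pm <- r$p[r$species == sp]
    tol <- 3 * sqrt(pe * (1 - pe) / 2000) + 2 / 2000
    expect_lt(abs(pm - pe), max(tol, 0.02))
  }
})

test_that("combination search finds indicators of pooled groups", {
  g <- rep(c("a", "b", "c"), each = 4)
  m <- matrix(1, 12, 1, dimnames = list(NULL, "sp"))
  m[g == "c", 1] <- 0   # present across a and b only
  r_single <- indval_test(m, g, n_perm = 49, seed = 6)
  r_comb <- indval_test(m, g, n_perm = 49, seed = 6, combinations = TRUE)
  expect_equal(r_comb$group, "a+b")
  expect_equal(r_comb$stat, 1)
  expect_lt(r_single$stat, 1)
})

test_that("degenerate inputs are flagged", {
  g <- c("a", "a", "b", "b")
  m <- matrix(rpois(4 * 2, 2) + 1, 4, 2, dimnames = list(NULL, c("x", "y")))
  expect_warning(indval_test(m, c("a", "a", "a", "b"), n_perm = 9, seed = 1),
                 "fewer than 2 sites")
  expect_error(indval_test(m, g, n_perm = 0), "at least 1")
  expect_error(indval_test(m, rep("a", 4), n_perm = 9), "two site groups")
  z <- cbind(m, dead = 0)
  expect_warning(rz <- indval_test(z, g, n_perm = 9, seed = 1),
                 "zero total abundance")
  expect_equal(rz$p[rz$species == "dead"], 1)
  expect_equal(rz$stat[rz$species == "dead"], 0)
})
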