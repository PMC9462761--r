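test_that("VIF matches the lm-based oracle and flags constructed collinearity", {
  set.seed(412)
  env <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  v <- vif(env)
  for (j in 1:3)
    expect_equal(unname(v[j]), oracle_vif(as.matrix(env), j))
  expect_true(all(v < 2))

  env$x4 <- env$x1 + env$x2 + rnorm(30, 0, 0.01)
  v4 <- vif(env)
  expect_gt(v4["x4"], 10)
})

test_that("the collinearity screen drops duplicated and derived variables", {
  set.seed(413)
  n <- 40
  env <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # duplicated column: exactly one of the pair goes
  env$a_copy <- env$a
  sel <- select_variables(env)
  expect_equal(sum(c("a", "a_copy") %in% names(sel$env)), 1)
  expect_equal(sel$log$stage, "spearman")

  # orthogonal noise survives untouched
  env2 <- data.frame(matrix(rnorm(n * 4), n))
  sel2 <- select_variables(env2)
  expect_equal(ncol(sel2$env), 4)
  expect_equal(nrow(sel2$log), 0)
  expect_true(all(vif(sel2$env) < 2))

  # a rank-correlation-free linear combination is caught by the VIF stage
  env3 <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                     x4 = rnorm(n))
  env3$lc <- with(env3, x1 + x2 + x3 + x4 + rnorm(n, 0, 0.05))
  sel3 <- select_variables(env3)
  expect_true(any(sel3$log$stage == "vif"))
  expect_true(all(vif(sel3$env) <= 10))

  # constant variables are dropped up front with a logged trigger
  env4 <- data.frame(a = rnorm(n), b = rnorm(n), flat = 3)
  sel4 <- select_variables(env4)
  expect_false("flat" %in% names(sel4$env))
  expect_equal(sel4$log$stage[sel4$log$variable == "flat"], "constant")

  expect_error(select_variables(data.frame(a = rnorm(n))), "at least two")
  expect_error(select_variables(data.frame(a = rep(1, n), b = rep(2, n))),
               "excluded")
})

test_that("Bray-Curtis matches hand values and vegan", {
  m <- rbind(a = c(1, 2), b = c(2, 2))
  expect_equal(as.numeric(bray_curtis(m, transform = "none")), 1 / 7)

  ident <- rbind(a = c(3, 1), b = c(3, 1))
  expect_equal(as.numeric(bray_curtis(ident, transform = "none")), 0)

  disjoint <- rbind(a = c(5, 0), b = c(0, 9))
  expect_equal(as.numeric(bray_curtis(disjoint, transform = "none")), 1)

  set.seed(414)
  for (i in 1:10) {
    mm <- matrix(rpois(6 * 8, 3), 6, 8)
    mm[rowSums(mm) == 0, 1] <- 1
    expect_equal(as.vector(bray_curtis(mm, transform = "none")),
                 as.vector(vegan::vegdist(mm, "bray")))
    expect_equal(as.vector(bray_curtis(mm, transform = "sqrt")),
                 as.vector(vegan::vegdist(sqrt(mm), "bray")))
    # pairwise against the double-loop oracle
    d <- as.matrix(bray_curtis(mm, transform = "none"))
    expect_equal(d[1, 2], oracle_bray(mm[1, ], mm[2, ]))
    expect_equal(d[3, 5], oracle_bray(mm[3, ], mm[5, ]))
  }

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero.*a")
})

test_that("dbRDA under Euclidean distance equals classical RDA", {
  set.seed(415)
  for (i in 1:5) {
    Y <- matrix(rnorm(10 * 6), 10, 6)
    env <- data.frame(a = rnorm(10), b = rnorm(10))
    fit <- dbrda(dist(Y), env)
    ref <- vegan::rda(Y ~ a + b, data = env)
    expect_equal(unname(fit$eig_constrained), unname(ref$CCA$eig),
                 tolerance = 1e-8)
    expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
    expect_equal(sort(fit$eig_unconstrained, decreasing = TRUE),
                 unname(ref$CA$eig), tolerance = 1e-8)
  }
})

test_that("dbRDA conserves inertia and is invariant to site order", {
  set.seed(416)
  m <- matrix(rpois(12 * 9, 4), 12, 9,
              dimnames = list(paste0("s", 1:12), paste0("x", 1:9)))
  env <- data.frame(u = rnorm(12), v = rnorm(12))
  d <- bray_curtis(m)
  fit <- dbrda(d, env)
  # constrained + unconstrained = total positive PCoA inertia
  expect_equal(sum(fit$eig_constrained) + sum(fit$eig_unconstrained),
               fit$total_inertia, tolerance = 1e-8)
  expect_true(all(fit$proportion >= 0) && sum(fit$proportion) <= 1 + 1e-10)
  # axis scores orthogonal
  cp <- crossprod(fit$lc)
  expect_equal(cp[lower.tri(cp)], rep(0, sum(lower.tri(cp))),
               tolerance = 1e-8)

  perm <- sample(12)
  m2 <- m[perm, ]
  fit2 <- dbrda(bray_curtis(m2), env[perm, , drop = FALSE])
  expect_equal(fit$eig_constrained, fit2$eig_constrained, tolerance = 1e-10)
  expect_equal(fit$negative_inertia, fit2$negative_inertia,
               tolerance = 1e-10)

  # vegan capscale agrees on the constrained eigenvalues for Bray-Curtis;
  # capscale leaves small (< 4) dissimilarities unscaled, so its
  # eigenvalues are raw sums of squares, ours divided by n - 1
  ref <- vegan::capscale(d ~ u + v, data = env)
  expect_equal(unname(fit$eig_constrained * (12 - 1)), unname(ref$CCA$eig),
               tolerance = 1e-6)
})

test_that("a binary variable splitting two community clusters loads axis 1", {
  set.seed(417)
  base1 <- c(20, 15, 10, 0, 0, 0)
  base2 <- c(0, 0, 0, 20, 15, 10)
  m <- rbind(t(replicate(5, rpois(6, base1 + 1))),
             t(replicate(5, rpois(6, base2 + 1))))
  rownames(m) <- paste0("s", 1:10)
  env <- data.frame(split = rep(c(0, 1), each = 5))
  fit <- dbrda(bray_curtis(m), env)
  sc <- fit$lc[, 1]
  expect_true(max(sc[1:5]) < min(sc[6:10]) ||
                min(sc[1:5]) > max(sc[6:10]))
  # the constrained axis carries more inertia than any residual axis
  expect_gt(fit$eig_constrained[1], max(fit$eig_unconstrained))
})

test_that("permutation tests reach the minimum p for perfect structure", {
  set.seed(418)
  # smooth strong compositional turnover along a continuous gradient: no
  # two sites are exchangeable, so no permutation ties or beats the
  # observed statistic and the minimum p is attainable
  x <- seq_len(12)
  m <- cbind(up1 = rpois(12, exp(x / 3)), up2 = rpois(12, exp(x / 3.5)),
             dn1 = rpois(12, exp((13 - x) / 3)),
             dn2 = rpois(12, exp((13 - x) / 3.5)),
             flat = rpois(12, 4))
  rownames(m) <- paste0("s", 1:12)
  env <- data.frame(split = x + rnorm(12, 0, 0.1))
  fit <- dbrda(bray_curtis(m), env)
  g <- dbrda_permutation_test(fit, by = "global", n_perm = 199, seed = 9)
  expect_equal(g$p, 1 / 200)
  # single-variable margin test equals the global test
  mg <- dbrda_permutation_test(fit, by = "margin", n_perm = 199, seed = 9)
  expect_equal(mg$pseudo_f, g$pseudo_f)
  expect_equal(mg$p, g$p)
  ax <- dbrda_permutation_test(fit, by = "axis", n_perm = 199, seed = 9)
  expect_equal(ax$p[1], 1 / 200)
  expect_error(dbrda_permutation_test(fit, n_perm = 0), "at least 1")
})

test_that("dbRDA rejects malformed inputs", {
  set.seed(419)
  m <- matrix(rpois(8 * 5, 3), 8, 5)
  d <- bray_curtis(m)
  expect_error(dbrda(as.matrix(d), data.frame(a = rnorm(8))), "dist object")
  expect_error(dbrda(d, data.frame(a = rnorm(7))), "match the sites")
  env <- data.frame(a = rnorm(8))
  env$b <- env$a
  expect_error(dbrda(d, env), "rank deficient")
  wide <- as.data.frame(matrix(rnorm(8 * 8), 8))
  expect_error(dbrda(d, wide), "more sites than")
})
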