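# Independent brute-force oracles, written as plain double loops so they
# share no code path with the package implementations they check.

oracle_ldi <- function(grid, w_B = 1.5, w_C = 1.0, w_P = 0.667) {
  total <- 0
  for (i in seq_len(nrow(grid))) {
    acc <- 0
    for (j in seq_len(ncol(grid))) {
      acc <- acc + switch(grid[i, j], "0" = 0, B = w_B, C = w_C, P = w_P)
    }
    total <- total + acc / ncol(grid)
  }
  total
}

oracle_diversity <- function(x) {
  tot <- 0
  for (v in x) tot <- tot + v
  S <- 0; H <- 0; D <- 0
  for (v in x) {
    if (v > 0) {
      S <- S + 1
      p <- v / tot
      H <- H - p * log(p)
      D <- D + p * p
    }
  }
  list(richness = S, abundance = tot, shannon = H, simpson = D,
       equitability = if (S > 1) H / log(S) else NA_real_)
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  num / den
}

oracle_indval_AB <- function(counts, groups, sp, g) {
  lev <- unique(groups)
  means <- numeric(length(lev))
  for (li in seq_along(lev)) {
    rows <- which(groups == lev[li])
    s <- 0
    for (r in rows) s <- s + counts[r, sp]
    means[li] <- s / length(rows)
  }
  A <- means[match(g, lev)] / sum(means)
  rows <- which(groups == g)
  pres <- 0
  for (r in rows) if (counts[r, sp] > 0) pres <- pres + 1
  c(A = A, B = pres / length(rows))
}

oracle_vif <- function(env, j) {
  fit <- stats::lm(env[, j] ~ ., data = as.data.frame(env[, -j, drop = FALSE]))
  r2 <- summary(fit)$r.squared
  1 / (1 - r2)
}

oracle_restrictedness <- function(counts, sp) {
  occ <- 0
  for (i in seq_len(nrow(counts))) if (counts[i, sp] > 0) occ <- occ + 1
  1 - occ / nrow(counts)
}

# random tally grid for property tests
random_tally_grid <- function(p_absent = 0.6) {
  codes <- sample(c("0", "B", "C", "P"), 55, replace = TRUE,
                  prob = c(p_absent, rep((1 - p_absent) / 3, 3)))
  matrix(codes, 11, 5)
}
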