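#' Specificity and fidelity components of the indicator value
#'
#' For a species and a target site group, specificity \eqn{A} is the
#' concentration of the species' abundance in that group and fidelity
#' \eqn{B} is the fraction of the group's sites where the species occurs.
#' With the group-size correction (default) \eqn{A} is computed from group
#' mean abundances, \eqn{A = \bar{x}_{g} / \sum_h \bar{x}_{h}}, so groups
#' with more sites do not dominate; without it, \eqn{A} uses group total
#' abundances.
#'
#' @param counts site-by-species abundance matrix.
#' @param groups factor/character vector of site group labels, aligned
#'   with the rows of \code{counts}.
#' @param species species id (column name) or index.
#' @param target_group group label.
#' @param size_corrected logical; use group means (default) rather than
#'   group totals for specificity.
#' @return named numeric vector \code{c(A =, B =)}, both in [0, 1].
#' @export
#' @examples
#' m <- matrix(c(4, 4, 0, 4), 4, 1, dimnames = list(NULL, "sp"))
#' indval_components(m, c("g1", "g1", "g2", "g2"), "sp", "g1")
indval_components <- function(counts, groups, species, target_group,
                              size_corrected = TRUE) {
  counts <- as_abundance(counts)
  groups <- .check_groups(groups, nrow(counts))
  x <- counts[, species]
  if (sum(x) == 0) {
    warning("species '", species, "' has zero total abundance")
    return(c(A = 0, B = 0))
  }
  if (!target_group %in% levels(groups))
    stop("unknown group '", target_group, "'")
  agg <- if (size_corrected) tapply(x, groups, mean) else tapply(x, groups, sum)
  A <- unname(agg[target_group] / sum(agg))
  in_g <- groups == target_group
  B <- mean(x[in_g] > 0)
  c(A = A, B = B)
}

#' Indicator value statistic
#'
#' Combines specificity and fidelity into the indicator value. The
#' \code{"sqrt"} convention, \eqn{\sqrt{A B}} (default, the convention of
#' the standard implementation, on the 0-1 scale), or the raw
#' Dufrene-Legendre product \eqn{A B}.
#'
#' @param A specificity in [0, 1].
#' @param B fidelity in [0, 1].
#' @param convention \code{"sqrt"} (default) or \code{"raw"}.
#' @return statistic in [0, 1]; 1 iff the species occurs at every site of
#'   its group and nowhere else.
#' @export
indval_stat <- function(A, B, convention = c("sqrt", "raw")) {
  convention <- match.arg(convention)
  if (any(A < -1e-12) || any(A > 1 + 1e-12) ||
      any(B < -1e-12) || any(B > 1 + 1e-12))
    stop("A and B must lie in [0, 1]")
  switch(convention, sqrt = sqrt(A * B), raw = A * B)
}

.check_groups <- function(groups, n_sites) {
  groups <- factor(groups)
  if (length(groups) != n_sites)
    stop("'groups' must assign every site to exactly one group")
  if (anyNA(groups)) stop("'groups' has missing assignments")
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("at least two site groups are required")
  groups
}

# Candidate group sets as a 0/1 matrix (rows = candidates, cols = groups).
# Singletons always; with combinations = TRUE all proper subsets of the
# groups of size >= 2 are added (the combination-search extension).
.candidate_sets <- function(k, combinations) {
  sets <- diag(1, k)
  if (combinations && k > 2L) {
    for (size in 2:(k - 1L)) {
      cmb <- utils::combn(k, size)
      add <- t(apply(cmb, 2, function(ix) {
        v <- numeric(k); v[ix] <- 1; v
      }))
      sets <- rbind(sets, add)
    }
  }
  sets
}

# Statistic matrix (candidates x species) for one group labelling.
# mu: k x S matrix of group means (or sums); pres_g: k x S presence counts;
# ng: group sizes; cand: candidate 0/1 matrix.
.indval_stat_matrix <- function(counts, pres, groups, cand,
                                size_corrected, convention) {
  k <- nlevels(groups)
  G <- stats::model.matrix(~ groups - 1)        # n x k indicator
  ng <- colSums(G)
  agg <- crossprod(G, counts)                   # k x S group sums
  if (size_corrected) agg <- agg / ng
  tot <- colSums(agg)
  pres_g <- crossprod(G, pres)                  # k x S presence counts
  A <- (cand %*% agg) / rep(tot, each = nrow(cand))
  A[, tot == 0] <- 0
  B <- (cand %*% pres_g) / as.vector(cand %*% ng)
  st <- A * B
  if (convention == "sqrt") st <- sqrt(st)
  list(A = A, B = B, stat = st)
}

#' Indicator species analysis with permutation inference
#'
#' For every species, finds the site group (or, optionally, combination of
#' groups) with the highest indicator value and tests its significance by
#' permuting the site-to-group labels while holding the abundance matrix
#' fixed. The permutation p-value uses the \eqn{(b+1)/(N+1)} estimator
#' with ties counted as exceedances, so the minimum attainable p at 999
#' permutations is 0.001.
#'
#' @inheritParams indval_components
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for reproducibility.
#' @param combinations logical; also search combinations of site groups
#'   (off by default).
#' @param convention statistic convention, see \code{\link{indval_stat}}.
#' @return data frame of class \code{"indval_result"} with columns
#'   \code{species}, \code{group} (best group or \code{+}-joined
#'   combination), \code{A}, \code{B}, \code{stat}, \code{stat_raw}
#'   (the uncombined product \eqn{AB}) and \code{p}, sorted by group then
#'   decreasing statistic.
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(60, 3), 12, 5,
#'             dimnames = list(NULL, paste0("sp", 1:5)))
#' m[1:4, 1] <- m[1:4, 1] + 20   # plant an indicator of group "a"
#' g <- rep(c("a", "b", "c"), each = 4)
#' indval_test(m, g, n_perm = 99, seed = 42)
indval_test <- function(counts, groups, n_perm = 999, seed = NULL,
                        combinations = FALSE, size_corrected = TRUE,
                        convention = c("sqrt", "raw")) {
  convention <- match.arg(convention)
  counts <- as_abundance(counts)
  groups <- .check_groups(groups, nrow(counts))
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (any(table(groups) < 2L))
    warning("site group(s) with fewer than 2 sites: ",
            "permutation inference is degenerate")
  zero_sp <- colSums(counts) == 0
  if (any(zero_sp))
    warning("species with zero total abundance: ",
            paste(colnames(counts)[zero_sp], collapse = ", "))

  pres <- (counts > 0) * 1
  cand <- .candidate_sets(nlevels(groups), combinations)
  obs <- .indval_stat_matrix(counts, pres, groups, cand,
                             size_corrected, convention)
  best <- apply(obs$stat, 2, which.max)
  obs_stat <- obs$stat[cbind(best, seq_len(ncol(counts)))]

  exceed <- integer(ncol(counts))
  n <- nrow(counts)
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    ps <- .indval_stat_matrix(counts, pres, gp, cand,
                              size_corrected, convention)
    pmax_stat <- apply(ps$stat, 2, max)
    exceed <- exceed + (pmax_stat >= obs_stat - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  p[zero_sp] <- 1

  lab <- apply(cand, 1, function(v)
    paste(levels(groups)[v > 0], collapse = "+"))
  A <- obs$A[cbind(best, seq_len(ncol(counts)))]
  B <- obs$B[cbind(best, seq_len(ncol(counts)))]
  out <- data.frame(
    species = colnames(counts),
    group = lab[best],
    A = A, B = B,
    stat = obs_stat,
    stat_raw = A * B,
    p = p,
    stringsAsFactors = FALSE
  )
  out[zero_sp, c("A", "B", "stat", "stat_raw")] <- 0
  out <- out[order(out$group, -out$stat), ]
  rownames(out) <- NULL
  class(out) <- c("indval_result", "data.frame")
  out
}

#' @export
print.indval_result <- function(x, alpha = NULL, ...) {
  cat("Indicator species analysis (", nrow(x), " species)\n", sep = "")
  y <- as.data.frame(x)
  if (!is.null(alpha)) y <- y[y$p <= alpha, , drop = FALSE]
  print(y, digits = 3, ...)
  invisible(x)
}
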