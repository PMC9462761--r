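# Spearman rho with tie-corrected large-sample p (t approximation on the
# rank correlation). Avoids the exact-test warning cor.test() emits under
# ties; identical to cor.test(..., exact = FALSE) up to the edgeworth
# series it applies for small n without ties.
.spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(rho = rho, p = p)
}

#' Variance inflation factors
#'
#' VIF of each variable regressed on all the others,
#' \eqn{VIF_j = 1/(1-R_j^2)}; values above 10 flag severe
#' multicollinearity.
#'
#' @param env data frame or matrix of numeric variables (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(env) {
  env <- as.matrix(env)
  if (ncol(env) < 2L) stop("VIF needs at least two variables")
  v <- vapply(seq_len(ncol(env)), function(j) {
    ssy <- sum((env[, j] - mean(env[, j]))^2)
    if (ssy == 0) return(NA_real_)   # constant variable: VIF undefined
    fit <- stats::lm.fit(cbind(1, env[, -j, drop = FALSE]), env[, j])
    r2 <- 1 - sum(fit$residuals^2) / ssy
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(v, colnames(env))
}

#' Collinearity screen for explanatory variables
#'
#' Two-stage variable selection applied before constrained ordination.
#' First, while any pair of variables is highly rank-correlated
#' (Spearman \eqn{|r| \ge} \code{r_max} with \eqn{p <} \code{alpha}), one
#' variable of the offending set is dropped: the one with the largest mean
#' absolute Spearman correlation to all other remaining variables
#' (alphabetical tie-break). Second, while any variance inflation factor
#' exceeds \code{vif_max}, the variable with the highest VIF is dropped.
#' Every exclusion and its trigger is logged.
#'
#' @param env data frame of numeric explanatory variables (sites in rows).
#' @param r_max Spearman correlation threshold (default 0.7).
#' @param vif_max VIF threshold (default 10).
#' @param alpha significance level for the correlation screen.
#' @return list with \code{env} (the reduced data frame) and
#'   \code{log} (data frame of exclusions: variable, stage, detail).
#' @export
select_variables <- function(env, r_max = 0.7, vif_max = 10, alpha = 0.05) {
  env <- as.data.frame(env)
  if (ncol(env) < 2L) stop("need at least two variables")
  if (nrow(env) < 3L) stop("need at least three sites")
  log <- data.frame(variable = character(0), stage = character(0),
                    detail = character(0), stringsAsFactors = FALSE)

  # constant variables carry no information and break both screens
  const <- vapply(env, function(x) stats::sd(x) == 0, logical(1))
  for (v in names(env)[const])
    log <- rbind(log, data.frame(variable = v, stage = "constant",
                                 detail = "zero variance"))
  env <- env[!const]
  if (ncol(env) == 0L)
    stop("all variables excluded by the collinearity screen")

  repeat {
    vars <- names(env)
    if (length(vars) < 2L) break
    hit <- NULL
    rho_all <- matrix(0, length(vars), length(vars),
                      dimnames = list(vars, vars))
    for (i in seq_along(vars)) for (j in seq_along(vars)) {
      if (i < j) {
        sp <- .spearman(env[[i]], env[[j]])
        rho_all[i, j] <- rho_all[j, i] <- sp["rho"]
        if (is.finite(sp["rho"]) && abs(sp["rho"]) >= r_max &&
            is.finite(sp["p"]) && sp["p"] < alpha)
          hit <- rbind(hit, c(i, j))
      }
    }
    if (is.null(hit)) break
    involved <- sort(unique(as.vector(hit)))
    mean_abs <- vapply(involved, function(i)
      mean(abs(rho_all[i, -i]), na.rm = TRUE), numeric(1))
    # drop the variable most correlated overall; alphabetical tie-break
    ord <- order(-mean_abs, vars[involved])
    drop <- vars[involved[ord[1]]]
    partner <- vars[setdiff(unique(as.vector(
      hit[rowSums(hit == involved[ord[1]]) > 0, , drop = FALSE])),
      involved[ord[1]])][1]
    log <- rbind(log, data.frame(
      variable = drop, stage = "spearman",
      detail = sprintf("|rho| >= %.2f with %s", r_max, partner)))
    env[[drop]] <- NULL
  }

  repeat {
    if (ncol(env) < 2L) break
    v <- vif(env)
    if (all(v <= vif_max, na.rm = TRUE)) break
    drop <- names(which.max(v))
    log <- rbind(log, data.frame(
      variable = drop, stage = "vif",
      detail = sprintf("VIF = %.2f > %.1f", v[drop], vif_max)))
    env[[drop]] <- NULL
  }

  if (ncol(env) == 0L)
    stop("all variables excluded by the collinearity screen")
  list(env = env, log = log)
}

#' Bray-Curtis dissimilarity
#'
#' Pairwise Bray-Curtis dissimilarity between sites,
#' \eqn{d_{ij} = \sum_s |x_{is}-x_{js}| / \sum_s (x_{is}+x_{js})},
#' optionally after square-root transforming the counts to reduce the
#' weight of the most abundant species.
#'
#' @param counts site-by-species abundance matrix without all-zero rows.
#' @param transform \code{"sqrt"} (default, as used for the community
#'   ordination) or \code{"none"}.
#' @return object of class \code{"dist"}.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(1, 2), b = c(2, 2)), transform = "none")  # 1/7
bray_curtis <- function(counts, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  counts <- as_abundance(counts)
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero site row(s): ",
         paste(rownames(counts)[zero], collapse = ", "))
  if (transform == "sqrt") counts <- sqrt(counts)
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- sum(abs(counts[i, ] - counts[j, ]))
    den <- sum(counts[i, ] + counts[j, ])
    d[i, j] <- d[j, i] <- num / den
  }
  stats::as.dist(d)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a dissimilarity matrix on explanatory
#' variables: the Gower-centred matrix \eqn{-\tfrac12 J D^2 J} is
#' eigen-decomposed into principal coordinates, the coordinates are
#' regressed on the (centred) explanatory variables, and the fitted values
#' are eigen-decomposed into the constrained axes. Axes with negative
#' principal-coordinate eigenvalues (possible for semi-metric
#' dissimilarities such as Bray-Curtis) are excluded from the regression
#' step by default and their total inertia is reported; a square-root
#' distance correction is available instead. Inertia is scaled by
#' \eqn{n-1} so that, for Euclidean distances on raw data, eigenvalues
#' equal those of classical redundancy analysis.
#'
#' @param d a \code{"dist"} object (e.g. from \code{\link{bray_curtis}}).
#' @param env data frame of explanatory variables, rows aligned with the
#'   sites of \code{d}.
#' @param sqrt_correction logical; take \eqn{\sqrt{d}} before the
#'   analysis to make Bray-Curtis embeddable (default \code{FALSE}).
#' @return object of class \code{"dbrda"}: a list with constrained
#'   (\code{eig_constrained}) and residual (\code{eig_unconstrained})
#'   eigenvalues, \code{negative_inertia}, \code{total_inertia},
#'   \code{proportion} (per constrained axis), site scores (\code{lc}
#'   fitted/linear-combination and \code{wa} weighted-average),
#'   \code{biplot} correlations of variables with the axes, the adjusted
#'   \eqn{R^2}, and the components needed by
#'   \code{\link{dbrda_permutation_test}}.
#' @export
dbrda <- function(d, env, sqrt_correction = FALSE) {
  if (!inherits(d, "dist")) stop("'d' must be a dist object")
  env <- as.data.frame(env)
  n <- attr(d, "Size")
  if (nrow(env) != n) stop("rows of 'env' must match the sites of 'd'")
  if (n <= ncol(env) + 1L)
    stop("need more sites than explanatory variables plus one")
  if (sqrt_correction) d <- sqrt(d)

  D2 <- as.matrix(d)^2
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% D2 %*% J
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  neg_inertia <- sum(abs(e$values[e$values < -tol])) / (n - 1)
  X <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                               sum(pos))
  rownames(X) <- attr(d, "Labels")

  Z <- stats::model.matrix(~ ., data = env)[, -1, drop = FALSE]
  Z <- scale(Z, center = TRUE, scale = FALSE)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z))
    stop("explanatory variables are rank deficient after selection")
  fit <- qr.fitted(qrZ, X)
  res <- X - fit

  q <- qrZ$rank
  sv <- svd(fit)
  keep <- sv$d > max(sv$d, 1) * 1e-10
  keep[seq_along(keep) > q] <- FALSE
  eig_c <- (sv$d[keep])^2 / (n - 1)
  axes <- sv$v[, keep, drop = FALSE]
  lc <- fit %*% axes
  wa <- X %*% axes
  colnames(lc) <- colnames(wa) <- names(eig_c) <-
    paste0("dbRDA", seq_along(eig_c))

  er <- svd(res)$d^2 / (n - 1)
  er <- er[er > max(er, 1e-12) * 1e-10]
  total <- sum(e$values[pos]) / (n - 1)

  Zs <- scale(Z)
  biplot <- stats::cor(Zs, lc)
  r2 <- sum(eig_c) / total
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - q)

  structure(list(
    eig_constrained = eig_c,
    eig_unconstrained = er,
    negative_inertia = neg_inertia,
    total_inertia = total,
    proportion = eig_c / total,
    lc = lc, wa = wa, biplot = biplot,
    r2 = r2, r2_adj = r2_adj,
    X = X, Z = Z, qrZ = qrZ, env = env, n = n, rank_env = q
  ), class = "dbrda")
}

#' @export
print.dbrda <- function(x, ...) {
  cat("Distance-based redundancy analysis\n")
  cat(sprintf("  sites: %d  constrained axes: %d  R2: %.4f (adj %.4f)\n",
              x$n, length(x$eig_constrained), x$r2, x$r2_adj))
  cat(sprintf("  constrained inertia: %.4f of %.4f (%.2f%%)\n",
              sum(x$eig_constrained), x$total_inertia, 100 * x$r2))
  if (x$negative_inertia > 0)
    cat(sprintf("  negative (imaginary) inertia discarded: %.4f\n",
                x$negative_inertia))
  cat("  axis proportions (%):",
      paste(sprintf("%.2f", 100 * x$proportion), collapse = " "), "\n")
  invisible(x)
}

# Pseudo-F of a fitted projection: (SS_fit/df_fit) / (SS_res/df_res).
.pseudo_f <- function(ss_fit, df_fit, ss_res, df_res) {
  (ss_fit / df_fit) / (ss_res / df_res)
}

#' Permutation tests for distance-based redundancy analysis
#'
#' Significance of the fitted ordination by free permutation of the site
#' rows of the principal-coordinate response. \code{by = "global"} tests
#' the whole model; \code{by = "axis"} tests each constrained axis
#' (pseudo-F of its eigenvalue over the residual mean square);
#' \code{by = "margin"} tests each explanatory variable with all others
#' retained (partial pseudo-F). p-values use the \eqn{(b+1)/(N+1)}
#' estimator.
#'
#' @param object a fitted \code{\link{dbrda}}.
#' @param by \code{"global"}, \code{"axis"} or \code{"margin"}.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return data frame with one row per tested term/axis: sum of squares,
#'   pseudo-F, p, and (for margins) the marginal adjusted \eqn{R^2} of
#'   the variable fitted alone.
#' @export
dbrda_permutation_test <- function(object, by = c("global", "axis", "margin"),
                                   n_perm = 999, seed = NULL) {
  by <- match.arg(by)
  if (!inherits(object, "dbrda")) stop("'object' must be a dbrda fit")
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  X <- object$X; qrZ <- object$qrZ; n <- object$n
  q <- object$rank_env
  df_res <- n - 1L - q

  ss <- function(m) sum(m^2)
  fit_ss <- function(Y) ss(qr.fitted(qrZ, Y))

  if (by == "global") {
    obs_fit <- fit_ss(X)
    obs_res <- ss(X) - obs_fit
    f_obs <- .pseudo_f(obs_fit, q, obs_res, df_res)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Xp <- X[sample.int(n), , drop = FALSE]
      pf <- fit_ss(Xp)
      fp <- .pseudo_f(pf, q, ss(Xp) - pf, df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    return(data.frame(term = "model", df = q,
                      ss = obs_fit / (n - 1),
                      pseudo_f = f_obs,
                      p = (exceed + 1) / (n_perm + 1)))
  }

  if (by == "axis") {
    eig <- object$eig_constrained * (n - 1)
    obs_res <- ss(X) - fit_ss(X)
    f_obs <- eig / (obs_res / df_res)
    exceed <- integer(length(eig))
    for (b in seq_len(n_perm)) {
      Xp <- X[sample.int(n), , drop = FALSE]
      fp <- qr.fitted(qrZ, Xp)
      dp <- svd(fp, nu = 0, nv = 0)$d^2
      resp <- ss(Xp) - sum(dp)
      k <- seq_along(eig)
      dp <- c(dp, rep(0, length(eig)))[k]
      fperm <- dp / (resp / df_res)
      exceed <- exceed + (fperm >= f_obs - 1e-12)
    }
    return(data.frame(axis = names(eig), df = 1,
                      eigenvalue = object$eig_constrained,
                      proportion = object$proportion,
                      pseudo_f = f_obs,
                      p = (exceed + 1) / (n_perm + 1)))
  }

  # by == "margin": each term against the model with all others retained
  Z <- object$Z
  terms <- colnames(Z)
  full_fit <- fit_ss(X)
  full_res <- ss(X) - full_fit
  out <- lapply(terms, function(tm) {
    Zr <- Z[, setdiff(terms, tm), drop = FALSE]
    qr_r <- if (ncol(Zr) > 0L) qr(Zr) else NULL
    red_fit <- function(Y) if (is.null(qr_r)) 0 else ss(qr.fitted(qr_r, Y))
    df_t <- q - (if (is.null(qr_r)) 0L else qr_r$rank)
    obs_ss <- full_fit - red_fit(X)
    f_obs <- .pseudo_f(obs_ss, df_t, full_res, df_res)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Xp <- X[sample.int(n), , drop = FALSE]
      pf_full <- fit_ss(Xp)
      pss <- pf_full - red_fit(Xp)
      fp <- .pseudo_f(pss, df_t, ss(Xp) - pf_full, df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    # marginal fit of the variable alone, for the adjusted R2 column
    qr_1 <- qr(Z[, tm, drop = FALSE])
    r2_1 <- ss(qr.fitted(qr_1, X)) / ss(X)
    r2_1_adj <- 1 - (1 - r2_1) * (n - 1) / (n - 1 - qr_1$rank)
    data.frame(term = tm, df = df_t,
               ss = obs_ss / (n - 1),
               r2_adj_marginal = r2_1_adj,
               pseudo_f = f_obs,
               p = (exceed + 1) / (n_perm + 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
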