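#' Log transform with zero offset
#'
#' Natural-log transform used to put environmental variables on comparable
#' scales; values equal to 0 receive a small additive offset first (the
#' transform is strictly increasing, so rank-based statistics are
#' unaffected by the offset choice).
#'
#' @param x numeric vector, non-negative.
#' @param offset additive offset applied to zeros (default 0.01).
#' @return log-transformed vector.
#' @export
log_offset <- function(x, offset = 0.01) {
  if (any(x < 0, na.rm = TRUE)) stop("log transform requires x >= 0")
  log(ifelse(x == 0, offset, x))
}

#' Spearman cross-correlation screen
#'
#' Pairwise Spearman rank correlations among environmental variables
#' (land use, habitat diversity, disturbance index, productivity, ...),
#' with tie-corrected p-values and a significance mask at \code{alpha}.
#' Variables are optionally log-transformed first; since the transform is
#' strictly monotone the rank correlations are unchanged, and the option
#' exists to mirror the conventional workflow.
#'
#' @param env data frame of numeric variables (>= 4 sites).
#' @param log_transform logical; log-transform (with zero offset) before
#'   ranking.
#' @param alpha significance level for the mask (default 0.05).
#' @return list of class \code{"correlation_screen"}: matrices
#'   \code{rho}, \code{p} and logical \code{significant}; constant
#'   variables yield \code{NA} entries.
#' @export
spearman_screen <- function(env, log_transform = TRUE, alpha = 0.05) {
  env <- as.data.frame(env)
  if (nrow(env) < 4L) stop("need at least four sites")
  num <- vapply(env, is.numeric, logical(1))
  env <- env[num]
  if (ncol(env) < 2L) stop("need at least two numeric variables")
  if (log_transform) {
    # only non-negative variables are log-scaled; ranks are unaffected
    # either way, so mixed tables remain comparable
    nonneg <- vapply(env, function(x) all(x >= 0, na.rm = TRUE), logical(1))
    env[nonneg] <- lapply(env[nonneg], log_offset)
  }
  vars <- names(env)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sp <- .spearman(env[[i]], env[[j]])
    rho[i, j] <- rho[j, i] <- sp["rho"]
    p[i, j] <- p[j, i] <- sp["p"]
  }
  sig <- is.finite(p) & p < alpha
  diag(sig) <- FALSE   # self-correlation is not an association
  structure(list(rho = rho, p = p, significant = sig, alpha = alpha),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Spearman correlation screen (alpha =", x$alpha, ")\n")
  m <- format(round(x$rho, 2))
  m[x$significant] <- paste0(m[x$significant], "*")
  diag(m) <- "1"
  print(m, quote = FALSE, ...)
  invisible(x)
}

#' Long-format correlation table
#'
#' @param screen a \code{\link{spearman_screen}} result.
#' @return data frame with columns \code{variable1}, \code{variable2},
#'   \code{rho}, \code{p}, \code{significant} (upper triangle only).
#' @export
correlation_table <- function(screen) {
  stopifnot(inherits(screen, "correlation_screen"))
  vars <- colnames(screen$rho)
  ij <- which(upper.tri(screen$rho), arr.ind = TRUE)
  data.frame(
    variable1 = vars[ij[, 1]],
    variable2 = vars[ij[, 2]],
    rho = screen$rho[ij],
    p = screen$p[ij],
    significant = screen$significant[ij]
  )
}

#' Permutation trend test of an assemblage metric along the disturbance
#' gradient
#'
#' Association between a per-site assemblage metric (e.g. total abundance
#' or equitability) and the disturbance index: Spearman rho and the
#' least-squares slope of metric on \eqn{\log(IDI)}, with a two-sided
#' permutation p-value obtained by shuffling the metric across sites.
#' This is a distribution-free trend test for direction-of-effect
#' recovery; it does not fit the mixed-effects models a full field
#' analysis would use for basin-structured data, and makes no claim to
#' reproduce their coefficients.
#'
#' @param metric numeric per-site metric.
#' @param idi numeric per-site disturbance index (positive after offset).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with \code{slope} (of metric on log IDI), \code{rho},
#'   \code{p} (two-sided permutation p on rho), \code{n}.
#' @export
trend_test <- function(metric, idi, n_perm = 999, seed = NULL) {
  if (length(metric) != length(idi))
    stop("'metric' and 'idi' must have equal length")
  ok <- is.finite(metric) & is.finite(idi)
  metric <- metric[ok]; idi <- idi[ok]
  n <- length(metric)
  if (n < 5L) stop("need at least five sites")
  if (stats::sd(metric) == 0 || stats::sd(idi) == 0)
    stop("zero variance in 'metric' or 'idi'")
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  lidi <- log_offset(idi)
  slope <- stats::cov(metric, lidi) / stats::var(lidi)
  rho_obs <- stats::cor(rank(metric), rank(lidi))
  r_idi <- rank(lidi)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rp <- stats::cor(rank(metric[sample.int(n)]), r_idi)
    exceed <- exceed + (abs(rp) >= abs(rho_obs) - 1e-12)
  }
  list(slope = slope, rho = rho_obs,
       p = (exceed + 1) / (n_perm + 1), n = n)
}
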