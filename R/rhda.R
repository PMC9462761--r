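#' Default RHDA scoring configuration
#'
#' The rapid habitat diversity assessment (RHDA) protocol scores 22 visual
#' parameters per stream reach; the first 10 rate signals of human
#' pressure in the reach and the remaining 12 rate environmental
#' characteristics of the site. Per-parameter scales vary between protocol
#' revisions, so the configuration is user-overridable; the default scores
#' every parameter on 0-5.
#'
#' @param param_max numeric vector of 22 per-parameter maxima.
#' @param labels optional character vector of 22 parameter labels.
#' @return list with elements \code{param_max} and \code{labels}.
#' @export
rhda_config <- function(param_max = rep(5, 22),
                        labels = sprintf("p%02d", 1:22)) {
  if (length(param_max) != 22L || length(labels) != 22L)
    stop("RHDA configuration requires exactly 22 parameters")
  if (any(!is.finite(param_max)) || any(param_max <= 0))
    stop("per-parameter maxima must be positive")
  list(param_max = as.numeric(param_max), labels = as.character(labels))
}

#' Validate one RHDA observer sheet
#'
#' Checks a single observer's sheet of 22 parameter scores against the
#' scoring configuration. The validator reports, never throws: an empty
#' result means the sheet is valid.
#'
#' @param sheet numeric vector of parameter scores (one observer).
#' @param config an \code{\link{rhda_config}}.
#' @return character vector of violations (empty if valid), each naming
#'   the offending parameter.
#' @export
#' @examples
#' validate_sheet(rep(3, 22))            # character(0)
#' validate_sheet(c(7, rep(3, 21)))      # score above the parameter max
validate_sheet <- function(sheet, config = rhda_config()) {
  violations <- character(0)
  if (length(sheet) != 22L) {
    violations <- c(violations,
                    sprintf("expected 22 parameters, got %d", length(sheet)))
    return(violations)
  }
  sheet <- as.numeric(sheet)
  for (i in seq_len(22L)) {
    if (!is.finite(sheet[i]))
      violations <- c(violations,
                      sprintf("parameter %s: non-numeric or missing score",
                              config$labels[i]))
    else if (sheet[i] < 0)
      violations <- c(violations,
                      sprintf("parameter %s: negative score %g",
                              config$labels[i], sheet[i]))
    else if (sheet[i] > config$param_max[i])
      violations <- c(violations,
                      sprintf("parameter %s: score %g exceeds maximum %g",
                              config$labels[i], sheet[i],
                              config$param_max[i]))
  }
  violations
}

#' Total habitat-diversity score for one site
#'
#' Each observer sheet totals its 22 parameter scores; with several
#' observers the site score is the arithmetic mean of the sheet totals
#' (which is how fractional site totals such as 85.6 arise).
#'
#' @param sheets a numeric vector (one observer), a list of numeric
#'   vectors, or a matrix with one row per observer.
#' @param config an \code{\link{rhda_config}} shared by all sheets.
#' @return list with \code{total} (mean total score) and
#'   \code{n_observers}.
#' @export
#' @examples
#' score_rhda(list(rep(3, 22), rep(4, 22)))  # total 77, two observers
score_rhda <- function(sheets, config = rhda_config()) {
  if (is.matrix(sheets))
    sheets <- lapply(seq_len(nrow(sheets)), function(i) sheets[i, ])
  if (!is.list(sheets)) sheets <- list(sheets)
  if (length(sheets) == 0L) stop("at least one observer sheet is required")
  for (k in seq_along(sheets)) {
    v <- validate_sheet(sheets[[k]], config)
    if (length(v) > 0L)
      stop("invalid RHDA sheet ", k, ": ", v[1])
  }
  totals <- vapply(sheets, function(s) sum(as.numeric(s)), numeric(1))
  list(total = mean(totals), n_observers = length(sheets))
}

#' Score RHDA sheets for many sites
#'
#' @param sheets data frame with columns \code{site_id},
#'   \code{observer_id} and \code{p01}...\code{p22}.
#' @param config an \code{\link{rhda_config}}.
#' @return data frame with columns \code{site_id}, \code{rhda} (mean total)
#'   and \code{n_observers}.
#' @export
score_rhda_table <- function(sheets, config = rhda_config()) {
  cols <- sprintf("p%02d", 1:22)
  stopifnot(is.data.frame(sheets), "site_id" %in% names(sheets))
  if (!all(cols %in% names(sheets)))
    stop("sheet table must contain columns p01...p22")
  split_rows <- split(seq_len(nrow(sheets)), sheets$site_id)
  out <- lapply(names(split_rows), function(s) {
    m <- as.matrix(sheets[split_rows[[s]], cols, drop = FALSE])
    sc <- score_rhda(m, config)
    data.frame(site_id = s, rhda = sc$total, n_observers = sc$n_observers)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
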