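# Eleven disturbance categories tallied along the in-stream transects, in
# protocol order.
DISTURBANCE_CATEGORIES <- c(
  "buildings", "channel_revetment", "pavement", "roads", "pipes",
  "trash_landfill", "parks_lawns", "row_crop_agriculture", "pasture",
  "logging", "mining"
)

PROXIMITY_CODES <- c("0", "B", "C", "P")

#' Proximity weights for local disturbance tallies
#'
#' Weights applied to the proximity codes of a disturbance tally before
#' averaging over transects. Code \code{B} marks a disturbance inside the
#' channel or on the margin, \code{C} within 10 m of the channel, and
#' \code{P} beyond 10 m; closer disturbance never weighs less. The defaults
#' follow the W1_hall weighting convention used in riparian human-influence
#' assessments.
#'
#' @param w_B weight for in-channel/margin observations (default 1.5).
#' @param w_C weight for observations within 10 m (default 1.0).
#' @param w_P weight for observations beyond 10 m (default 0.667).
#' @return A named list of class \code{"proximity_weights"}.
#' @export
#' @examples
#' proximity_weights()
proximity_weights <- function(w_B = 1.5, w_C = 1.0, w_P = 0.667) {
  w <- c(w_B = w_B, w_C = w_C, w_P = w_P)
  if (any(!is.finite(w)) || any(w < 0))
    stop("proximity weights must be finite and non-negative")
  if (!(w_B >= w_C && w_C >= w_P))
    stop("proximity weights must satisfy w_B >= w_C >= w_P ",
         "(closer disturbance never weighs less)")
  structure(list(w_B = w_B, w_C = w_C, w_P = w_P),
            class = "proximity_weights")
}

#' Construct a local disturbance tally
#'
#' A tally records, for each of the 11 disturbance categories and each
#' cross-channel transect of a sampled reach, the proximity code of the
#' observed disturbance: \code{"0"} (absent), \code{"B"} (in the channel or
#' on the margin), \code{"C"} (closer than 10 m) or \code{"P"} (beyond
#' 10 m). The study protocol uses 5 transects per reach.
#'
#' @param grid character matrix of proximity codes, categories in rows and
#'   transects in columns. \code{NA} cells are treated as absent, with a
#'   warning.
#' @param categories character vector of the 11 category names; defaults to
#'   the protocol order in \code{DISTURBANCE_CATEGORIES}.
#' @return A \code{"disturbance_tally"} object.
#' @export
#' @examples
#' g <- matrix("0", 11, 5)
#' g[1, ] <- "B"   # buildings on the margin at every transect
#' disturbance_tally(g)
disturbance_tally <- function(grid, categories = DISTURBANCE_CATEGORIES) {
  grid <- as.matrix(grid)
  if (length(categories) != 11L)
    stop("a disturbance tally has exactly 11 categories, got ",
         length(categories))
  if (nrow(grid) != 11L)
    stop("tally grid must have 11 rows (one per category), got ", nrow(grid))
  if (ncol(grid) < 1L)
    stop("tally grid must have at least one transect")
  if (anyNA(grid)) {
    warning("missing tally cells treated as absent ('0')")
    grid[is.na(grid)] <- "0"
  }
  mode(grid) <- "character"
  bad <- which(matrix(!(grid %in% PROXIMITY_CODES), nrow(grid)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "unknown proximity code '%s' at category %d ('%s'), transect %d",
      grid[bad[1, 1], bad[1, 2]], bad[1, 1], categories[bad[1, 1]],
      bad[1, 2]))
  dimnames(grid) <- list(categories, paste0("t", seq_len(ncol(grid))))
  structure(list(grid = grid, categories = categories,
                 n_transects = ncol(grid)),
            class = "disturbance_tally")
}

#' Local Disturbance Index (LDI)
#'
#' Proximity-weighted tally of human disturbance observed along the
#' transects of a sampled reach (the W1_hall metric): each category
#' contributes the mean, over transects, of the weight of its proximity
#' code (absence contributing 0), and the LDI is the sum of the 11 category
#' contributions.
#'
#' @param tally a \code{\link{disturbance_tally}}.
#' @param weights a \code{\link{proximity_weights}} object.
#' @return Non-negative scalar; 0 iff no disturbance was recorded.
#' @export
#' @examples
#' g <- matrix("0", 11, 5); g[1, ] <- "B"
#' compute_ldi(disturbance_tally(g))  # 1.5
compute_ldi <- function(tally, weights = proximity_weights()) {
  if (!inherits(tally, "disturbance_tally"))
    tally <- disturbance_tally(tally)
  if (!inherits(weights, "proximity_weights"))
    stop("'weights' must be a proximity_weights object")
  wmap <- c("0" = 0, B = weights$w_B, C = weights$w_C, P = weights$w_P)
  w <- matrix(wmap[tally$grid], nrow = 11L)
  sum(rowMeans(w))
}

#' Catchment Disturbance Index (CDI)
#'
#' Weighted sum of catchment land-use percentages,
#' \deqn{CDI = 4 \times \%urban + 2 \times \%(agriculture{+}pasture),}
#' ranging from 0 (no human land use in the catchment) to 400 (catchment
#' entirely urban).
#'
#' @param urban_pct percentage of the catchment under urban land use, 0-100.
#' @param agri_pasture_pct percentage under agriculture, pasture and
#'   silviculture (pooled), 0-100.
#' @return CDI value(s) in [0, 400]. Vectorised over sites.
#' @export
#' @examples
#' compute_cdi(100, 0)  # 400
#' compute_cdi(20, 30)  # 140
compute_cdi <- function(urban_pct, agri_pasture_pct) {
  .check_pct(urban_pct, "urban_pct")
  .check_pct(agri_pasture_pct, "agri_pasture_pct")
  if (any(urban_pct + agri_pasture_pct > 100 + 1e-8))
    stop("urban_pct + agri_pasture_pct exceeds 100%")
  4 * urban_pct + 2 * agri_pasture_pct
}

.check_pct <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop("'", name, "' must lie in [0, 100]")
  invisible(x)
}

#' Integrated Disturbance Index (IDI)
#'
#' Euclidean combination of the normalised local and catchment disturbance
#' indices,
#' \deqn{IDI = \sqrt{(LDI/5)^2 + (CDI/300)^2},}
#' summarising human pressure at the site. Values near 1 indicate major
#' disturbance in the channel, riparian zone and/or catchment. With the
#' default \code{"cdi300"} normalisation the raw index can exceed 1 (CDI
#' reaches 400); both the raw value and a value clamped to [0, 1] are
#' reported. The alternative \code{"cdi400"} normalisation,
#' \eqn{\sqrt{((LDI/5)^2 + (CDI/400)^2)/2}}, bounds the catchment term at 1
#' and rescales so a maximally disturbed catchment with LDI = 5 scores 1.
#'
#' @param ldi local disturbance index, non-negative. Vectorised.
#' @param cdi catchment disturbance index in [0, 400]. Vectorised.
#' @param normalization \code{"cdi300"} (default) or \code{"cdi400"}.
#' @param thresholds classification thresholds, see
#'   \code{\link{classify_disturbance}}.
#' @return A data frame with columns \code{ldi}, \code{cdi}, \code{idi},
#'   \code{idi_clamped} and \code{level}.
#' @export
#' @examples
#' compute_idi(3, 150)  # idi = sqrt(0.36 + 0.25) ~ 0.781, HIGH
compute_idi <- function(ldi, cdi, normalization = c("cdi300", "cdi400"),
                        thresholds = c(low = 0.10, high = 0.20)) {
  normalization <- match.arg(normalization)
  if (any(!is.finite(ldi)) || any(ldi < 0))
    stop("'ldi' must be finite and non-negative")
  if (any(!is.finite(cdi)) || any(cdi < 0) || any(cdi > 400))
    stop("'cdi' must lie in [0, 400]")
  idi <- switch(normalization,
    cdi300 = sqrt((ldi / 5)^2 + (cdi / 300)^2),
    cdi400 = sqrt(((ldi / 5)^2 + (cdi / 400)^2) / 2)
  )
  data.frame(
    ldi = ldi, cdi = cdi, idi = idi,
    idi_clamped = pmin(idi, 1),
    level = classify_disturbance(idi, thresholds)
  )
}

#' Classify sites into disturbance levels
#'
#' Three-level classification of the IDI: low disturbance (conditions
#' closer to natural), medium (altered sites) and high (extremely impacted
#' sites). The published bands (< 0.09 low, 0.10-0.19 medium, > 0.2 high)
#' leave the gaps [0.09, 0.10) and [0.19, 0.20] unassigned; the bands are
#' closed here as LOW < 0.10 <= MEDIUM < 0.20 <= HIGH so that every value
#' is classifiable. Thresholds are overridable.
#'
#' @param idi numeric vector of IDI values, non-negative.
#' @param thresholds named numeric vector \code{c(low=, high=)}: lower
#'   bounds of the MEDIUM and HIGH bands.
#' @return factor with levels \code{LOW}, \code{MEDIUM}, \code{HIGH}.
#' @export
#' @examples
#' classify_disturbance(c(0.049, 0.175, 0.814))
classify_disturbance <- function(idi, thresholds = c(low = 0.10, high = 0.20)) {
  if (any(!is.finite(idi)) || any(idi < 0))
    stop("'idi' must be finite and non-negative")
  if (!all(c("low", "high") %in% names(thresholds)) ||
      thresholds[["low"]] >= thresholds[["high"]])
    stop("'thresholds' must name low < high")
  cut(idi, breaks = c(-Inf, thresholds[["low"]], thresholds[["high"]], Inf),
      labels = c("LOW", "MEDIUM", "HIGH"), right = FALSE)
}

#' Score disturbance for a set of sites
#'
#' Convenience wrapper running the full disturbance pipeline per site:
#' LDI from the tallies, CDI from the land-use profile, and the integrated
#' index with its three-level classification.
#'
#' @param land_use data frame with columns \code{site_id},
#'   \code{urban_pct}, \code{agri_pasture_pct} (and optionally
#'   \code{forest_pct}).
#' @param tallies named list of \code{\link{disturbance_tally}} objects,
#'   one per site (names matching \code{site_id}); \code{NULL} scores the
#'   catchment component only (LDI = 0).
#' @inheritParams compute_idi
#' @param weights a \code{\link{proximity_weights}} object.
#' @return data frame with one row per site: \code{site_id}, \code{ldi},
#'   \code{cdi}, \code{idi}, \code{idi_clamped}, \code{level}.
#' @export
score_disturbance <- function(land_use, tallies = NULL,
                              weights = proximity_weights(),
                              normalization = c("cdi300", "cdi400"),
                              thresholds = c(low = 0.10, high = 0.20)) {
  stopifnot(is.data.frame(land_use),
            all(c("site_id", "urban_pct", "agri_pasture_pct") %in%
                  names(land_use)))
  if (anyDuplicated(land_use$site_id))
    stop("duplicate site_id in land_use table")
  ldi <- if (is.null(tallies)) {
    rep(0, nrow(land_use))
  } else {
    missing <- setdiff(land_use$site_id, names(tallies))
    if (length(missing) > 0L)
      stop("no tally for site(s): ", paste(missing, collapse = ", "))
    vapply(as.character(land_use$site_id),
           function(s) compute_ldi(tallies[[s]], weights), numeric(1))
  }
  cdi <- compute_cdi(land_use$urban_pct, land_use$agri_pasture_pct)
  out <- compute_idi(ldi, cdi, normalization, thresholds)
  cbind(site_id = land_use$site_id, out)
}
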