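#' Validate a site-by-species abundance matrix
#'
#' @param counts matrix or data frame of non-negative counts, sites in
#'   rows, species in columns, with unique dimnames.
#' @return the validated numeric matrix (invisibly usable downstream).
#' @keywords internal
as_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("abundance matrix must be numeric")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("abundance matrix needs at least one site and one species")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("abundance matrix has negative or non-finite cells")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sp", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate site ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate species ids")
  counts
}

#' Diversity profile of one site
#'
#' Assemblage-structure summary of a single site's species counts:
#' species richness, total abundance, Shannon diversity
#' \eqn{H = -\sum p_i \log p_i} (natural log by default), Simpson
#' dominance \eqn{D = \sum p_i^2}, Pielou equitability
#' \eqn{J = H / \log S} (undefined for a single-species site, returned as
#' \code{NA}), and, when species origins are supplied, the non-native to
#' native abundance ratio NNAbu (\code{NA} when no native individuals
#' occur).
#'
#' @param counts numeric vector of one site's species counts (named by
#'   species), at least one positive.
#' @param origin optional character/factor vector aligned with
#'   \code{counts}, values \code{"NATIVE"}/\code{"NON_NATIVE"}.
#' @param base logarithm base for Shannon diversity (default
#'   \code{exp(1)}, i.e. nats).
#' @return list with \code{richness}, \code{abundance}, \code{shannon},
#'   \code{simpson_dominance}, \code{equitability}, \code{nnabu}.
#' @export
#' @examples
#' diversity_profile(c(a = 1, b = 2, c = 3))
diversity_profile <- function(counts, origin = NULL, base = exp(1)) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite")
  total <- sum(counts)
  if (total <= 0) stop("site has no individuals (all-zero counts)")
  present <- counts > 0
  S <- sum(present)
  p <- counts[present] / total
  H <- -sum(p * log(p, base = base))
  D <- sum(p^2)
  J <- if (S > 1L) H / log(S, base = base) else NA_real_
  nnabu <- NA_real_
  if (!is.null(origin)) {
    origin <- as.character(origin)
    if (length(origin) != length(counts))
      stop("'origin' must align with 'counts'")
    native <- sum(counts[origin == "NATIVE"])
    nonnat <- sum(counts[origin == "NON_NATIVE"])
    nnabu <- if (native > 0) nonnat / native else NA_real_
  }
  list(richness = S, abundance = total, shannon = H,
       simpson_dominance = D, equitability = J, nnabu = nnabu)
}

#' Diversity profiles for all sites of an abundance matrix
#'
#' @param counts site-by-species abundance matrix.
#' @param attrs optional species attribute table (data frame with columns
#'   \code{species_id} and \code{origin}); used for NNAbu.
#' @inheritParams diversity_profile
#' @return data frame with one row per site.
#' @export
diversity_table <- function(counts, attrs = NULL, base = exp(1)) {
  counts <- as_abundance(counts)
  origin <- NULL
  if (!is.null(attrs)) {
    stopifnot(all(c("species_id", "origin") %in% names(attrs)))
    missing <- setdiff(colnames(counts), attrs$species_id)
    if (length(missing) > 0L)
      stop("species without origin attribute: ",
           paste(utils::head(missing, 3), collapse = ", "))
    origin <- attrs$origin[match(colnames(counts), attrs$species_id)]
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    as.data.frame(diversity_profile(counts[i, ], origin, base))
  })
  out <- cbind(site_id = rownames(counts), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Species restrictedness
#'
#' Occupancy-based rarity metric at the regional scale: for species
#' \eqn{i} occupying \eqn{K_i} of \eqn{K} sites,
#' \eqn{R_i = 1 - K_i/K}. A species found at a single site of 25 scores
#' 0.96; a ubiquitous species scores 0. Abundances (including relative
#' abundances) are binarised at > 0, so the metric depends on occupancy
#' only.
#'
#' @param counts site-by-species abundance (or presence/absence) matrix.
#' @return named numeric vector of per-species restrictedness in [0, 1].
#' @export
#' @examples
#' m <- matrix(0, 25, 2, dimnames = list(NULL, c("rare", "common")))
#' m[1, "rare"] <- 4; m[, "common"] <- 1
#' restrictedness(m)  # rare = 0.96, common = 0
restrictedness <- function(counts) {
  counts <- as_abundance(counts)
  occ <- colSums(counts > 0)
  if (any(occ == 0))
    warning("species never observed (zero total count): ",
            paste(colnames(counts)[occ == 0], collapse = ", "))
  r <- 1 - occ / nrow(counts)
  names(r) <- colnames(counts)
  r
}
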