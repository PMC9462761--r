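#' Pipeline configuration
#'
#' Bundles the thresholds and constants of the analysis workflow:
#' proximity weights, IDI normalisation and classification thresholds,
#' the collinearity screen (Spearman r >= 0.7, VIF > 10), the
#' significance level (0.05), the number of permutations (999), and the
#' seed controlling every stochastic step.
#'
#' @param weights \code{\link{proximity_weights}}.
#' @param normalization IDI normalisation variant, see
#'   \code{\link{compute_idi}}.
#' @param thresholds IDI classification thresholds.
#' @param r_max Spearman threshold of the variable screen.
#' @param vif_max VIF threshold.
#' @param alpha significance level.
#' @param n_perm permutations for every permutation test.
#' @param seed integer seed.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(weights = proximity_weights(),
                            normalization = c("cdi300", "cdi400"),
                            thresholds = c(low = 0.10, high = 0.20),
                            r_max = 0.7, vif_max = 10, alpha = 0.05,
                            n_perm = 999, seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(r_max > 0, vif_max > 0, alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(weights = weights, normalization = normalization,
                 thresholds = thresholds, r_max = r_max,
                 vif_max = vif_max, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

# 32-bit FNV-1a hash of a string, reported as 8 hex digits; used to
# fingerprint the configuration in the run manifest.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * p mod 2^32, split to stay within exact double arithmetic
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# environment variables considered for ordination/correlation, in
# preference order; whichever are present in the site table are used
.ENV_VARS <- c("ph", "temperature", "dissolved_oxygen", "conductivity",
               "tds", "turbidity", "ammonia", "total_phosphorus",
               "idi", "rhda")

#' Run the full disturbance-response workflow
#'
#' Orders the stages of the analysis: disturbance scoring and
#' classification, correlation screen of the environmental variables,
#' then - when abundance data are supplied - Bray-Curtis dbRDA with
#' collinearity pre-selection and permutation tests, indicator species
#' analysis across the disturbance levels, restrictedness, diversity
#' profiles, and permutation trend tests of each assemblage metric
#' against the disturbance index. All result tables are written to
#' \code{out_dir} as delimited text together with a JSON run manifest
#' (configuration fingerprint, seed, versions, stage log); identical
#' configuration and inputs yield byte-identical outputs.
#'
#' When \code{sites} already carries an \code{idi} column (e.g. published
#' scores) it is used directly; otherwise IDI is computed from the
#' land-use columns (\code{urban_pct}, \code{agri_pasture_pct}) and, when
#' supplied, the tallies. When \code{abundance} is \code{NULL} the
#' community stages are skipped and logged as skipped.
#'
#' @param sites site attribute data frame (column \code{site_id} plus
#'   attributes).
#' @param tallies optional named list of \code{\link{disturbance_tally}}.
#' @param abundance optional site-by-species count matrix; rows must
#'   match \code{sites$site_id}.
#' @param attrs optional species attribute table (for NNAbu).
#' @param out_dir output directory, created if needed.
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) list with every computed table and the manifest.
#' @export
run_pipeline <- function(sites, tallies = NULL, abundance = NULL,
                         attrs = NULL, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  # -- disturbance scores ---------------------------------------------
  if (all(c("urban_pct", "agri_pasture_pct") %in% names(sites))) {
    scores <- score_disturbance(sites, tallies, config$weights,
                                config$normalization, config$thresholds)
    note("disturbance: scored from land use and tallies")
  } else if ("idi" %in% names(sites)) {
    scores <- data.frame(
      site_id = sites$site_id, ldi = NA_real_, cdi = NA_real_,
      idi = sites$idi, idi_clamped = pmin(sites$idi, 1),
      level = classify_disturbance(sites$idi, config$thresholds))
    note("disturbance: classified supplied IDI values")
  } else {
    stop("stage 'disturbance': sites need either land-use columns ",
         "(urban_pct, agri_pasture_pct) or an 'idi' column")
  }
  .write_table(scores, file.path(out_dir, "site_scores.csv"))

  # -- correlation screen ---------------------------------------------
  env_all <- sites[, setdiff(names(sites), "site_id"), drop = FALSE]
  env_all <- env_all[vapply(env_all, is.numeric, logical(1))]
  if (!"idi" %in% names(env_all)) env_all$idi <- scores$idi
  screen <- spearman_screen(env_all, log_transform = TRUE,
                            alpha = config$alpha)
  corr_tab <- correlation_table(screen)
  .write_table(corr_tab, file.path(out_dir, "correlations.csv"))
  note("correlation: Spearman screen")

  ord_axes <- ord_terms <- ord_scores <- iv <- restr <- div <- trends <- NULL
  if (is.null(abundance)) {
    note("community stages skipped: no abundance data")
  } else {
    abundance <- as_abundance(abundance)
    if (!identical(rownames(abundance), as.character(sites$site_id)))
      stop("stage 'community': abundance rows must match sites$site_id")

    # ordination on physico-chemistry + disturbance + habitat
    env_vars <- intersect(.ENV_VARS, names(env_all))
    if (length(env_vars) >= 2L) {
      env <- as.data.frame(lapply(env_all[env_vars], log_offset))
      sel <- select_variables(env, config$r_max, config$vif_max,
                              config$alpha)
      d <- bray_curtis(abundance, transform = "sqrt")
      fit <- dbrda(d, sel$env)
      ord_axes <- dbrda_permutation_test(fit, by = "axis",
                                         n_perm = config$n_perm,
                                         seed = config$seed + 11L)
      ord_terms <- dbrda_permutation_test(fit, by = "margin",
                                          n_perm = config$n_perm,
                                          seed = config$seed + 12L)
      ord_scores <- data.frame(site_id = rownames(fit$lc), fit$lc)
      .write_table(ord_axes, file.path(out_dir, "ordination_axes.csv"))
      .write_table(ord_terms, file.path(out_dir, "ordination_terms.csv"))
      .write_table(ord_scores, file.path(out_dir, "ordination_scores.csv"))
      if (nrow(sel$log) > 0L)
        .write_table(sel$log, file.path(out_dir, "variable_exclusions.csv"))
      note(sprintf("ordination: dbRDA on %d selected variables",
                   ncol(sel$env)))
    } else {
      note("ordination skipped: fewer than two environmental variables")
    }

    iv <- indval_test(abundance, scores$level, n_perm = config$n_perm,
                      seed = config$seed + 13L)
    .write_table(as.data.frame(iv), file.path(out_dir, "indval.csv"))
    note("indval: indicator species across disturbance levels")

    r <- restrictedness(abundance)
    restr <- data.frame(species_id = names(r), restrictedness = r)
    .write_table(restr, file.path(out_dir, "restrictedness.csv"))
    note("restrictedness")

    div <- diversity_table(abundance, attrs)
    .write_table(div, file.path(out_dir, "diversity.csv"))
    note("diversity profiles")

    mets <- c("abundance", "richness", "shannon", "simpson_dominance",
              "equitability", "nnabu")
    trends <- do.call(rbind, lapply(mets, function(m) {
      y <- div[[m]]
      if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0)
        return(data.frame(metric = m, slope = NA, rho = NA, p = NA,
                          n = sum(is.finite(y))))
      tt <- trend_test(y, scores$idi, n_perm = config$n_perm,
                       seed = config$seed + 14L)
      data.frame(metric = m, slope = tt$slope, rho = tt$rho, p = tt$p,
                 n = tt$n)
    }))
    .write_table(trends, file.path(out_dir, "trend_tests.csv"))
    note("trend tests of assemblage metrics vs IDI")
  }

  cfg_list <- unclass(config)
  cfg_list$weights <- unclass(cfg_list$weights)
  cfg_list$thresholds <- as.list(cfg_list$thresholds)
  cfg_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "streamdisturb",
    version = as.character(utils::packageVersion("streamdisturb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_hash = .fnv1a(as.character(cfg_json)),
    n_sites = nrow(sites),
    n_species = if (is.null(abundance)) 0L else ncol(abundance),
    stages = stages,
    files = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scores = scores, screen = screen,
                 correlations = corr_tab, ordination_axes = ord_axes,
                 ordination_terms = ord_terms, indval = iv,
                 restrictedness = restr, diversity = div,
                 trends = trends, manifest = manifest))
}
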