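# All tables are delimited text: comma by default, tab accepted; UTF-8;
# '.' decimal separator regardless of locale.

.read_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

.write_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, dec = ".", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8", eol = "\n")
}

#' Read a site-by-species abundance matrix
#'
#' Expects a delimited file whose header row holds species ids and whose
#' first column holds site ids; cells are non-negative integer counts.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return numeric matrix with site row names and species column names.
#' @export
read_abundance <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  if (ncol(df) < 2L) stop("abundance file needs site ids plus species")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate site id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    num <- matrix(suppressWarnings(as.numeric(m)), nrow = nrow(m))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at site '%s', species '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count at site '%s', species '%s'",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]]))
  frac <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac) > 0L)
    stop(sprintf("non-integer count at site '%s', species '%s'",
                 ids[frac[1, 1]], colnames(m)[frac[1, 2]]))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  as_abundance(m)
}

#' Write a site-by-species abundance matrix
#'
#' Inverse of \code{\link{read_abundance}}; the round trip is lossless.
#'
#' @param counts abundance matrix with dimnames.
#' @param path file path.
#' @param sep field separator.
#' @export
write_abundance <- function(counts, path, sep = ",") {
  counts <- as_abundance(counts)
  df <- data.frame(site_id = rownames(counts), counts,
                   check.names = FALSE)
  .write_table(df, path, sep)
  invisible(path)
}

#' Read a site attribute table
#'
#' Delimited table with a \code{site_id} column plus per-site attributes
#' (land-use percentages, habitat score, physico-chemistry, ...).
#'
#' @inheritParams read_abundance
#' @return data frame.
#' @export
read_sites <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  if (!"site_id" %in% names(df)) stop("site table needs a 'site_id' column")
  if (anyDuplicated(df$site_id)) stop("duplicate site ids in site table")
  df
}

#' Read local disturbance tallies
#'
#' Long-format delimited file with one row per (site, category):
#' columns \code{site_id}, \code{category}, then one column per transect
#' holding proximity codes in \code{0/B/C/P}.
#'
#' @inheritParams read_abundance
#' @return named list of \code{\link{disturbance_tally}} objects.
#' @export
read_tallies <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  need <- c("site_id", "category")
  if (!all(need %in% names(df)))
    stop("tally file needs 'site_id' and 'category' columns")
  tcols <- setdiff(names(df), need)
  if (length(tcols) < 1L) stop("tally file has no transect columns")
  out <- lapply(split(df, df$site_id), function(chunk) {
    ord <- match(DISTURBANCE_CATEGORIES, chunk$category)
    if (anyNA(ord))
      stop("site '", chunk$site_id[1], "': missing categories ",
           paste(DISTURBANCE_CATEGORIES[is.na(ord)], collapse = ", "))
    grid <- as.matrix(chunk[ord, tcols, drop = FALSE])
    mode(grid) <- "character"
    grid[grid == ""] <- NA
    disturbance_tally(grid)
  })
  out
}

#' Write local disturbance tallies
#'
#' @param tallies named list of \code{\link{disturbance_tally}} objects.
#' @param path file path.
#' @param sep field separator.
#' @export
write_tallies <- function(tallies, path, sep = ",") {
  rows <- lapply(names(tallies), function(s) {
    g <- tallies[[s]]$grid
    data.frame(site_id = s, category = rownames(g), g,
               check.names = FALSE)
  })
  .write_table(do.call(rbind, rows), path, sep)
  invisible(path)
}

#' Read a species attribute table
#'
#' Delimited table with columns \code{species_id}, \code{basin},
#' \code{origin} (\code{NATIVE}/\code{NON_NATIVE}) and logical
#' \code{endemic}.
#'
#' @inheritParams read_abundance
#' @return data frame.
#' @export
read_species_attributes <- function(path, sep = ",") {
  df <- .read_table(path, sep)
  need <- c("species_id", "basin", "origin")
  if (!all(need %in% names(df)))
    stop("species attribute table needs columns ",
         paste(need, collapse = ", "))
  bad <- setdiff(unique(df$origin), c("NATIVE", "NON_NATIVE"))
  if (length(bad) > 0L)
    stop("unknown origin value(s): ", paste(bad, collapse = ", "))
  if (!"endemic" %in% names(df)) df$endemic <- FALSE
  df$endemic <- as.logical(df$endemic)
  df
}

#' Packaged stream characteristics fixture
#'
#' Per-site characteristics of the 25 sampled streams of the motivating
#' survey: forest land cover (\code{flc}), agricultural (\code{alu}) and
#' urban (\code{ulu}) land-use percentages, the habitat diversity total
#' (\code{rhda}), the integrated disturbance index (\code{idi}) and
#' chlorophyll-a (\code{chla}, ug/L).
#'
#' @return data frame with 25 rows.
#' @export
#' @examples
#' head(table1_streams())
table1_streams <- function() {
  path <- system.file("extdata", "table1_streams.csv",
                      package = "streamdisturb", mustWork = TRUE)
  read_sites(path)
}
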