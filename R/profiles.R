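#' Long-form metabolite profile tables
#'
#' A metabolite profile set is a long-form `data.frame` holding replicate-level
#' GC-MS relative responses, one row per (sample, metabolite), with columns
#' `sample_id`, `genotype`, `season`, `tissue`, `replicate`, `metabolite` and
#' `response`.  The control genotype (default `"M82"`) must be present with at
#' least two replicates in every (season, tissue) stratum, responses must be
#' strictly positive (they are log-transformed downstream), and
#' (sample_id, metabolite) pairs must be unique.
#'
#' `validate_profiles()` checks the invariants and returns the table invisibly;
#' violations are reported with the offending row indices.
#'
#' @param profiles A long-form profile `data.frame`.
#' @param control_id Name of the control genotype. Default `"M82"`.
#' @param require_control If `FALSE`, skip the per-stratum control check
#'   (useful for subsets that deliberately exclude the control).
#' @return `profiles`, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles, control_id = "M82",
                              require_control = TRUE) {
  needed <- c("sample_id", "genotype", "season", "tissue", "replicate",
              "metabolite", "response")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0L)
    .fail("profile table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(profiles$response) | profiles$response <= 0)
  if (length(bad) > 0L)
    .fail("non-positive or missing response in row(s): ",
          paste(head(bad, 10L), collapse = ", "),
          if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  key <- paste(profiles$sample_id, profiles$metabolite, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    .fail("duplicated (sample_id, metabolite) pair(s) in row(s): ",
          paste(head(dup, 10L), collapse = ", "))
  if (require_control) {
    strata <- unique(profiles[, c("season", "tissue")])
    for (i in seq_len(nrow(strata))) {
      sel <- profiles$season == strata$season[i] &
        profiles$tissue == strata$tissue[i]
      ctl <- profiles[sel & profiles$genotype == control_id, ]
      n_rep <- length(unique(ctl$replicate))
      if (n_rep < 2L)
        .fail(sprintf(
          "control genotype '%s' has %d replicate(s) (need >= 2) in stratum (season=%s, tissue=%s)",
          control_id, n_rep, strata$season[i], strata$tissue[i]))
    }
  }
  invisible(profiles)
}

#' Read and write metabolite profile tables
#'
#' Delimited-text readers/writers for [validate_profiles()]-conformant tables.
#' Column mapping is configuration-driven: `columns` renames file columns onto
#' the canonical names, so any well-labelled long-form export can be ingested.
#' Writing then reading a valid table is a lossless round trip.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param columns Named character vector mapping canonical field names to
#'   column names in the file, e.g. `c(response = "value")`.  Unmapped fields
#'   are looked up under their canonical names.
#' @param control_id,require_control Passed to [validate_profiles()].
#' @return `read_profiles()`: a validated profile `data.frame`.
#'   `write_profiles()`: the path, invisibly.
#' @export
read_profiles <- function(path, sep = "\t", columns = character(),
                          control_id = "M82", require_control = TRUE) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  canon <- c("sample_id", "genotype", "season", "tissue", "replicate",
             "metabolite", "response")
  for (field in canon) {
    src <- if (field %in% names(columns)) columns[[field]] else field
    if (!src %in% names(tab))
      .fail("cannot resolve column '", src, "' for field '", field, "'")
    names(tab)[names(tab) == src] <- field
  }
  tab <- tab[, canon]
  tab$replicate <- as.integer(tab$replicate)
  tab$response <- as.numeric(tab$response)
  validate_profiles(tab, control_id = control_id,
                    require_control = require_control)
}

#' @rdname read_profiles
#' @param profiles A validated profile table.
#' @export
write_profiles <- function(profiles, path, sep = "\t") {
  validate_profiles(profiles, require_control = FALSE)
  write.table(profiles, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Introgression segment maps
#'
#' A segment map is a `data.frame` with columns `il_id`, `chromosome`, `start`
#' and `end` (centimorgan, closed intervals, `start < end`).  Two segments
#' overlap iff their intervals intersect with positive length; the overlap is
#' what mQTL localization reasons about.
#'
#' @param path Path to a 4-column delimited file (`il_id`, `chromosome`,
#'   `start`, `end`).
#' @param sep Field separator.
#' @return A validated segment-map `data.frame`.
#' @export
read_segment_map <- function(path, sep = "\t") {
  if (!file.exists(path)) .fail("no such file: ", path)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_segment_map(tab)
}

#' @rdname read_segment_map
#' @param map A segment-map `data.frame`.
#' @export
write_segment_map <- function(map, path, sep = "\t") {
  validate_segment_map(map)
  write.table(map, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_segment_map
#' @export
validate_segment_map <- function(map) {
  needed <- c("il_id", "chromosome", "start", "end")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols) > 0L)
    .fail("segment map lacks column(s): ", paste(missing_cols, collapse = ", "))
  map$start <- as.numeric(map$start)
  map$end <- as.numeric(map$end)
  bad <- which(!(map$start < map$end))
  if (length(bad) > 0L)
    .fail("segment start >= end in row(s): ", paste(bad, collapse = ", "))
  map[, needed]
}

#' Read a genotype-by-trait morphological matrix
#'
#' First column identifies the genotype; remaining columns are numeric trait
#' measurements.  Missing values are permitted (trait tables from field trials
#' rarely are complete) and handled downstream by pairwise-complete
#' correlation.
#'
#' @param path Path to a delimited file.
#' @param sep Field separator.
#' @return A numeric matrix with genotypes as row names and traits as columns.
#' @export
read_trait_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) .fail("no such file: ", path)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_trait_matrix
#' @param traits Numeric genotype-by-trait matrix with row names.
#' @export
write_trait_matrix <- function(traits, path, sep = "\t") {
  tab <- data.frame(genotype = rownames(traits), traits,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype-mean metabolite matrix
#'
#' Averages replicates (optionally within one season/tissue stratum) to the
#' genotype level, the unit at which population-wide correlations are computed.
#'
#' @param profiles A long-form profile table.
#' @param season,tissue Optional filters; `NULL` keeps all levels.
#' @param log10 If `TRUE` (default) average log10-transformed responses,
#'   the scale on which all population statistics operate.
#' @return A genotype x metabolite numeric matrix of means.
#' @export
genotype_means <- function(profiles, season = NULL, tissue = NULL,
                           log10 = TRUE) {
  if (!is.null(season)) profiles <- profiles[profiles$season %in% season, ]
  if (!is.null(tissue)) profiles <- profiles[profiles$tissue %in% tissue, ]
  if (nrow(profiles) == 0L) .fail("no rows left after season/tissue filter")
  v <- if (log10) log10(profiles$response) else profiles$response
  tab <- tapply(v, list(profiles$genotype, profiles$metabolite), mean)
  m <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  m
}
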