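# Reading, validating, filtering and replicating species-level fossil
# occurrence tables (PBDB-style exports and PyRate-style tab files).

OCC_COLUMNS <- c("occurrence_id", "species_name", "genus", "family",
                 "min_ma", "max_ma", "environment", "lng", "lat",
                 "site_id", "qualifier", "accepted", "extant")

normalize_binomial <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# A species name carrying an open-nomenclature token counts as qualified
# even when no qualifier column is present (export formats vary).
name_qualifier <- function(species_name) {
  q <- rep("none", length(species_name))
  q[grepl("\\baff\\.?(\\s|$)", species_name, ignore.case = TRUE)] <- "aff"
  q[grepl("\\bcf\\.?(\\s|$)", species_name, ignore.case = TRUE)] <- "cf"
  q
}

#' Construct an occurrence table
#'
#' Validates and classes a data frame of fossil occurrences. Required
#' columns are `species_name`, `min_ma` and `max_ma`; all other standard
#' columns (`occurrence_id`, `genus`, `family`, `environment`, `lng`,
#' `lat`, `site_id`, `qualifier`, `accepted`, `extant`) are filled with
#' neutral defaults when absent. Extra columns are preserved untouched.
#'
#' Ages are in Ma before present (larger = older, present = 0). Invariants
#' enforced: `max_ma >= min_ma >= 0`, non-empty species names, unique
#' occurrence ids.
#'
#' @param df data frame of occurrences.
#' @param provenance free-text provenance string stored as an attribute.
#' @return a data frame of class `occurrence_table`.
#' @export
occurrence_table <- function(df, provenance = "unknown") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("species_name", "min_ma", "max_ma"))
    if (is.null(df[[col]])) stop(sprintf("missing required column '%s'", col))
  n <- nrow(df)
  if (is.null(df$occurrence_id)) df$occurrence_id <- as.character(seq_len(n))
  df$occurrence_id <- as.character(df$occurrence_id)
  if (is.null(df$genus))
    df$genus <- vapply(strsplit(as.character(df$species_name), "\\s+"),
                       `[`, "", 1L)
  if (is.null(df$family)) df$family <- rep(NA_character_, n)
  if (is.null(df$environment)) df$environment <- rep(NA_character_, n)
  if (is.null(df$lng)) df$lng <- rep(NA_real_, n)
  if (is.null(df$lat)) df$lat <- rep(NA_real_, n)
  if (is.null(df$site_id)) df$site_id <- as.character(seq_len(n))
  df$site_id <- as.character(df$site_id)
  if (is.null(df$qualifier)) df$qualifier <- name_qualifier(df$species_name)
  if (is.null(df$accepted)) df$accepted <- rep(TRUE, n)
  if (is.null(df$extant)) df$extant <- rep(FALSE, n)
  df$min_ma <- as.numeric(df$min_ma)
  df$max_ma <- as.numeric(df$max_ma)

  bad <- which(is.na(df$min_ma) | is.na(df$max_ma))
  if (length(bad))
    stop(sprintf("unparsable age in row %d", bad[1L]))
  bad <- which(df$min_ma < 0)
  if (length(bad))
    stop(sprintf("negative age in row %d", bad[1L]))
  bad <- which(df$max_ma < df$min_ma)
  if (length(bad))
    stop(sprintf("max_ma < min_ma in row %d", bad[1L]))
  bad <- which(is.na(df$species_name) | !nzchar(trimws(df$species_name)))
  if (length(bad))
    stop(sprintf("empty species_name in row %d", bad[1L]))
  if (anyDuplicated(df$occurrence_id))
    stop("occurrence_id values must be unique")

  attr(df, "provenance") <- provenance
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read an occurrence table from disk
#'
#' Two dialects are supported. `pbdb_csv` is a comma-separated export with
#' columns `accepted_name`, `genus`, `family`, `min_ma`, `max_ma`,
#' `environment`, `lng`, `lat`, `collection_no`, `primary_reso` (the
#' identification qualifier) and `flags` (accepted-name marker).
#' `pyrate_table` is tab-separated with columns `Species`, `Status`
#' (extinct/extant), `min_age`, `max_age`, one row per occurrence.
#' Unknown columns are carried along as opaque metadata.
#'
#' @param path file path.
#' @param dialect one of `"pbdb_csv"`, `"pyrate_table"`.
#' @return an `occurrence_table`.
#' @export
read_occurrences <- function(path, dialect = c("pbdb_csv", "pyrate_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "pbdb_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    required <- c("accepted_name", "genus", "family", "min_ma", "max_ma",
                  "environment", "lng", "lat", "collection_no",
                  "primary_reso", "flags")
    missing <- setdiff(required, names(raw))
    if (length(missing))
      stop(sprintf("missing required column '%s'", missing[1L]))
    qual <- rep("none", nrow(raw))
    qual[grepl("aff", raw$primary_reso, ignore.case = TRUE)] <- "aff"
    qual[grepl("cf", raw$primary_reso, ignore.case = TRUE)] <- "cf"
    name_q <- name_qualifier(raw$accepted_name)
    qual[qual == "none" & name_q != "none"] <- name_q[qual == "none" & name_q != "none"]
    acc <- toupper(trimws(as.character(raw$flags))) %in%
      c("A", "ACCEPTED", "TRUE", "1", "YES")
    df <- data.frame(
      occurrence_id = if (!is.null(raw$occurrence_no))
        as.character(raw$occurrence_no) else as.character(seq_len(nrow(raw))),
      species_name = raw$accepted_name,
      genus = raw$genus, family = raw$family,
      min_ma = suppressWarnings(as.numeric(raw$min_ma)),
      max_ma = suppressWarnings(as.numeric(raw$max_ma)),
      environment = raw$environment,
      lng = suppressWarnings(as.numeric(raw$lng)),
      lat = suppressWarnings(as.numeric(raw$lat)),
      site_id = as.character(raw$collection_no),
      qualifier = qual, accepted = acc,
      extant = if (!is.null(raw$extant))
        tolower(raw$extant) %in% c("true", "1", "extant")
      else rep(FALSE, nrow(raw)),
      stringsAsFactors = FALSE)
    extra <- setdiff(names(raw), c(required, "occurrence_no", "extant"))
    for (col in extra) df[[col]] <- raw[[col]]
    bad <- which(is.na(df$min_ma) | is.na(df$max_ma))
    if (length(bad)) stop(sprintf("unparsable age in row %d", bad[1L]))
    occurrence_table(df, provenance = path)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    required <- c("Species", "Status", "min_age", "max_age")
    missing <- setdiff(required, names(raw))
    if (length(missing))
      stop(sprintf("missing required column '%s'", missing[1L]))
    df <- data.frame(
      species_name = raw$Species,
      min_ma = suppressWarnings(as.numeric(raw$min_age)),
      max_ma = suppressWarnings(as.numeric(raw$max_age)),
      extant = tolower(trimws(raw$Status)) == "extant",
      stringsAsFactors = FALSE)
    extra <- setdiff(names(raw), required)
    for (col in extra) df[[col]] <- raw[[col]]
    bad <- which(is.na(df$min_ma) | is.na(df$max_ma))
    if (length(bad)) stop(sprintf("unparsable age in row %d", bad[1L]))
    occurrence_table(df, provenance = path)
  }
}

#' Write an occurrence table to disk
#'
#' Round-trips both supported dialects; `pyrate_table` writes the
#' tab-separated `Species`/`Status`/`min_age`/`max_age` layout.
#'
#' @param table an `occurrence_table`.
#' @param path output file path.
#' @param dialect output dialect.
#' @export
write_occurrences <- function(table, path,
                              dialect = c("pyrate_table", "pbdb_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "pyrate_table") {
    out <- data.frame(
      Species = table$species_name,
      Status = ifelse(table$extant, "extant", "extinct"),
      min_age = table$min_ma, max_age = table$max_ma,
      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    out <- data.frame(
      occurrence_no = table$occurrence_id,
      accepted_name = table$species_name,
      genus = table$genus, family = table$family,
      min_ma = table$min_ma, max_ma = table$max_ma,
      environment = table$environment, lng = table$lng, lat = table$lat,
      collection_no = table$site_id, primary_reso = ifelse(
        table$qualifier == "none", "", paste0(table$qualifier, ".")),
      flags = ifelse(table$accepted, "A", ""),
      extant = table$extant,
      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Filter an occurrence table
#'
#' Filters compose conjunctively; the input table is never modified.
#' Supported rules:
#' \describe{
#'   \item{drop_qualified}{remove records with qualifier `aff` or `cf`.}
#'   \item{accepted_only}{keep records with `accepted = TRUE`.}
#'   \item{environment_in}{keep records whose environment is in the given
#'     set; with `environment_mode = "species"` every occurrence of a
#'     species with at least one matching occurrence is kept instead.}
#'   \item{family_in}{keep records whose family is in the given set.}
#'   \item{lng_window}{`c(lo, hi)` closed longitude interval on modern
#'     coordinates; `lo > hi` wraps across the antimeridian.}
#'   \item{co_occurrence}{keep only records at sites where at least one
#'     record of the given reference family exists.}
#' }
#'
#' @param table an `occurrence_table`.
#' @param rules named list of filter rules (may be empty).
#' @return a filtered `occurrence_table`.
#' @export
filter_occurrences <- function(table, rules = list()) {
  known <- c("drop_qualified", "accepted_only", "environment_in",
             "family_in", "lng_window", "co_occurrence", "environment_mode")
  unknown <- setdiff(names(rules), known)
  if (length(unknown))
    stop(sprintf("unknown filter rule '%s'", unknown[1L]))
  keep <- rep(TRUE, nrow(table))
  if (isTRUE(rules$drop_qualified))
    keep <- keep & !(table$qualifier %in% c("aff", "cf"))
  if (isTRUE(rules$accepted_only))
    keep <- keep & table$accepted
  if (!is.null(rules$environment_in)) {
    mode <- rules$environment_mode %||% "occurrence"
    in_env <- table$environment %in% rules$environment_in
    if (identical(mode, "species")) {
      ok_species <- unique(table$species_name[in_env])
      keep <- keep & table$species_name %in% ok_species
    } else keep <- keep & in_env
  }
  if (!is.null(rules$family_in))
    keep <- keep & table$family %in% rules$family_in
  if (!is.null(rules$lng_window)) {
    w <- rules$lng_window
    if (length(w) != 2L) stop("lng_window must be c(lo, hi)")
    inw <- if (w[1L] <= w[2L]) table$lng >= w[1L] & table$lng <= w[2L]
           else table$lng >= w[1L] | table$lng <= w[2L]
    keep <- keep & !is.na(inw) & inw
  }
  if (!is.null(rules$co_occurrence)) {
    ref_sites <- unique(table$site_id[table$family %in% rules$co_occurrence])
    keep <- keep & table$site_id %in% ref_sites
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Flag extant species by name matching
#'
#' Sets the `extant` flag to `TRUE` exactly for species in `extant_names`;
#' matching is exact on normalized (trimmed, whitespace-squashed,
#' case-folded) binomials.
#'
#' @param table an `occurrence_table`.
#' @param extant_names character vector of extant species names.
#' @return the table with its `extant` column rewritten.
#' @export
mark_extant <- function(table, extant_names) {
  table$extant <- normalize_binomial(table$species_name) %in%
    normalize_binomial(extant_names)
  table
}

#' Resample occurrence ages within their stratigraphic ranges
#'
#' Draws, for each occurrence, an age uniformly within `[min_ma, max_ma]`,
#' producing `n_replicates` independent age replicates. Identical seeds
#' give identical output.
#'
#' @param table an `occurrence_table`.
#' @param n_replicates number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @return list of `age_replicate` objects, each with `replicate_index`
#'   and a named `ages` vector (names = occurrence ids).
#' @export
resample_ages <- function(table, n_replicates = 50L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  set.seed(seed)
  n <- nrow(table)
  lapply(seq_len(n_replicates), function(r) {
    ages <- stats::runif(n, table$min_ma, table$max_ma)
    names(ages) <- table$occurrence_id
    structure(list(replicate_index = r, ages = ages),
              class = "age_replicate")
  })
}

#' Split species into equally sized random subsets
#'
#' Species-level random partition; subset sizes differ by at most one and
#' every occurrence of a species maps to exactly one subset. Remainder
#' species are distributed one per subset in random order.
#'
#' @param table an `occurrence_table`.
#' @param n_subsets number of subsets (1 <= n <= number of species).
#' @param seed integer RNG seed.
#' @return object of class `subset_partition`: list with `n_subsets` and a
#'   named integer `assignment` (species name -> subset index).
#' @export
split_subsets <- function(table, n_subsets, seed = 1L) {
  species <- unique(table$species_name)
  s <- length(species)
  if (n_subsets < 1L || n_subsets > s)
    stop("n_subsets must be between 1 and the number of species")
  set.seed(seed)
  species <- sample(species)
  base <- s %/% n_subsets
  rem <- s %% n_subsets
  sizes <- rep(base, n_subsets)
  if (rem > 0L) {
    lucky <- sample(n_subsets, rem)
    sizes[lucky] <- sizes[lucky] + 1L
  }
  assignment <- rep(seq_len(n_subsets), times = sizes)
  names(assignment) <- species
  structure(list(n_subsets = n_subsets, assignment = assignment),
            class = "subset_partition")
}

#' Extract the occurrences of one subset
#' @param table an `occurrence_table`.
#' @param partition a `subset_partition` from [split_subsets()].
#' @param index subset index.
#' @return an `occurrence_table` restricted to the subset's species.
#' @export
subset_occurrences <- function(table, partition, index) {
  sp <- names(partition$assignment)[partition$assignment == index]
  out <- table[table$species_name %in% sp, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- c("occurrence_table", "data.frame")
  out
}

# Collapse an occurrence table (plus one age replicate) to per-lineage
# occurrence-age sets; the unit handed to the preservation likelihoods
# and the lifespan sampler.
build_lineages <- function(table, replicate = NULL) {
  ages <- if (is.null(replicate)) {
    (table$min_ma + table$max_ma) / 2
  } else {
    replicate$ages[table$occurrence_id]
  }
  sp <- table$species_name
  o <- order(sp)
  sp <- sp[o]; ages <- ages[o]
  ext <- table$extant[o]
  idx <- !duplicated(sp)
  species <- sp[idx]
  extant <- ext[idx]
  occ <- split(ages, factor(sp, levels = species))
  structure(list(
    species = species,
    extant = as.logical(tapply(ext, factor(sp, levels = species), any)),
    occ = occ,
    fa = vapply(occ, max, 0),
    la = vapply(occ, min, 0),
    k = vapply(occ, length, 0L)
  ), class = "lineage_set")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("Occurrence table: %d occurrences, %d species (%s)\n",
              nrow(x), length(unique(x$species_name)),
              attr(x, "provenance") %||% "unknown"))
  if (nrow(x)) {
    cat(sprintf("  age span: %.2f-%.2f Ma; %d extant species\n",
                min(x$min_ma), max(x$max_ma),
                length(unique(x$species_name[x$extant]))))
  }
  invisible(x)
}
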