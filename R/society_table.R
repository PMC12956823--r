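#' Construct and validate a society trait table
#'
#' A `society_table` is the package's central data container: one row per
#' society, holding a binary kava presence/absence trait, two five-level
#' ordinal traits (political complexity and social stratification, on the
#' Murdock--Provost scales, coded 0--4), a three-valued atoll indicator
#' (0 = not an atoll, 0.5 = "almost atoll", 1 = atoll) and geographic
#' coordinates in decimal degrees. Missing trait values are represented by
#' `NA`, never by sentinel codes.
#'
#' @param df A data.frame with columns `society_id`, `language_taxon`,
#'   `kava`, `political_complexity`, `social_stratification`, `atoll_raw`,
#'   `latitude`, `longitude`. Extra columns are preserved.
#' @return The validated data.frame with class `society_table`.
#' @export
society_table <- function(df) {
  required <- c("society_id", "language_taxon", "kava",
                "political_complexity", "social_stratification",
                "atoll_raw", "latitude", "longitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    ct_schema_error(paste0("missing required column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) ct_schema_error("society table has no rows")
  df$society_id <- as.character(df$society_id)
  df$language_taxon <- as.character(df$language_taxon)
  # stable column types so that write/read round trips are exact
  for (col in c("kava", "political_complexity", "social_stratification")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$atoll_raw <- as.numeric(df$atoll_raw)
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  if (anyDuplicated(df$society_id)) {
    ct_validation_error(paste0("duplicate society_id: ",
      paste(unique(df$society_id[duplicated(df$society_id)]), collapse = ", ")))
  }
  check_binary(df, "kava")
  check_ordinal(df, "political_complexity")
  check_ordinal(df, "social_stratification")
  bad_atoll <- which(!is.na(df$atoll_raw) & !df$atoll_raw %in% c(0, 0.5, 1))
  if (length(bad_atoll) > 0L) {
    ct_validation_error(paste0("atoll_raw outside {0, 0.5, 1} in row(s) ",
                               paste(bad_atoll, collapse = ", ")))
  }
  bad_lat <- which(!is.na(df$latitude) &
                     (df$latitude < -90 | df$latitude > 90))
  bad_lon <- which(!is.na(df$longitude) &
                     (df$longitude < -180 | df$longitude > 180))
  if (length(bad_lat) > 0L || length(bad_lon) > 0L) {
    ct_validation_error(paste0("coordinates out of range in row(s) ",
      paste(sort(unique(c(bad_lat, bad_lon))), collapse = ", ")))
  }
  class(df) <- c("society_table", "data.frame")
  df
}

check_ordinal <- function(df, col) {
  x <- df[[col]]
  bad <- which(!is.na(x) & (x %% 1 != 0 | x < 0 | x > 4))
  if (length(bad) > 0L) {
    ct_validation_error(paste0(
      col, " outside {0,...,4} in row(s) ", paste(bad, collapse = ", "),
      " (society ", paste(df$society_id[bad], collapse = ", "), ")"))
  }
  invisible(TRUE)
}

check_binary <- function(df, col) {
  x <- df[[col]]
  bad <- which(!is.na(x) & !x %in% c(0, 1))
  if (length(bad) > 0L) {
    ct_validation_error(paste0(
      col, " outside {0,1} in row(s) ", paste(bad, collapse = ", "),
      " (society ", paste(df$society_id[bad], collapse = ", "), ")"))
  }
  invisible(TRUE)
}

#' Read a society trait table from delimited text
#'
#' The canonical on-disk format is CSV with a header. `column_spec` maps the
#' canonical field names onto the file's column names, so tables exported
#' from other tools can be ingested without editing the file.
#'
#' @param path Path to a CSV file.
#' @param column_spec Named character vector mapping canonical names
#'   (`society_id`, `kava`, ...) to column names in the file. Defaults to
#'   the identity mapping.
#' @return A [society_table].
#' @export
read_society_table <- function(path, column_spec = NULL) {
  if (!file.exists(path)) ct_schema_error(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) ct_schema_error(paste0("cannot parse ", path, ": ",
                                               conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L) {
    ct_schema_error(paste0("empty table in ", path))
  }
  if (!is.null(column_spec)) {
    absent <- setdiff(unname(column_spec), names(df))
    if (length(absent) > 0L) {
      ct_schema_error(paste0("column_spec refers to absent column(s): ",
                             paste(absent, collapse = ", ")))
    }
    for (canon in names(column_spec)) {
      names(df)[names(df) == column_spec[[canon]]] <- canon
    }
  }
  society_table(df)
}

#' Write a society trait table to CSV
#'
#' Values and missingness round-trip exactly through [read_society_table()].
#'
#' @param table A [society_table].
#' @param path Output path.
#' @export
write_society_table <- function(table, path) {
  stopifnot(inherits(table, "society_table"))
  df <- as.data.frame(table)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  for (col in c("atoll_raw", "latitude", "longitude")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Binarize the three-valued atoll indicator
#'
#' "Almost atolls" (coded 0.5) do not fit the strict definition of an atoll;
#' two defensible binarizations exist and results should be checked under
#' both. `exclude_half` recodes 0.5 as missing (those societies drop out of
#' models using atoll); `half_as_atoll` recodes 0.5 as 1.
#'
#' @param table A [society_table].
#' @param mode `"exclude_half"` or `"half_as_atoll"`.
#' @return The table with an added binary `atoll` column.
#' @export
binarize_atolls <- function(table, mode = c("exclude_half", "half_as_atoll")) {
  stopifnot(inherits(table, "society_table"))
  if (length(mode) == 1L && !mode %in% c("exclude_half", "half_as_atoll")) {
    ct_config_error(paste0("unknown atoll binarization mode: ", mode))
  }
  mode <- match.arg(mode)
  a <- table$atoll_raw
  table$atoll <- switch(mode,
    exclude_half  = ifelse(is.na(a) | a == 0.5, NA_real_, a),
    half_as_atoll = ifelse(is.na(a), NA_real_, as.numeric(a >= 0.5)))
  table
}

#' Map societies to tree tip labels
#'
#' Some societies correspond to more than one language in the phylogeny; the
#' mapping from society to tip is therefore supplied explicitly (one tip per
#' society) rather than guessed from label similarity.
#'
#' @param society_id Character vector of society ids.
#' @param tip_label Character vector of tip labels, same length.
#' @return A `taxon_map` data.frame.
#' @export
taxon_map <- function(society_id, tip_label) {
  if (length(society_id) != length(tip_label)) {
    ct_validation_error("society_id and tip_label lengths differ")
  }
  if (anyDuplicated(society_id)) {
    ct_validation_error("taxon map has duplicate society ids")
  }
  if (anyDuplicated(tip_label)) {
    ct_validation_error("taxon map is not injective: duplicate tip labels")
  }
  out <- data.frame(society_id = as.character(society_id),
                    tip_label = as.character(tip_label),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxon_map", "data.frame")
  out
}

#' Read a taxon map from a two-column CSV
#'
#' @param path CSV with columns `society_id` and `tip_label`.
#' @return A [taxon_map].
#' @export
read_taxon_map <- function(path) {
  if (!file.exists(path)) ct_schema_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("society_id", "tip_label") %in% names(df))) {
    ct_schema_error("taxon map needs columns society_id and tip_label")
  }
  taxon_map(df$society_id, df$tip_label)
}
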