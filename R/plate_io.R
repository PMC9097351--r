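#' Read a long-format plate table
#'
#' Reads screening measurements in the long plate dialect used throughout
#' the package: one row per well with the compound pair, the two doses
#' (micromolar), the well role and the raw optical density. Control wells
#' (`neg_ctrl` = vehicle, `pos_ctrl` = cytotoxic control such as 3 uM
#' bortezomib) must carry zero doses for the screened pair.
#'
#' @param path Path to a CSV file with columns exactly
#'   `plate_id,row,col,compound_a,dose_a,compound_b,dose_b,role,od`.
#' @return A validated data frame of well records (one row per well).
#' @details Validation rejects missing columns, unparseable or negative
#'   doses/ODs, unknown roles, control wells with nonzero doses, and
#'   duplicate `(plate_id, row, col)` addresses. Errors name the
#'   offending row so malformed exports are easy to locate.
#' @seealso [plate_qc()], [normalize_matrix()], [write_plate_table()]
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("plate table not found: %s", path), "input_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_well_records(coerce_well_records(df))
}

plate_columns <- c("plate_id", "row", "col", "compound_a", "dose_a",
                   "compound_b", "dose_b", "role", "od")

well_roles <- c("sample", "neg_ctrl", "pos_ctrl", "blank")

coerce_well_records <- function(df) {
  missing <- setdiff(plate_columns, names(df))
  if (length(missing)) {
    abort(sprintf("plate table is missing column(s): %s",
                  paste(missing, collapse = ", ")), "input_format_error")
  }
  df <- df[plate_columns]
  for (nm in c("row", "col", "dose_a", "dose_b", "od")) {
    val <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(val) & !is.na(df[[nm]]) & nzchar(df[[nm]]))
    if (length(bad)) {
      abort(sprintf("column '%s' is not numeric at data row %d (value '%s')",
                    nm, bad[1], df[[nm]][bad[1]]), "input_format_error")
    }
    df[[nm]] <- val
  }
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  df
}

#' Validate a data frame of well records
#'
#' @param df Data frame with the plate-table columns.
#' @return `df`, invisibly passed through after validation.
#' @export
validate_well_records <- function(df) {
  bad_role <- which(!df$role %in% well_roles)
  if (length(bad_role)) {
    abort(sprintf("unknown well role '%s' at data row %d",
                  df$role[bad_role[1]], bad_role[1]), "input_format_error")
  }
  for (nm in c("dose_a", "dose_b", "od")) {
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0)
    if (length(bad)) {
      abort(sprintf("column '%s' missing or negative at data row %d",
                    nm, bad[1]), "input_format_error")
    }
  }
  ctrl <- df$role %in% c("neg_ctrl", "pos_ctrl")
  bad_ctrl <- which(ctrl & (df$dose_a != 0 | df$dose_b != 0))
  if (length(bad_ctrl)) {
    abort(sprintf("control well with nonzero library dose at data row %d",
                  bad_ctrl[1]), "input_format_error")
  }
  key <- paste(df$plate_id, df$row, df$col, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf("duplicate well address (%s, row %d, col %d) at data row %d",
                  df$plate_id[dup[1]], df$row[dup[1]], df$col[dup[1]], dup[1]),
          "input_format_error")
  }
  df
}

#' Write well records as a plate CSV
#'
#' Inverse of [read_plate_table()]; the written file round-trips through
#' the reader without loss.
#'
#' @param records Well-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(records, path) {
  utils::write.csv(records[plate_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
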