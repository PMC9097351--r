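#' Construct a checkerboard dose matrix
#'
#' The central container for one compound-pair block: ascending dose
#' grids for both compounds (each beginning with 0 = vehicle) and the
#' percent-of-vehicle viability grid, with the vehicle cell fixed at 100.
#'
#' @param compound_a,compound_b Compound names.
#' @param doses_a,doses_b Ascending numeric dose vectors (uM), first
#'   element 0.
#' @param viability Numeric matrix, `length(doses_a)` x `length(doses_b)`,
#'   percent of vehicle; `viability[1, 1]` must be 100.
#' @param cell_line,replicate Optional metadata.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(compound_a, compound_b, doses_a, doses_b,
                        viability, cell_line = NA_character_,
                        replicate = 1L) {
  if (any(doses_a < 0) || any(doses_b < 0)) {
    abort("doses must be non-negative", "validation_error")
  }
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    abort("dose grids must begin with 0 (vehicle level)", "validation_error")
  }
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    abort("dose grids must be strictly increasing", "validation_error")
  }
  viability <- as.matrix(viability)
  if (!all(dim(viability) == c(length(doses_a), length(doses_b)))) {
    abort("viability grid dimensions do not match dose grids",
          "validation_error")
  }
  if (anyNA(viability)) {
    abort("viability grid contains missing values", "incomplete_block_error")
  }
  if (abs(viability[1, 1] - 100) > 1e-8) {
    abort("vehicle cell must equal 100 (vehicle-normalized grid)",
          "validation_error")
  }
  dimnames(viability) <- list(format(doses_a, trim = TRUE),
                              format(doses_b, trim = TRUE))
  structure(list(compound_a = compound_a, compound_b = compound_b,
                 doses_a = as.numeric(doses_a),
                 doses_b = as.numeric(doses_b),
                 viability = viability, cell_line = cell_line,
                 replicate = as.integer(replicate)),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("<dose_matrix> %s x %s (%d x %d incl. vehicle)%s\n",
              x$compound_a, x$compound_b,
              length(x$doses_a), length(x$doses_b),
              if (is.na(x$cell_line)) "" else paste0(" in ", x$cell_line)))
  print(round(x$viability, 2))
  invisible(x)
}

#' Normalize one plate block to percent-of-vehicle viability
#'
#' Converts raw ODs of one compound-pair block to percent viability:
#' `100 * (od - blank_mean) / (vehicle_mean - blank_mean)`, floored at 0
#' (values above 100, i.e. growth stimulation, are retained). The vehicle
#' reference is the mean OD of the plate's `neg_ctrl` wells; the blank
#' reference is the mean of `blank` wells, or 0 if the plate carries none.
#' The grid's vehicle cell is set to 100 exactly.
#'
#' @param records Well records for a single plate.
#' @param qc Optional [plate_qc()] table; if the plate failed QC the call
#'   errors unless `allow_failed_qc = TRUE`.
#' @param allow_failed_qc Override to normalize a failed-QC plate.
#' @param cell_line,replicate Metadata attached to the result (taken from
#'   the plate manifest in pipeline use).
#' @return A [dose_matrix()].
#' @export
normalize_matrix <- function(records, qc = NULL, allow_failed_qc = FALSE,
                             cell_line = NA_character_, replicate = 1L) {
  pid <- unique(records$plate_id)
  if (length(pid) != 1L) {
    abort("normalize_matrix() expects records for exactly one plate",
          "validation_error")
  }
  if (!is.null(qc)) {
    row <- qc[qc$plate_id == pid, , drop = FALSE]
    if (nrow(row) == 1L && !row$passed && !allow_failed_qc) {
      abort(sprintf("plate %s failed QC (Z' = %.3f); pass allow_failed_qc = TRUE to override",
                    pid, row$z_factor), "qc_failed_error")
    }
  }
  blank <- records$od[records$role == "blank"]
  blank_mean <- if (length(blank)) mean(blank) else 0
  veh <- records$od[records$role == "neg_ctrl"]
  if (!length(veh)) {
    abort(sprintf("plate %s has no vehicle (neg_ctrl) wells", pid),
          "degenerate_control_error")
  }
  veh_mean <- mean(veh)
  if (veh_mean <= blank_mean) {
    abort(sprintf("plate %s: vehicle mean OD (%.4f) not above blank mean (%.4f)",
                  pid, veh_mean, blank_mean), "degenerate_control_error")
  }

  smp <- records[records$role == "sample", , drop = FALSE]
  doses_a <- sort(unique(c(0, smp$dose_a)))
  doses_b <- sort(unique(c(0, smp$dose_b)))
  v <- matrix(NA_real_, length(doses_a), length(doses_b))
  i <- match(smp$dose_a, doses_a)
  j <- match(smp$dose_b, doses_b)
  v[cbind(i, j)] <- pmax(0, 100 * (smp$od - blank_mean) / (veh_mean - blank_mean))
  v[1, 1] <- 100
  if (anyNA(v)) {
    miss <- which(is.na(v), arr.ind = TRUE)
    abort(sprintf("plate %s: incomplete block; %d well(s) missing (first at dose_a = %g, dose_b = %g)",
                  pid, nrow(miss), doses_a[miss[1, 1]], doses_b[miss[1, 2]]),
          "incomplete_block_error")
  }
  compound_a <- setdiff(unique(smp$compound_a), "")[1]
  compound_b <- setdiff(unique(smp$compound_b), "")[1]
  dose_matrix(compound_a, compound_b, doses_a, doses_b, v,
              cell_line = cell_line, replicate = replicate)
}
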