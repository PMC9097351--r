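#' Excess over highest single agent (ExcessHSA)
#'
#' For every combination well `(i, j)` the excess is the combination's
#' viability minus the highest-single-agent reference, i.e. the lower of
#' the two single-agent viabilities at the well's marginal doses:
#' `excess[i, j] = V[i, j] - min(V[i, 0], V[0, j])`. Negative values mean
#' the combination kills more than the better single agent (synergy).
#' The matrix score is the SUM of excesses over all combination wells.
#'
#' @param mat A normalized [dose_matrix()].
#' @return List with `grid` (the `(n_a - 1) x (n_b - 1)` excess grid, in
#'   percentage points) and `sum`.
#' @export
excess_hsa <- function(mat) {
  v <- mat$viability
  na <- nrow(v); nb <- ncol(v)
  hsa_ref <- pmin(matrix(v[-1, 1], na - 1, nb - 1),
                  matrix(v[1, -1], na - 1, nb - 1, byrow = TRUE))
  grid <- v[-1, -1, drop = FALSE] - hsa_ref
  list(grid = grid, sum = sum(grid))
}

#' Bliss excess (observed minus Bliss-expected viability)
#'
#' Under Bliss independence the survival fractions of non-interacting
#' drugs multiply, so the expected combination viability is
#' `V_exp[i, j] = V[i, 0] * V[0, j] / 100`. The per-well excess is
#' `V[i, j] - V_exp[i, j]` (negative = synergy), summed over combination
#' wells for the matrix score.
#'
#' @inheritParams excess_hsa
#' @return List with `grid` and `sum`, as in [excess_hsa()].
#' @export
excess_bliss <- function(mat) {
  v <- mat$viability
  na <- nrow(v); nb <- ncol(v)
  expected <- matrix(v[-1, 1], na - 1, nb - 1) *
    matrix(v[1, -1], na - 1, nb - 1, byrow = TRUE) / 100
  grid <- v[-1, -1, drop = FALSE] - expected
  list(grid = grid, sum = sum(grid))
}

#' Classify a matrix-sum synergy score
#'
#' Thresholds follow the screen convention on the summed ExcessHSA score:
#' synergistic below `thresholds[1]`, antagonistic above `thresholds[2]`,
#' additive on the closed interval between them (so -20 and +20 are
#' additive with the defaults).
#'
#' @param score Matrix-sum score(s), percentage points.
#' @param thresholds Length-2 numeric `(lo, hi)`, default `c(-20, 20)`.
#' @return Character vector in
#'   `c("synergistic", "additive", "antagonistic")`.
#' @export
classify_interaction <- function(score, thresholds = c(-20, 20)) {
  if (thresholds[1] >= thresholds[2]) {
    abort("synergy thresholds must satisfy lo < hi", "validation_error")
  }
  if (any(!is.finite(score))) {
    abort("scores must be finite", "validation_error")
  }
  ifelse(score < thresholds[1], "synergistic",
         ifelse(score > thresholds[2], "antagonistic", "additive"))
}

#' Score one checkerboard matrix with both synergy metrics
#'
#' @param mat A normalized [dose_matrix()].
#' @param thresholds Classification thresholds, see
#'   [classify_interaction()].
#' @return An object of class `synergy_score` carrying both excess grids,
#'   both sums, and the interaction class (from the ExcessHSA sum).
#' @export
score_matrix <- function(mat, thresholds = c(-20, 20)) {
  h <- excess_hsa(mat)
  b <- excess_bliss(mat)
  structure(list(compound_a = mat$compound_a, compound_b = mat$compound_b,
                 cell_line = mat$cell_line,
                 excess_hsa_grid = h$grid, excess_bliss_grid = b$grid,
                 excess_hsa_sum = h$sum, excess_bliss_sum = b$sum,
                 interaction_class = classify_interaction(h$sum, thresholds)),
            class = "synergy_score")
}

#' @export
print.synergy_score <- function(x, ...) {
  cat(sprintf("<synergy_score> %s + %s%s: ExcessHSA sum = %.2f, Bliss sum = %.2f -> %s\n",
              x$compound_a, x$compound_b,
              if (is.na(x$cell_line)) "" else paste0(" [", x$cell_line, "]"),
              x$excess_hsa_sum, x$excess_bliss_sum, x$interaction_class))
  invisible(x)
}

#' Rank compounds by average ExcessHSA across cell lines
#'
#' Averages each compound's matrix-sum ExcessHSA over the cell lines
#' whose plates passed QC and ranks ascending (most synergistic, i.e.
#' most negative, first). Ties break lexicographically by compound name
#' for deterministic output.
#'
#' @param scores Data frame with columns `compound`, `cell_line`,
#'   `excess_hsa_sum` and optionally `qc_passed` (default all pass).
#' @param annotations Optional data frame `compound`, `moa_class`;
#'   compounds missing from it are labelled `"unannotated"` with a
#'   warning.
#' @param thresholds Classification thresholds applied to the average.
#' @return Data frame: `rank`, `compound`, `moa_class`, one
#'   `score.<cell_line>` column per cell line, `n_cell_lines`,
#'   `average_excess_hsa`, `interaction_class`.
#' @export
rank_compounds <- function(scores, annotations = NULL,
                           thresholds = c(-20, 20)) {
  req <- c("compound", "cell_line", "excess_hsa_sum")
  if (!all(req %in% names(scores))) {
    abort(sprintf("scores must have columns %s", paste(req, collapse = ", ")),
          "validation_error")
  }
  if (is.null(scores$qc_passed)) scores$qc_passed <- TRUE
  keep <- scores[scores$qc_passed, , drop = FALSE]
  if (!nrow(keep)) {
    abort("no passing plates to rank", "validation_error")
  }
  avg <- stats::aggregate(excess_hsa_sum ~ compound, keep, mean)
  names(avg)[2] <- "average_excess_hsa"
  n_cl <- stats::aggregate(cell_line ~ compound, keep,
                           function(x) length(unique(x)))
  names(n_cl)[2] <- "n_cell_lines"
  wide <- stats::reshape(
    keep[c("compound", "cell_line", "excess_hsa_sum")],
    idvar = "compound", timevar = "cell_line", direction = "wide",
    v.names = "excess_hsa_sum")
  names(wide) <- sub("^excess_hsa_sum\\.", "score.", names(wide))
  out <- merge(merge(wide, n_cl, by = "compound"), avg, by = "compound")
  if (!is.null(annotations)) {
    out$moa_class <- annotations$moa_class[match(out$compound,
                                                 annotations$compound)]
    if (anyNA(out$moa_class)) {
      warn(sprintf("%d compound(s) missing from annotation table; labelled 'unannotated'",
                   sum(is.na(out$moa_class))), "missing_annotation_warning")
      out$moa_class[is.na(out$moa_class)] <- "unannotated"
    }
  } else {
    out$moa_class <- "unannotated"
  }
  out <- out[order(out$average_excess_hsa, out$compound), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$interaction_class <- classify_interaction(out$average_excess_hsa,
                                                thresholds)
  rownames(out) <- NULL
  front <- c("rank", "compound", "moa_class")
  out[c(front, setdiff(names(out), front))]
}

#' Mean average-ExcessHSA per mechanism-of-action class
#'
#' @param entries A rank table from [rank_compounds()].
#' @return Data frame `moa_class`, `n_compounds`, `mean_excess_hsa`,
#'   ordered most synergistic first. Classes with no compounds are simply
#'   absent.
#' @export
class_average <- function(entries) {
  agg <- stats::aggregate(average_excess_hsa ~ moa_class, entries, mean)
  names(agg)[2] <- "mean_excess_hsa"
  n <- stats::aggregate(compound ~ moa_class, entries, length)
  names(n)[2] <- "n_compounds"
  out <- merge(n, agg, by = "moa_class")
  out <- out[order(out$mean_excess_hsa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
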