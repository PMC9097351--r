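#' Z-prime (Z') plate quality factor
#'
#' Separation statistic between positive- and negative-control optical
#' densities, `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`.
#' Values approach 1 for well-separated, tight controls; screens
#' conventionally require Z' > 0.5-0.6.
#'
#' @param pos_ods Numeric vector of positive-control ODs (n >= 2).
#' @param neg_ods Numeric vector of negative-control (vehicle) ODs (n >= 2).
#' @return Z' as a single number, always <= 1. The score is invariant
#'   under any affine rescaling `od -> a * od + b` with `a > 0`.
#' @examples
#' z_factor(c(0.1, 0.1, 0.1), c(1, 1, 1))  # 1: zero-variance controls
#' @export
z_factor <- function(pos_ods, neg_ods) {
  if (length(pos_ods) < 2 || length(neg_ods) < 2) {
    abort("need at least 2 positive and 2 negative control wells",
          "insufficient_controls_error")
  }
  mu_p <- mean(pos_ods); mu_n <- mean(neg_ods)
  if (mu_p == mu_n) {
    abort("positive and negative control means coincide; Z' undefined",
          "undefined_separation_error")
  }
  1 - 3 * (stats::sd(pos_ods) + stats::sd(neg_ods)) / abs(mu_p - mu_n)
}

#' Per-plate control summary and Z' quality control
#'
#' @param records Well-record data frame (possibly many plates).
#' @param z_min Minimum Z' for a plate to pass (default 0.6, the primary
#'   96-well screen threshold; use 0.5 for a 384-well secondary screen).
#' @return A `plate_qc` data frame with one row per plate: control means
#'   and SDs, `z_factor` and logical `passed`.
#' @export
plate_qc <- function(records, z_min = 0.6) {
  out <- lapply(split(records, records$plate_id), function(p) {
    pos <- p$od[p$role == "pos_ctrl"]
    neg <- p$od[p$role == "neg_ctrl"]
    z <- z_factor(pos, neg)
    data.frame(plate_id = p$plate_id[1],
               mu_pos = mean(pos), sd_pos = stats::sd(pos),
               mu_neg = mean(neg), sd_neg = stats::sd(neg),
               z_factor = z, passed = z > z_min)
  })
  qc <- do.call(rbind, out)
  rownames(qc) <- NULL
  class(qc) <- c("plate_qc", "data.frame")
  qc
}
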