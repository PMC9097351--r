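#' Read a xenograft growth table
#'
#' @param path CSV with columns `animal_id, arm, day, volume_mm3`.
#' @return Validated data frame of per-animal tumor-volume measurements.
#' @export
read_growth_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("growth table not found: %s", path), "input_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "arm", "day", "volume_mm3")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(sprintf("growth table is missing column(s): %s",
                  paste(missing, collapse = ", ")), "input_format_error")
  }
  if (any(!is.finite(df$volume_mm3) | df$volume_mm3 <= 0)) {
    abort("volumes must be positive numbers", "input_format_error")
  }
  df[req]
}

#' Tumor growth inhibition (TGI) between two arms
#'
#' `TGI = 100 * [1 - (TVf_treated - TVi_treated) /
#' (TVf_control - TVi_control)]`, where TVi and TVf are the arm-mean
#' tumor volumes at the start and end of treatment. Start and end are
#' the first and last measurement days shared by both arms; animals
#' missing at the endpoint are excluded from the TVf mean and counted.
#' The statistic is invariant under any common rescaling of volumes.
#'
#' @param growth Growth data frame (`animal_id, arm, day, volume_mm3`).
#' @param treated_arm,control_arm Arm labels present in `growth`.
#' @param thresholds Named numeric with `responder` (default 60) and
#'   `regression` (default 100) TGI cutoffs; both strict inequalities.
#' @return An object of class `tgi_result`: the four mean volumes, `tgi`
#'   (percent), `responder`, `regression`, and `dropped_animals`.
#' @examples
#' g <- rbind(
#'   data.frame(animal_id = "c1", arm = "vehicle", day = c(0, 21),
#'              volume_mm3 = c(100, 900)),
#'   data.frame(animal_id = "t1", arm = "drug", day = c(0, 21),
#'              volume_mm3 = c(100, 300)))
#' tgi(g, "drug", "vehicle")  # 75%
#' @export
tgi <- function(growth, treated_arm, control_arm = "vehicle",
                thresholds = c(responder = 60, regression = 100)) {
  trt <- growth[growth$arm == treated_arm, , drop = FALSE]
  ctl <- growth[growth$arm == control_arm, , drop = FALSE]
  if (!nrow(trt) || !nrow(ctl)) {
    abort(sprintf("arm '%s' or '%s' has no measurements",
                  treated_arm, control_arm), "alignment_error")
  }
  shared <- intersect(unique(trt$day), unique(ctl$day))
  if (length(shared) < 2) {
    abort(sprintf("arms '%s' and '%s' share fewer than 2 measurement days",
                  treated_arm, control_arm), "alignment_error")
  }
  d0 <- min(shared); d1 <- max(shared)
  arm_mean <- function(a, day) mean(a$volume_mm3[a$day == day])
  n_drop <- function(a) {
    length(setdiff(a$animal_id[a$day == d0], a$animal_id[a$day == d1]))
  }
  tvi_t <- arm_mean(trt, d0); tvf_t <- arm_mean(trt, d1)
  tvi_c <- arm_mean(ctl, d0); tvf_c <- arm_mean(ctl, d1)
  if (tvf_c - tvi_c == 0) {
    abort("control arm shows zero net growth; TGI undefined",
          "undefined_tgi_error")
  }
  value <- 100 * (1 - (tvf_t - tvi_t) / (tvf_c - tvi_c))
  cls <- classify_response(value, thresholds)
  structure(list(arm = treated_arm, control_arm = control_arm,
                 tvi_treated = tvi_t, tvf_treated = tvf_t,
                 tvi_control = tvi_c, tvf_control = tvf_c,
                 day_start = d0, day_end = d1, tgi = value,
                 responder = cls$responder, regression = cls$regression,
                 dropped_animals = n_drop(trt) + n_drop(ctl)),
            class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("<tgi_result> %s vs %s (day %g-%g): TGI = %.2f%% [%s]\n",
              x$arm, x$control_arm, x$day_start, x$day_end, x$tgi,
              if (x$regression) "regression" else
                if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' Responder / regression classification of a TGI value
#'
#' @param tgi TGI percentage(s).
#' @param thresholds Named numeric, `responder` and `regression` cutoffs
#'   (strict `>`).
#' @return List with logical vectors `responder` and `regression`.
#' @export
classify_response <- function(tgi,
                              thresholds = c(responder = 60,
                                             regression = 100)) {
  if (any(!is.finite(tgi))) abort("TGI must be finite", "validation_error")
  list(responder = tgi > thresholds[["responder"]],
       regression = tgi > thresholds[["regression"]])
}

#' Per-arm TGI table against a common control arm
#'
#' @param growth Growth data frame.
#' @param control_arm Control arm label.
#' @param thresholds See [tgi()].
#' @return Data frame with one row per treated arm: `arm, tgi, responder,
#'   regression, dropped_animals`.
#' @export
tgi_table <- function(growth, control_arm = "vehicle",
                      thresholds = c(responder = 60, regression = 100)) {
  arms <- setdiff(unique(growth$arm), control_arm)
  if (!length(arms)) {
    abort("growth table contains no treated arm besides the control",
          "alignment_error")
  }
  rows <- lapply(arms, function(a) {
    r <- tgi(growth, a, control_arm, thresholds)
    data.frame(arm = a, tgi = r$tgi, responder = r$responder,
               regression = r$regression,
               dropped_animals = r$dropped_animals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immuno-reactive score (IRS) for IHC staining
#'
#' IRS = staining intensity (0 = negative, 1 = weak, 2 = moderate,
#' 3 = strong) multiplied by the positive-cell percentage category
#' (0% = 0, 1-10% = 1, 11-50% = 2, 51-80% = 3, 81-100% = 4), giving a
#' score in 0-12. Fractional percentages in (0, 1) fall in category 1
#' (any positivity scores at least 1).
#'
#' @param intensity Integer(s) in 0-3.
#' @param pct_positive Percentage(s) of positive tumor cells in 0-100.
#' @return Integer IRS in 0-12.
#' @examples
#' irs(3, 90)  # 12
#' irs(2, 30)  # 4
#' @export
irs <- function(intensity, pct_positive) {
  if (any(!intensity %in% 0:3)) {
    abort("intensity must be an integer in 0..3", "validation_error")
  }
  if (any(!is.finite(pct_positive) | pct_positive < 0 | pct_positive > 100)) {
    abort("pct_positive must lie in [0, 100]", "validation_error")
  }
  as.integer(intensity * irs_pct_category(pct_positive))
}

#' Positive-percentage category used by the IRS
#'
#' @param pct_positive Percentages in 0-100.
#' @return Integer category 0-4.
#' @export
irs_pct_category <- function(pct_positive) {
  ifelse(pct_positive == 0, 0L,
         ifelse(pct_positive <= 10, 1L,
                ifelse(pct_positive <= 50, 2L,
                       ifelse(pct_positive <= 80, 3L, 4L))))
}
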