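#' Serial dilution dose series
#'
#' @param top Top concentration (uM), > 0.
#' @param fold Constant dilution factor between points, > 1 (e.g. 5 for a
#'   1:5 series, 3 for a 1:3 series).
#' @param n Number of points, >= 1.
#' @return Descending dose vector `top, top/fold, ..., top/fold^(n-1)`.
#' @examples
#' dose_series(20, 5, 5)  # 20 4 0.8 0.16 0.032
#' @export
dose_series <- function(top, fold, n) {
  if (!is_number(top) || top <= 0) {
    abort("top concentration must be a positive number", "validation_error")
  }
  if (!is_number(fold) || fold <= 1) {
    abort("dilution fold must be > 1", "validation_error")
  }
  if (!is_number(n) || n < 1 || n != round(n)) {
    abort("number of points must be a positive integer", "validation_error")
  }
  top / fold^(0:(n - 1))
}

#' Specification of a simulated checkerboard response surface
#'
#' Defines the ground truth for one compound-pair block: single-agent
#' median-effect parameters, a Bliss interaction offset, the serial
#' dilution design, control-well counts, and the measurement noise model.
#' Single-agent effects follow `fa = 1 / (1 + (Dm/D)^m)`; combination
#' inhibition is the Bliss expectation `fa_a + fa_b - fa_a * fa_b` plus
#' `bliss_offset` (positive = extra inhibition = synergy), clipped to
#' `[0, 1]`. Measured OD is `blank + (vehicle_od - blank) * V/100` with
#' multiplicative lognormal noise of scale `noise_sigma`.
#'
#' @param dm_a,m_a,dm_b,m_b Median-effect parameters for the two agents
#'   (`Dm` in uM, `m` dimensionless).
#' @param bliss_offset Interaction offset on the inhibition-fraction
#'   scale; 0 gives an exactly Bliss-null surface.
#' @param noise_sigma SD of the lognormal multiplicative OD noise
#'   (default 0.03, a typical plate-reader CV).
#' @param top_a,fold_a,n_a,top_b,fold_b,n_b Dilution design per agent
#'   (defaults: 5-point 1:5 series from 20 uM, the 6x6 discovery design).
#' @param vehicle_od,blank_od Expected ODs of an untreated well and an
#'   empty well.
#' @param pos_viability Residual viability fraction in positive-control
#'   (cytotoxic) wells.
#' @param n_neg,n_pos,n_blank Numbers of extra vehicle, positive-control
#'   and blank wells per plate.
#' @param compound_a,compound_b,cell_line,plate_id Metadata.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `surface_spec` list.
#' @export
surface_spec <- function(dm_a = 1, m_a = 1, dm_b = 1, m_b = 1,
                         bliss_offset = 0, noise_sigma = 0.03,
                         top_a = 20, fold_a = 5, n_a = 5,
                         top_b = 20, fold_b = 5, n_b = 5,
                         vehicle_od = 1, blank_od = 0.05,
                         pos_viability = 0.02,
                         n_neg = 6, n_pos = 6, n_blank = 4,
                         compound_a = "anchor", compound_b = "partner",
                         cell_line = "CL1", plate_id = "P001",
                         seed = 1L) {
  if (blank_od >= vehicle_od) {
    abort("vehicle_od must exceed blank_od", "validation_error")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0", "validation_error")
  spec <- list(dm_a = dm_a, m_a = m_a, dm_b = dm_b, m_b = m_b,
               bliss_offset = bliss_offset, noise_sigma = noise_sigma,
               top_a = top_a, fold_a = fold_a, n_a = n_a,
               top_b = top_b, fold_b = fold_b, n_b = n_b,
               vehicle_od = vehicle_od, blank_od = blank_od,
               pos_viability = pos_viability,
               n_neg = n_neg, n_pos = n_pos, n_blank = n_blank,
               compound_a = compound_a, compound_b = compound_b,
               cell_line = cell_line, plate_id = plate_id,
               seed = as.integer(seed))
  structure(spec, class = "surface_spec")
}

me_fa <- function(d, dm, m) ifelse(d > 0, 1 / (1 + (dm / d)^m), 0)

# Noiseless truth for a surface spec: viability grid plus clipping count.
surface_truth <- function(spec) {
  doses_a <- c(0, rev(dose_series(spec$top_a, spec$fold_a, spec$n_a)))
  doses_b <- c(0, rev(dose_series(spec$top_b, spec$fold_b, spec$n_b)))
  fa_a <- me_fa(doses_a, spec$dm_a, spec$m_a)
  fa_b <- me_fa(doses_b, spec$dm_b, spec$m_b)
  bliss <- outer(fa_a, fa_b, function(a, b) a + b - a * b)
  inhib <- bliss
  combo <- outer(doses_a > 0, doses_b > 0, "&")
  inhib[combo] <- inhib[combo] + spec$bliss_offset
  clipped <- sum(inhib[combo] < 0 | inhib[combo] > 1)
  inhib <- pmin(pmax(inhib, 0), 1)
  list(doses_a = doses_a, doses_b = doses_b,
       viability = 100 * (1 - inhib),
       clipped_frac = clipped / sum(combo))
}

#' Simulate one checkerboard plate with known ground truth
#'
#' Generates the full long-format well table of one plate (block wells
#' plus vehicle, positive-control and blank wells) together with the
#' noiseless truth: the true [dose_matrix()] and its true
#' [score_matrix()] result. The same seed always yields identical output.
#'
#' @param spec A [surface_spec()].
#' @return List with `records` (well-record data frame in the
#'   [read_plate_table()] dialect), `truth_matrix`, `truth_score`, and
#'   `clipped_frac` (fraction of combination wells whose inhibition was
#'   clipped to `[0, 1]`; a warning is raised above 5%).
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  tr <- surface_truth(spec)
  if (tr$clipped_frac > 0.05) {
    warn(sprintf("%.1f%% of combination wells clipped to [0, 1] inhibition",
                 100 * tr$clipped_frac), "clipping_warning")
  }
  na <- length(tr$doses_a); nb <- length(tr$doses_b)
  i <- rep(seq_len(na), nb); j <- rep(seq_len(nb), each = na)
  block <- data.frame(
    plate_id = spec$plate_id, row = i, col = j,
    compound_a = spec$compound_a, dose_a = tr$doses_a[i],
    compound_b = spec$compound_b, dose_b = tr$doses_b[j],
    role = ifelse(i == 1 & j == 1, "neg_ctrl", "sample"),
    viability = tr$viability[cbind(i, j)])
  ctrl_row <- function(n, col, role, viability) {
    if (n < 1) return(NULL)
    data.frame(plate_id = spec$plate_id, row = seq_len(n), col = col,
               compound_a = "", dose_a = 0, compound_b = "", dose_b = 0,
               role = role, viability = viability)
  }
  wells <- rbind(block,
                 ctrl_row(spec$n_neg, nb + 2L, "neg_ctrl", 100),
                 ctrl_row(spec$n_pos, nb + 3L, "pos_ctrl",
                          100 * spec$pos_viability),
                 ctrl_row(spec$n_blank, nb + 4L, "blank", NA))
  set.seed(spec$seed)
  noise <- exp(stats::rnorm(nrow(wells), 0, spec$noise_sigma))
  signal <- ifelse(wells$role == "blank", spec$blank_od,
                   spec$blank_od +
                     (spec$vehicle_od - spec$blank_od) * wells$viability / 100)
  wells$od <- signal * noise
  wells$viability <- NULL
  truth_matrix <- dose_matrix(spec$compound_a, spec$compound_b,
                              tr$doses_a, tr$doses_b, tr$viability,
                              cell_line = spec$cell_line)
  list(records = wells, truth_matrix = truth_matrix,
       truth_score = score_matrix(truth_matrix),
       clipped_frac = tr$clipped_frac)
}

#' Default mechanism-class composition for a simulated screening library
#'
#' The default 162-compound library emulates the shape of an anchored
#' combination screen: a majority of targeted agents with a positive
#' Bliss interaction offset against the anchor (125 synergists across
#' PI3K-, EGFR-, MEK-, BRD4-, CDK-like and other targeted classes) plus
#' chemotherapy-like classes whose partners are nearly inert against the
#' anchor, giving additive (offset 0) or antagonistic (negative offset)
#' matrices. `partner_dm` is the partner's median-effect Dm; the large
#' values in the additive/antagonist classes make those partners
#' essentially inactive over the tested range, so their HSA and Bliss
#' excesses stay near zero unless the offset moves them.
#'
#' @return Data frame `moa_class, n, delta, partner_dm, partner_m`.
#' @export
default_library_classes <- function() {
  data.frame(
    moa_class = c("PI3K", "EGFR", "MEK", "BRD4", "CDK",
                  "targeted_other", "chemo_additive", "chemo_antagonist"),
    n = c(13L, 8L, 5L, 3L, 6L, 90L, 20L, 17L),
    delta = c(0.25, 0.20, 0.18, 0.20, 0.15, 0.12, 0, -0.12),
    partner_dm = c(1, 1.5, 2, 1, 1.2, 2, 2000, 2000),
    partner_m = c(1.2, 1.2, 1, 1.5, 1, 1, 1, 1))
}

#' Simulate a full anchored combination screen
#'
#' Builds one checkerboard plate per compound x cell line with known
#' per-compound interaction offsets, plus the compound annotation table
#' and a truth table of noiseless scores and labels. Per-compound offsets
#' are the class offset jittered multiplicatively (uniform 0.8-1.2,
#' seeded), which spreads ranks without moving any compound across the
#' synergy/additivity boundary.
#'
#' @param classes Class composition table, see
#'   [default_library_classes()].
#' @param cell_lines Character vector of cell-line labels (default four,
#'   the discovery-screen shape).
#' @param anchor_dm Per-cell-line anchor Dm values, recycled over
#'   `cell_lines`.
#' @param design List with `top`, `fold`, `n` for the dilution design of
#'   both agents (default 5-point 1:5 from 20 uM, i.e. 6x6 blocks).
#' @param noise_sigma OD noise SD applied to every plate.
#' @param seed Master seed; per-plate seeds are derived from it.
#' @return List: `records` (all plates, one data frame), `manifest`
#'   (`plate_id, compound_a, compound_b, cell_line`), `annotations`
#'   (`compound, moa_class`), `truth_plate` (per-plate noiseless sums and
#'   class), `truth_compound` (per-compound offset, average noiseless
#'   ExcessHSA and label).
#' @export
simulate_library <- function(classes = default_library_classes(),
                             cell_lines = paste0("CL", 1:4),
                             anchor_dm = c(0.8, 1, 1.3, 2),
                             design = list(top = 20, fold = 5, n = 5),
                             noise_sigma = 0, seed = 1L) {
  n_compounds <- sum(classes$n)
  compounds <- sprintf("compound_%03d", seq_len(n_compounds))
  cls <- rep(classes$moa_class, classes$n)
  set.seed(seed)
  delta <- rep(classes$delta, classes$n) * stats::runif(n_compounds, 0.8, 1.2)
  pdm <- rep(classes$partner_dm, classes$n)
  pm <- rep(classes$partner_m, classes$n)
  anchor_dm <- rep_len(anchor_dm, length(cell_lines))

  records <- vector("list", n_compounds * length(cell_lines))
  truth <- vector("list", length(records))
  manifest <- vector("list", length(records))
  idx <- 0L
  for (c_i in seq_len(n_compounds)) {
    for (l_i in seq_along(cell_lines)) {
      idx <- idx + 1L
      pid <- sprintf("P%04d_%s", c_i, cell_lines[l_i])
      spec <- surface_spec(
        dm_a = anchor_dm[l_i], m_a = 1, dm_b = pdm[c_i], m_b = pm[c_i],
        bliss_offset = delta[c_i], noise_sigma = noise_sigma,
        top_a = design$top, fold_a = design$fold, n_a = design$n,
        top_b = design$top, fold_b = design$fold, n_b = design$n,
        compound_a = "anchor", compound_b = compounds[c_i],
        cell_line = cell_lines[l_i], plate_id = pid,
        seed = (seed + idx) %% .Machine$integer.max)
      sim <- suppressWarnings(simulate_matrix(spec))
      records[[idx]] <- sim$records
      manifest[[idx]] <- data.frame(plate_id = pid, compound_a = "anchor",
                                    compound_b = compounds[c_i],
                                    cell_line = cell_lines[l_i])
      ts <- sim$truth_score
      truth[[idx]] <- data.frame(plate_id = pid, compound = compounds[c_i],
                                 cell_line = cell_lines[l_i],
                                 excess_hsa_sum = ts$excess_hsa_sum,
                                 excess_bliss_sum = ts$excess_bliss_sum,
                                 interaction_class = ts$interaction_class)
    }
  }
  truth_plate <- do.call(rbind, truth)
  avg <- stats::aggregate(excess_hsa_sum ~ compound, truth_plate, mean)
  truth_compound <- data.frame(
    compound = compounds, moa_class = cls, delta = delta,
    avg_excess_hsa = avg$excess_hsa_sum[match(compounds, avg$compound)])
  truth_compound$label <- classify_interaction(truth_compound$avg_excess_hsa)
  list(records = do.call(rbind, records),
       manifest = do.call(rbind, manifest),
       annotations = data.frame(compound = compounds, moa_class = cls),
       truth_plate = truth_plate,
       truth_compound = truth_compound)
}

#' Loewe-additive sham-combination matrix
#'
#' Builds a checkerboard for two copies of the same median-effect drug in
#' which each combination well's effect equals the single-agent effect at
#' the summed dose `d1 + d2`. By construction the combination index is
#' exactly 1 at every well, making this the reference oracle for CI
#' computations.
#'
#' @param dm,m Median-effect parameters of the (shared) drug.
#' @param doses Positive dose levels used for both axes.
#' @return A [dose_matrix()].
#' @export
loewe_matrix <- function(dm = 1, m = 1, doses = c(0.125, 0.25, 0.5, 1, 2)) {
  doses <- sort(doses)
  d <- c(0, doses)
  v <- 100 * (1 - outer(d, d, function(a, b) me_fa(a + b, dm, m)))
  dose_matrix("drug", "drug-copy", d, d, v)
}

#' Specification of a simulated xenograft growth experiment
#'
#' Arms grow exponentially: control volume `V(t) = V0 * exp(k t)` and a
#' treated arm with effect fraction `e` grows at rate `k (1 - e)` (so
#' `e = 1` is stasis and `e > 1` regression). Measurement noise is
#' multiplicative lognormal per observation.
#'
#' @param v0 Baseline volume (mm^3) at treatment start.
#' @param k Control growth rate per day.
#' @param effects Named numeric of per-arm effect fractions; must include
#'   the control arm with effect 0 (default arm name `"vehicle"`).
#' @param sigma Lognormal measurement-noise SD.
#' @param n_animals Animals per arm.
#' @param days Measurement days from treatment start (default twice
#'   weekly over 21 days).
#' @param seed Integer seed.
#' @return A `growth_spec` list.
#' @export
growth_spec <- function(v0 = 100, k = 0.1,
                        effects = c(vehicle = 0, combo = 1.1),
                        sigma = 0.1, n_animals = 7,
                        days = c(0, 3, 7, 10, 14, 17, 21), seed = 1L) {
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    abort("effects must be a named vector of arms", "validation_error")
  }
  if (length(days) < 2 || is.unsorted(days, strictly = TRUE)) {
    abort("days must be >= 2 strictly increasing timepoints",
          "validation_error")
  }
  structure(list(v0 = v0, k = k, effects = effects, sigma = sigma,
                 n_animals = as.integer(n_animals), days = days,
                 seed = as.integer(seed)),
            class = "growth_spec")
}

#' Simulate xenograft growth arms with known true TGI
#'
#' @param spec A [growth_spec()].
#' @return List with `curves` (long data frame `animal_id, arm, day,
#'   volume_mm3`) and `truth` (per treated arm: effect and the
#'   closed-form noiseless TGI
#'   `100 * (1 - (exp(k (1 - e) T) - 1) / (exp(k T) - 1))` with `T` the
#'   last measurement day).
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  set.seed(spec$seed)
  arms <- names(spec$effects)
  curves <- do.call(rbind, lapply(arms, function(a) {
    e <- spec$effects[[a]]
    do.call(rbind, lapply(seq_len(spec$n_animals), function(an) {
      mu <- spec$v0 * exp(spec$k * (1 - e) * spec$days)
      data.frame(animal_id = sprintf("%s_%02d", a, an), arm = a,
                 day = spec$days,
                 volume_mm3 = mu * exp(stats::rnorm(length(spec$days), 0,
                                                    spec$sigma)))
    }))
  }))
  rownames(curves) <- NULL
  control <- arms[spec$effects == 0][1]
  tt <- max(spec$days)
  treated <- setdiff(arms, control)
  truth <- data.frame(
    arm = treated,
    effect = unname(spec$effects[treated]),
    true_tgi = 100 * (1 - (exp(spec$k * (1 - spec$effects[treated]) * tt) - 1) /
                        (exp(spec$k * tt) - 1)))
  rownames(truth) <- NULL
  list(curves = curves, truth = truth, control_arm = control)
}
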