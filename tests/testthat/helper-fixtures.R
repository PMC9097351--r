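# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal hand-built dose matrix from explicit margins and combo grid.
make_matrix <- function(doses_a, doses_b, viability, ...) {
  dose_matrix("drugA", "drugB", doses_a, doses_b, viability, ...)
}

# 3x3 matrix (2 doses per drug) where every combination well equals the
# HSA reference and the single agents are Bliss-consistent with it.
hsa_identity_matrix <- function() {
  v <- rbind(c(100, 100, 100),
             c(80,  80,  80),
             c(50,  50,  50))
  make_matrix(c(0, 1, 2), c(0, 1, 2), v)
}

# Exactly Bliss-null matrix built from multiplying survival fractions.
bliss_null_matrix <- function(va = c(100, 80, 50), vb = c(100, 90, 40)) {
  make_matrix(c(0, 1, 2)[seq_along(va)], c(0, 1, 2)[seq_along(vb)],
              outer(va, vb) / 100)
}

# One simulated plate's records with deliberately ruined controls, to
# exercise the failed-QC exclusion policy.
failed_qc_plate <- function(plate_id = "BAD1") {
  spec <- surface_spec(noise_sigma = 0, plate_id = plate_id, seed = 3L)
  rec <- simulate_matrix(spec)$records
  pos <- rec$role == "pos_ctrl"
  rec$od[pos] <- rec$od[pos] + c(0, 0.9, 0, 0.9, 0, 0.9)  # huge pos-ctrl SD
  rec
}
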