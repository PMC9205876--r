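# Small, fast fixtures built in code.

# compact cohort: small grid and ring so a full feature extraction stays fast
small_cohort_spec <- function(n_subjects = 3L, seed = 1L, modality = "T1",
                              ...) {
  cohort_spec(
    n_subjects = n_subjects, modality = modality,
    matrix_shape = c(48L, 48L), spacing_range_mm = c(1.77, 2.34),
    ring_inner_mm = 8, ring_outer_mm = 16,
    seed = seed, ...
  )
}

# a quant_map/roi_mask pair with a rectangular ROI and reproducible values
toy_map <- function(values, spacing = 1, modality = "T1", id = "toy") {
  quant_map(values, spacing, modality, id)
}

rect_mask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  roi_mask(m)
}
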