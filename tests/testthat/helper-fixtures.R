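# Shared fixtures: distribution-spec rows and small deterministic tables.

make_spec <- function(parameter, law, p1, p2 = NA_real_, p3 = NA_real_,
                      lower = NA_real_, upper = NA_real_) {
  data.frame(parameter = parameter, population = NA_character_,
             region = NA_character_, law = law, p1 = p1, p2 = p2, p3 = p3,
             lower = lower, upper = upper, units = "",
             stringsAsFactors = FALSE)
}

# ingestion-only point-mass exposure set (child-like scenario used in the
# worked dose example); C is replaced per test
point_specs <- function(C = make_spec("C", "point", 1)) {
  rbind(C,
        make_spec("BA", "point", 1),
        make_spec("IngR", "point", 100),
        make_spec("InhR", "point", 0),
        make_spec("EF", "point", 350),
        make_spec("ED", "point", 6),
        make_spec("BW", "point", 15),
        make_spec("AT", "point", 2190),
        make_spec("PEF", "point", 1.36e9),
        make_spec("SA", "point", 0),
        make_spec("AF", "point", 0),
        make_spec("ABF", "point", 0))
}

ingestion_only_tox <- function(sf = 6.1) {
  data.frame(pathway = c("ingestion", "inhalation", "dermal"),
             rfd = c(1e-3, NA_real_, NA_real_),
             sf = c(sf, NA_real_, NA_real_),
             stringsAsFactors = FALSE)
}

full_ctx <- function() {
  list(C = 1, BA = 1, IngR = 100, InhR = 14.5, EF = 350, ED = 6, BW = 15,
       AT = 2190, PEF = 1.36e9, SA = 2000, AF = 0.2, ABF = 0.001)
}

# normalized imputation error over masked cells: per-column errors are
# scaled by the complete-data column sd (missForest-style NRMSE) so that
# wide-scaled properties do not dominate the comparison
nrmse_on_mask <- function(completed, mask, col_sds) {
  sqrt(mean(vapply(seq_len(nrow(mask)), function(i) {
    ((completed[mask$row[i], mask$column[i]] - mask$value[i]) /
       col_sds[[mask$column[i]]])^2
  }, numeric(1))))
}

# exact affine ground truth (no noise, no interaction, no method offsets)
affine_truth <- function() {
  default_ground_truth(sigma_noise = 0, interaction_strength = 0,
                       method_shifts = c(PBET = 0, UBM = 0, DIN = 0,
                                         IVG = 0, SBET = 0))
}
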