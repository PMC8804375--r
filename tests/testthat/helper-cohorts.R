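# shared fixtures built in code

# a small deterministic simulated cohort reused across tests
small_cohort <- function(seed = 101, n = c(8L, 6L, 9L, 12L)) {
  generate_cohort(generator_config(groups = group_calibration(n), seed = seed))
}

# hand-assembled 1-subject cohort with a constant grid
constant_cohort <- function(value = 50, bme1 = 0L, bme2 = 0L,
                            diagnosis = "HC") {
  grid <- as.list(setNames(rep(value, 72), c(pdff_cols(1), pdff_cols(2))))
  tibble::as_tibble(c(
    list(subject_id = "X1", diagnosis = diagnosis, age = 30, sex = "M",
         bmi = 22, disease_duration = NA_real_, hla_b27 = NA_integer_,
         smoking = 0L, bdmards = NA_integer_, asdas = NA_real_,
         mny = NA_integer_, bme_r1 = bme1, bme_r2 = bme2),
    grid
  ))
}

# set one reader's grid of one subject from a length-36 vector
set_grid <- function(cohort, row, reader, values) {
  stopifnot(length(values) == 36)
  cohort[row, pdff_cols(reader)] <- as.list(values)
  cohort
}
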