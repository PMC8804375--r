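#' Diagnosis groups and ROI grid layout
#'
#' The study design distinguishes four diagnosis groups: healthy controls
#' (`HC`), patients with back pain not attributable to spondyloarthritis
#' (`nonSpA`), and the non-radiographic (`nr-axSpA`) and radiographic
#' (`r-axSpA`) subtypes of axial spondyloarthritis. The two axSpA subtypes
#' are the positive class for every diagnostic-accuracy computation.
#'
#' PDFF is measured on a fixed grid: 3 consecutive semi-coronal slices,
#' 4 joint quadrants (left/right sacral and iliac sides: `LS`, `LI`, `RS`,
#' `RI`), and 3 circular ROIs per quadrant per slice — 36 ROI values per
#' reader, 72 per subject with two readers.
#'
#' @return `diagnosis_levels()` returns the four group labels in display
#'   order. `quadrant_levels()` returns the four quadrant codes.
#'   `pdff_cols(reader)` returns the 36 column names holding that reader's
#'   ROI grid, in slice-major order.
#' @examples
#' diagnosis_levels()
#' head(pdff_cols(1))
#' @export
diagnosis_levels <- function() c("HC", "nonSpA", "nr-axSpA", "r-axSpA")

#' @rdname diagnosis_levels
#' @export
quadrant_levels <- function() c("LS", "LI", "RS", "RI")

#' @rdname diagnosis_levels
#' @param reader Reader number, 1 or 2.
#' @export
pdff_cols <- function(reader) {
  stopifnot(reader %in% c(1L, 2L))
  grid <- roi_grid()
  sprintf("pdff_r%d_s%d_%s_%d", reader, grid$slice, grid$quadrant, grid$roi)
}

# canonical (slice, quadrant, roi) enumeration: slice-major, then quadrant,
# then roi, so cell j of a grid vector is roi_grid()[j, ]
roi_grid <- function() {
  tidyr::expand_grid(
    slice = 1:3,
    quadrant = quadrant_levels(),
    roi = 1:3
  )
}

#' Is a diagnosis label an axSpA case?
#'
#' @param diagnosis Character or factor vector of group labels
#'   (see [diagnosis_levels()]).
#' @return Logical vector: `TRUE` for `nr-axSpA` and `r-axSpA`, `FALSE` for
#'   `HC` and `nonSpA`.
#' @examples
#' is_axspa(c("HC", "r-axSpA"))
#' @export
is_axspa <- function(diagnosis) {
  as.character(diagnosis) %in% c("nr-axSpA", "r-axSpA")
}

cohort_flag_cols <- function() c("hla_b27", "smoking", "bdmards", "mny", "bme_r1", "bme_r2")

cohort_cols <- function() {
  c(
    "subject_id", "diagnosis", "age", "sex", "bmi", "disease_duration",
    "hla_b27", "smoking", "bdmards", "asdas", "mny", "bme_r1", "bme_r2",
    pdff_cols(1), pdff_cols(2)
  )
}

#' Validate a cohort table
#'
#' Checks the structural invariants every downstream computation assumes:
#' all 85 required columns present (13 clinical plus 72 ROI values), unique
#' subject identifiers, known diagnosis labels, PDFF values finite and in
#' \[0, 100\], binary flags coded 0/1 (NA allowed only where a field does
#' not apply), non-missing bone-marrow-edema reads for both readers, and
#' positive age/BMI. Incomplete ROI grids are a hard error naming the
#' subject and the missing or invalid (slice, quadrant, ROI) cell — the
#' measurement protocol always places all 36 ROIs, so a missing cell
#' signals a corrupted file, not censored data.
#'
#' @param cohort A data frame in the wide one-row-per-subject layout
#'   (see [read_cohort()]).
#' @return The validated cohort as a tibble (invisibly unchanged), with
#'   `diagnosis` as a factor over [diagnosis_levels()].
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_cols(), names(cohort))
  if (length(missing_cols) > 0) {
    roi_missing <- grep("^pdff_", missing_cols, value = TRUE)
    if (length(roi_missing) > 0) {
      stop("cohort is missing ROI cell column(s): ",
           paste(roi_missing, collapse = ", "), call. = FALSE)
    }
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id) > 0) {
    stop("duplicated subject_id values", call. = FALSE)
  }
  bad_dx <- setdiff(unique(as.character(cohort$diagnosis)), diagnosis_levels())
  if (length(bad_dx) > 0) {
    stop("unknown diagnosis label(s): ", paste(bad_dx, collapse = ", "),
         call. = FALSE)
  }
  cohort$diagnosis <- factor(as.character(cohort$diagnosis),
                             levels = diagnosis_levels())
  if (nrow(cohort) > 0) {
    bad_sex <- setdiff(unique(as.character(cohort$sex)), c("M", "F"))
    if (length(bad_sex) > 0) {
      stop("sex must be 'M' or 'F'; saw: ", paste(bad_sex, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(cohort$age) | cohort$age <= 0)) {
      stop("age must be finite and positive", call. = FALSE)
    }
    if (any(!is.finite(cohort$bmi) | cohort$bmi <= 0)) {
      stop("bmi must be finite and positive", call. = FALSE)
    }
    dur <- cohort$disease_duration
    if (any(!is.na(dur) & dur < 0)) {
      stop("disease_duration must be >= 0 when present", call. = FALSE)
    }
    for (fl in cohort_flag_cols()) {
      v <- cohort[[fl]]
      if (any(!is.na(v) & !v %in% c(0, 1))) {
        stop("column '", fl, "' must be coded 0/1 (NA where not applicable)",
             call. = FALSE)
      }
    }
    if (anyNA(cohort$bme_r1) || anyNA(cohort$bme_r2)) {
      stop("bme_r1 and bme_r2 must be non-missing for every subject",
           call. = FALSE)
    }
    for (rd in 1:2) {
      pm <- as.matrix(cohort[, pdff_cols(rd)])
      bad <- which(!is.finite(pm) | pm < 0 | pm > 100, arr.ind = TRUE)
      if (nrow(bad) > 0) {
        i <- bad[1, 1]; j <- bad[1, 2]
        cell <- roi_grid()[j, ]
        stop(sprintf(
          "subject '%s', reader %d: PDFF at slice %d quadrant %s roi %d is missing or outside [0, 100]",
          cohort$subject_id[i], rd, cell$slice, cell$quadrant, cell$roi
        ), call. = FALSE)
      }
    }
  }
  cohort
}

#' Read and write a cohort CSV
#'
#' The on-disk format is a UTF-8, comma-delimited file with a header row and
#' one row per subject: `subject_id`, `diagnosis` (`HC`, `nonSpA`,
#' `nr-axSpA`, `r-axSpA`), `age`, `sex` (`M`/`F`), `bmi`,
#' `disease_duration`, `hla_b27`, `smoking`, `bdmards`, `asdas`, `mny`,
#' `bme_r1`, `bme_r2`, followed by the 72 ROI columns
#' `pdff_r{reader}_s{slice}_{LS|LI|RS|RI}_{roi}`. Flags are coded 0/1;
#' fields that do not apply to a group (e.g. disease duration for healthy
#' controls, modified New York status for non-cases) carry the explicit
#' missing marker `NA`, never zero.
#' Numeric values round-trip at full double precision.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort tibble with a
#'   `provenance` attribute recording the source file. `write_cohort()`
#'   writes `cohort` to `path` and returns `path` invisibly.
#' @seealso [validate_cohort()] for the invariants enforced on load,
#'   [generate_cohort()] to simulate a cohort.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spec <- readr::cols(
    subject_id = readr::col_character(),
    diagnosis = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_double()
  )
  cohort <- readr::read_csv(path, col_types = spec, progress = FALSE)
  for (fl in cohort_flag_cols()) {
    if (fl %in% names(cohort)) cohort[[fl]] <- as.integer(cohort[[fl]])
  }
  cohort <- validate_cohort(cohort)
  attr(cohort, "provenance") <- paste0("read from ", path)
  cohort
}

#' @rdname read_cohort
#' @param cohort A valid cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- dplyr::mutate(cohort, diagnosis = as.character(.data$diagnosis))
  readr::write_csv(out[, cohort_cols()], path, progress = FALSE)
  invisible(path)
}
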