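#' Hemolysis QC filter on plasma samples
#'
#' Free hemoglobin absorbs at 414 nm; plasma samples with A414 above 0.2 are
#' discarded as hemolyzed (exactly 0.2 is kept). Because downstream dose
#' equalization needs every timepoint of a subject, a subject is retained
#' only if all of their timepoints pass; samples with missing A414 are
#' flagged and treated as failing.
#'
#' @param samples data frame with at least `subject`, `timepoint`, `a414`.
#' @param threshold absorbance cutoff (default 0.2).
#' @return List with `kept` and `discarded` sample tables (the `discarded`
#'   table gains a `reason` column: `hemolysis`, `missing_a414` or
#'   `subject_failed`) and `subjects_excluded`.
#' @export
hemolysis_filter <- function(samples, threshold = 0.2) {
  needed <- c("subject", "timepoint", "a414")
  stopifnot(is.data.frame(samples), all(needed %in% names(samples)))
  fail_missing <- is.na(samples$a414)
  fail_hemo <- !fail_missing & samples$a414 > threshold
  sample_fail <- fail_missing | fail_hemo
  bad_subjects <- unique(samples$subject[sample_fail])
  in_bad <- samples$subject %in% bad_subjects
  discarded <- samples[in_bad, , drop = FALSE]
  if (nrow(discarded)) {
    discarded$reason <- ifelse(fail_missing[in_bad], "missing_a414",
                               ifelse(fail_hemo[in_bad], "hemolysis",
                                      "subject_failed"))
  }
  kept <- samples[!in_bad, , drop = FALSE]
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded,
       subjects_excluded = bad_subjects)
}

#' Within-subject EV dose equalization
#'
#' Equalizes the EV dose across a subject's blood-collection timepoints by
#' dilution: every timepoint is diluted down to the subject's lowest
#' measured EV concentration, so the same number of vesicles is used at
#' every timepoint while individual differences between subjects are kept.
#'
#' @param samples data frame for one or more subjects with `subject`,
#'   `timepoint`, `concentration` (particles/mL, > 0).
#' @return Data frame of class `dose_plan` with `dilution_factor` (>= 1, and
#'   exactly 1 at each subject's minimum-concentration timepoint) and
#'   `effective_concentration` (equal within subject).
#' @export
equalize_dose <- function(samples) {
  needed <- c("subject", "timepoint", "concentration")
  stopifnot(is.data.frame(samples), all(needed %in% names(samples)))
  if (any(!is.finite(samples$concentration)) ||
      any(samples$concentration <= 0)) {
    stopf("EV concentrations must be positive to plan dilutions")
  }
  if (anyDuplicated(samples[c("subject", "timepoint")])) {
    stopf("invariant violated: one sample per subject x timepoint")
  }
  plan <- do.call(rbind, lapply(split(samples, samples$subject), function(s) {
    lo <- min(s$concentration)
    s$dilution_factor <- s$concentration / lo
    s$effective_concentration <- lo   # conc / (conc / lo), exactly
    s
  }))
  rownames(plan) <- NULL
  class(plan) <- c("dose_plan", "data.frame")
  plan
}

#' Pool EV samples of one group and timepoint
#'
#' Combines the EV isolates of the individual donors of one intervention
#' group at one timepoint into a single lot. By default each donor
#' contributes the same number of particles (the largest count every donor
#' can supply); `method = "full_volume"` instead pools the entire available
#' volume of every sample.
#'
#' @param samples data frame with `subject`, `group`, `timepoint`,
#'   `concentration` (particles/mL), `volume` (mL).
#' @param method `"equal_particles"` or `"full_volume"`.
#' @return List with `total_particles`, `volume` (mL), `concentration`
#'   (particles/mL), `contributions` (per-donor particles and volume taken),
#'   `group`, `timepoint`, `method`.
#' @export
pool_samples <- function(samples, method = c("equal_particles",
                                             "full_volume")) {
  method <- match.arg(method)
  needed <- c("subject", "group", "timepoint", "concentration", "volume")
  stopifnot(is.data.frame(samples), all(needed %in% names(samples)),
            nrow(samples) >= 1L)
  if (length(unique(samples$group)) != 1L ||
      length(unique(samples$timepoint)) != 1L) {
    stopf("pooling mixes groups or timepoints; pool one group x timepoint at a time")
  }
  if (any(samples$concentration <= 0) || any(samples$volume <= 0)) {
    stopf("concentrations and volumes must be positive")
  }
  avail <- samples$concentration * samples$volume
  if (method == "equal_particles") {
    per_donor <- min(avail)
    vol_taken <- per_donor / samples$concentration
    particles <- rep(per_donor, nrow(samples))
  } else {
    vol_taken <- samples$volume
    particles <- avail
  }
  contributions <- data.frame(subject = samples$subject,
                              particles = particles,
                              volume_ml = vol_taken)
  total <- sum(particles); vol <- sum(vol_taken)
  list(total_particles = total, volume = vol, concentration = total / vol,
       contributions = contributions,
       group = samples$group[1], timepoint = samples$timepoint[1],
       method = method)
}

#' Normalize assay readouts to the pre-intervention timepoint
#'
#' Within-subject normalization used before between-group comparisons:
#' every post-intervention readout is divided by the same subject's
#' pre-intervention readout, so pre maps to exactly 1 and the values are
#' unit-free. Subjects whose pre value is 0 (or missing) cannot be
#' normalized and are excluded with a warning.
#'
#' @param readouts data frame with `subject`, `timepoint`, `value`.
#' @param pre_label the label of the pre-intervention timepoint.
#' @return The readouts with a `normalized_value` column, excluded subjects
#'   dropped.
#' @export
normalize_to_pre <- function(readouts, pre_label = "pre") {
  needed <- c("subject", "timepoint", "value")
  stopifnot(is.data.frame(readouts), all(needed %in% names(readouts)))
  out <- do.call(rbind, lapply(split(readouts, readouts$subject),
                               function(s) {
    pre <- s$value[s$timepoint == pre_label]
    if (length(pre) != 1L || is.na(pre) || pre == 0) {
      warnf("subject '%s' has no usable '%s' readout; excluded",
            s$subject[1], pre_label)
      return(NULL)
    }
    s$normalized_value <- s$value / pre
    s
  }))
  rownames(out) <- NULL
  out
}
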