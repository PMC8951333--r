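#' Hargreaves trimmed-mean withdrawal latency
#'
#' Session summary of the thermal-pain (plantar) test: of the five
#' withdrawal latencies measured per hind paw, one highest and one lowest
#' value are removed and the mean of the remaining three is returned.
#'
#' @param latencies exactly five positive withdrawal latencies, seconds.
#' @return Trimmed-mean latency, seconds.
#' @export
hargreaves_latency <- function(latencies) {
  if (length(latencies) != 5L) {
    stopf("Hargreaves session must have exactly 5 trials, got %d",
          length(latencies))
  }
  if (any(!is.finite(latencies)) || any(latencies <= 0)) {
    stopf("withdrawal latencies must be positive and finite")
  }
  mean(sort(latencies)[2:4])
}

#' Corner-test right-turn frequency
#'
#' Fraction of right turns over the ten corner-test trials of one session.
#' After a left-side occlusion, contralateral sensory/motor deficits raise
#' this frequency above the 0.5 of an intact mouse.
#'
#' @param turns exactly ten outcomes, each `"L"` or `"R"`.
#' @return Right-turn frequency in `[0, 1]`.
#' @export
corner_right_frequency <- function(turns) {
  if (length(turns) != 10L) {
    stopf("corner test must have exactly 10 trials, got %d", length(turns))
  }
  if (!all(turns %in% c("L", "R"))) {
    stopf("corner-test outcomes must be 'L' or 'R'")
  }
  sum(turns == "R") / 10
}

#' Validate tMCAO induction from the neuroscore
#'
#' Five-point neurological scale: 0 no deficit, 1 failure to fully extend
#' the right forepaw, 2 circling to the left, 3 falling to the left, 4 no
#' spontaneous walking / decreased consciousness. A score of 1-4 counts as
#' successful stroke induction.
#'
#' @param score integer score in 0..4.
#' @return `TRUE` if the occlusion counts as successfully induced.
#' @export
validate_tmcao_induction <- function(score) {
  if (length(score) != 1L || !is.numeric(score) || is.na(score) ||
      score != round(score) || score < 0 || score > 4) {
    stopf("neuroscore must be a single integer in 0..4, got %s",
          paste(score, collapse = ", "))
  }
  score >= 1
}

#' Summarise behavioral trial tables
#'
#' Applies the per-session endpoint to tidy trial tables as produced by
#' [generate_behavior_dataset()]: the Hargreaves trimmed mean per
#' animal/day/paw, and the right-turn frequency per animal/day.
#'
#' @param hargreaves data frame with `animal`, `group`, `day`, `paw`,
#'   `trial`, `latency_s` (5 trials per session).
#' @param corner data frame with `animal`, `group`, `day`, `trial`, `turn`
#'   (10 trials per session).
#' @return List of session-level data frames `hargreaves` (with
#'   `latency_s`) and `corner` (with `right_freq`).
#' @export
summarize_behavior <- function(hargreaves = NULL, corner = NULL) {
  out <- list()
  if (!is.null(hargreaves)) {
    key <- interaction(hargreaves$animal, hargreaves$day, hargreaves$paw,
                       drop = TRUE)
    out$hargreaves <- do.call(rbind, lapply(split(hargreaves, key),
                                            function(s) data.frame(
      animal = s$animal[1], group = s$group[1], day = s$day[1],
      paw = s$paw[1], latency_s = hargreaves_latency(s$latency_s))))
    rownames(out$hargreaves) <- NULL
  }
  if (!is.null(corner)) {
    key <- interaction(corner$animal, corner$day, drop = TRUE)
    out$corner <- do.call(rbind, lapply(split(corner, key),
                                        function(s) data.frame(
      animal = s$animal[1], group = s$group[1], day = s$day[1],
      right_freq = corner_right_frequency(s$turn))))
    rownames(out$corner) <- NULL
  }
  out
}
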