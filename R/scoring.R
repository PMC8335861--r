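#' Disease durations at a survey wave
#'
#' Computes \eqn{T_j}, the number of years a respondent has lived with each
#' diagnosed disease by a given wave. Two reference conventions are
#' supported: `"diagnosis_year"` counts from the stated year of onset, while
#' `"first_report"` counts from the survey wave at which the diagnosis was
#' first reported (self-reported onset timing in panel surveys is often
#' ambiguous, so both are offered).
#'
#' @param onsets named numeric vector mapping disease id to onset year;
#'   diseases never diagnosed are simply absent.
#' @param wave_year calendar year of the wave.
#' @param convention `"diagnosis_year"` (default) or `"first_report"`.
#' @param first_report named numeric vector mapping disease id to the year of
#'   first report; required when `convention = "first_report"`.
#' @return named numeric vector of durations in years (diseases without
#'   onset omitted), floored at 0.
#' @examples
#' disease_duration(c(hypertension = 2011), 2018)
#' @export
disease_duration <- function(onsets, wave_year,
                             convention = c("diagnosis_year", "first_report"),
                             first_report = NULL) {
  convention <- match.arg(convention)
  if (length(onsets) == 0) return(stats::setNames(numeric(0), character(0)))
  if (any(onsets > wave_year))
    stop("onset year after wave year for disease(s): ",
         paste(names(onsets)[onsets > wave_year], collapse = ", "))
  ref <- if (convention == "diagnosis_year") {
    onsets
  } else {
    if (is.null(first_report))
      stop("first_report years required under the first_report convention")
    missing <- setdiff(names(onsets), names(first_report))
    if (length(missing))
      stop("no first-report year for disease(s): ", paste(missing, collapse = ", "))
    first_report[names(onsets)]
  }
  pmax(wave_year - ref, 0)
}

#' Score one person-wave: durations to YLDs
#'
#' Applies the disability-weight registry to a set of disease durations:
#' \eqn{YLD_j = W_j T_j} per disease and \eqn{YLD_{all} = \sum_j YLD_j}.
#' For chronic non-fatal conditions the YLDs are treated as the DALYs.
#'
#' @param durations named numeric vector of disease durations in years.
#' @param table a `daly_weight_table` (default [disease_weights()]).
#' @return list with `per_disease` (named numeric, \eqn{W_j T_j}) and
#'   `total` (their sum).
#' @examples
#' score_person_wave(c(hypertension = 5))$total # 1.8
#' @export
score_person_wave <- function(durations, table = disease_weights()) {
  validate_weight_table(table)
  if (length(durations) == 0)
    return(list(per_disease = stats::setNames(numeric(0), character(0)), total = 0))
  unknown <- setdiff(names(durations), table$disease)
  if (length(unknown))
    stop("unknown disease id(s): ", paste(unknown, collapse = ", "))
  if (any(durations < 0)) stop("durations must be nonnegative")
  w <- stats::setNames(table$weight, table$disease)[names(durations)]
  per <- w * durations
  list(per_disease = per, total = sum(per))
}

#' Score an entire panel
#'
#' Computes per-disease and total YLDs (treated as DALYs) for every observed
#' person-wave in a long-format panel. Onset years are read from the
#' `onset_<disease>` columns; under the `"first_report"` convention each
#' disease's reference year is the earliest of the person's observed waves at
#' or after the onset year.
#'
#' @param panel a `panel_dataset` (or plain data frame with `person_id`,
#'   `wave_year` and `onset_*` columns).
#' @inheritParams score_person_wave
#' @inheritParams disease_duration
#' @return data frame with one row per person-wave: `person_id`,
#'   `wave_year`, a `dalys` column (total YLDs), and `yld_<disease>`
#'   columns. The duration convention used is recorded in the
#'   `"duration_convention"` attribute.
#' @export
score_panel <- function(panel, table = disease_weights(),
                        convention = c("diagnosis_year", "first_report")) {
  convention <- match.arg(convention)
  validate_weight_table(table)
  stopifnot(all(c("person_id", "wave_year") %in% names(panel)))
  onset_cols <- grep("^onset_", names(panel), value = TRUE)
  diseases <- sub("^onset_", "", onset_cols)
  unknown <- setdiff(diseases, table$disease)
  if (length(unknown))
    stop("panel carries onset columns for unknown disease(s): ",
         paste(unknown, collapse = ", "))

  n <- nrow(panel)
  wave <- panel$wave_year
  w <- stats::setNames(table$weight, table$disease)

  ylds <- matrix(0, n, length(diseases), dimnames = list(NULL, diseases))
  for (k in seq_along(diseases)) {
    d <- diseases[k]
    onset <- panel[[onset_cols[k]]]
    has <- !is.na(onset)
    bad <- has & onset > wave
    if (any(bad)) {
      i <- which(bad)[1]
      stop("onset year ", onset[i], " after wave ", wave[i], " for person ",
           panel$person_id[i], ", disease ", d)
    }
    if (convention == "diagnosis_year") {
      ref <- onset
    } else {
      # first observed wave at or after onset, per person
      ref <- rep(NA_real_, n)
      idx <- which(has)
      if (length(idx)) {
        sp <- split(idx, panel$person_id[idx])
        for (rows in sp) {
          waves_p <- sort(unique(wave[rows]))
          for (i in rows) {
            cand <- waves_p[waves_p >= onset[i]]
            ref[i] <- if (length(cand)) cand[1] else wave[i]
          }
        }
      }
    }
    ylds[has, k] <- w[d] * pmax(wave[has] - ref[has], 0)
  }

  out <- data.frame(person_id = panel$person_id, wave_year = wave,
                    dalys = rowSums(ylds), stringsAsFactors = FALSE)
  colnames(ylds) <- paste0("yld_", diseases)
  out <- cbind(out, as.data.frame(ylds))
  attr(out, "duration_convention") <- convention
  out
}
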