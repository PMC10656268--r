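# Object Space task bookkeeping: exploration totals and the
# discrimination index.

#' Discrimination index
#'
#' `DI = (t_novel - t_familiar) / (t_novel + t_familiar)`, in \[-1, 1\].
#' Positive values indicate preference for the novel object location (the
#' memory readout), 0 no preference, negative values preference for the
#' familiar location.
#'
#' @param tNovel,tFamiliar exploration times, s (non-negative).
#' @return DI, or `NA` when total exploration is zero.
#' @examples
#' discriminationIndex(30, 10)  # 0.5
#' @export
discriminationIndex <- function(tNovel, tFamiliar) {
  if (any(c(tNovel, tFamiliar) < 0)) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  tot <- tNovel + tFamiliar
  ifelse(tot > 0, (tNovel - tFamiliar) / tot, NA_real_)
}

#' Tidy session table of exploration and DI
#'
#' Builds the long-format per-trial table the group-level statistics
#' consume: DI and total exploration per trial x condition x treatment,
#' with the test trial flagged.  The "showed memory under vehicle"
#' inclusion filter (vehicle test DI > 0) is provided as a boolean column
#' per animal, never silently applied.
#'
#' @param trials data.frame with columns `animal`, `condition`
#'   (`Stable`/`Overlapping`/`HomeCage`), `treatment` (`VEH`/`CBD`),
#'   `trial` (1-5 or `"TEST"`), `t_novel_s`, `t_familiar_s`.
#' @return data.frame with added `total_exploration_s`, `di`, `is_test`,
#'   `vehicle_memory` columns.  Duplicate (animal, condition, treatment,
#'   trial) keys are an error.
#' @export
behaviorSessionTable <- function(trials) {
  key <- interaction(trials$animal, trials$condition, trials$treatment,
                     trials$trial, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate trial keys", call. = FALSE)
  out <- trials
  out$total_exploration_s <- out$t_novel_s + out$t_familiar_s
  out$di <- mapply(discriminationIndex, out$t_novel_s, out$t_familiar_s)
  out$is_test <- toupper(as.character(out$trial)) == "TEST"
  vehMem <- tapply(seq_len(nrow(out)), out$animal, function(i) {
    sel <- i[out$is_test[i] & out$treatment[i] == "VEH"]
    if (!length(sel)) return(NA)
    any(out$di[sel] > 0, na.rm = TRUE)
  })
  out$vehicle_memory <- as.logical(vehMem[as.character(out$animal)])
  out
}

#' Read a trial-score CSV
#'
#' Expects columns `animal, condition, treatment, trial, t_novel_s,
#' t_familiar_s`.
#'
#' @param path CSV path.
#' @return data.frame of trials.
#' @export
readBehaviorCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
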