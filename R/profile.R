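#' Construct a concentration-time profile
#'
#' One subject's serum concentration-time series after an IV bolus, with
#' below-limit-of-quantification (BLQ) flags and dose metadata. This is the
#' unit of analysis for [run_nca()].
#'
#' @param subject_id Character scalar identifier.
#' @param group Group label (e.g. `"control"`, `"hep70"`, `"hep90"`).
#' @param dose Administered dose, µmol.
#' @param body_weight Body weight, g (optional, `NA` allowed).
#' @param times Sampling times in minutes, strictly increasing, all `> 0`
#'   unless a time-zero value is supplied deliberately.
#' @param concentrations Serum concentrations, µmol/L, same length as
#'   `times`, all `>= 0`.
#' @param blq Logical BLQ flags, one per sample. Defaults to all `FALSE`.
#' @return An object of class `conc_time_profile`.
#' @export
conc_time_profile <- function(subject_id, group, dose, body_weight = NA_real_,
                              times, concentrations, blq = NULL) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations)) {
    stop("times and concentrations must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive", call. = FALSE)
  if (is.null(blq)) blq <- rep(FALSE, length(times))
  blq <- as.logical(blq)
  if (length(blq) != length(times) || any(is.na(blq))) {
    stop("blq must be a logical vector matching times", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 dose = dose,
                 body_weight = body_weight,
                 times = times,
                 concentrations = concentrations,
                 blq = blq),
            class = "conc_time_profile")
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf("<conc_time_profile> subject %s (%s), dose %.2f umol\n",
              x$subject_id, x$group, x$dose))
  print(data.frame(time_min = x$times, conc_umol_L = x$concentrations,
                   blq = x$blq), row.names = FALSE)
  invisible(x)
}

# Quantifiable samples only (BLQ excluded), as used by all NCA steps.
quantifiable <- function(profile) {
  keep <- !profile$blq
  list(times = profile$times[keep], conc = profile$concentrations[keep],
       n = sum(keep))
}

not_evaluable <- function(reason, subject_id = NA_character_) {
  cond <- structure(class = c("gadnca_not_evaluable", "error", "condition"),
                    list(message = reason, call = NULL,
                         subject_id = subject_id, reason = reason))
  stop(cond)
}
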