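#' Lobe names of the rat liver
#'
#' The five lobes weighed after explantation: left lateral, median, right,
#' caudate and the paracaval portion. 70% hepatectomy removes the left
#' lateral and median lobes; 90% hepatectomy additionally removes the right
#' lobe.
#'
#' @export
RAT_LIVER_LOBES <- c("left_lateral", "median", "right", "caudate", "paracaval")

#' Lobe-wise liver weight record
#'
#' @param lobe_weights Named numeric vector of wet lobe weights in g; names
#'   must cover [RAT_LIVER_LOBES].
#' @param total_weight Total explanted wet liver weight, g.
#' @param group Group label (default `"control"`).
#' @return An object of class `liver_weight_record`.
#' @details For control (whole-liver) records the dissected lobes must
#'   account for the total to within 5% (dissection loss tolerance).
#' @export
liver_weight_record <- function(lobe_weights, total_weight, group = "control") {
  missing <- setdiff(RAT_LIVER_LOBES, names(lobe_weights))
  if (length(missing)) {
    stop("missing lobe weight(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lobe_weights <- lobe_weights[RAT_LIVER_LOBES]
  if (any(lobe_weights <= 0) || total_weight <= 0) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  if (identical(group, "control") &&
      abs(sum(lobe_weights) - total_weight) / total_weight > 0.05) {
    stop("lobe weights differ from the total by more than 5%", call. = FALSE)
  }
  structure(list(lobe_weights = lobe_weights, total_weight = total_weight,
                 group = group),
            class = "liver_weight_record")
}

#' Relative lobe weights
#'
#' `relative weight (%) = 100 * lobe weight (g) / total liver weight (g)`.
#' Values are returned unrounded; round to one decimal for reporting.
#'
#' @param record A [liver_weight_record()].
#' @return Named numeric vector of percentages, one per lobe.
#' @examples
#' rec <- reference_liver_weights()$control
#' round(relative_lobe_weights(rec), 1)
#' @export
relative_lobe_weights <- function(record) {
  stopifnot(inherits(record, "liver_weight_record"))
  100 * record$lobe_weights / record$total_weight
}

#' Combined relative weight of a set of lobes
#'
#' @param record A [liver_weight_record()].
#' @param lobes Character vector of lobe names to combine.
#' @return Percentage of the total liver weight accounted for by the lobes.
#' @export
combined_relative_weight <- function(record, lobes) {
  stopifnot(inherits(record, "liver_weight_record"))
  if (!length(lobes)) stop("lobes must be non-empty", call. = FALSE)
  bad <- setdiff(lobes, names(record$lobe_weights))
  if (length(bad)) {
    stop("unknown lobe name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  100 * sum(record$lobe_weights[lobes]) / record$total_weight
}

#' Liver regeneration rate
#'
#' Percentage of a reference total liver weight recovered by the remnant:
#' `100 * remnant / reference`. The reference is typically the control-group
#' mean total liver weight, since no per-animal preoperative liver weight is
#' available in a terminal design — an approximation, documented as such.
#'
#' @param remnant_weight Explanted remnant liver weight, g.
#' @param reference_total_weight Reference (pre-resection) total weight, g.
#' @return Regeneration rate in %.
#' @export
regeneration_rate <- function(remnant_weight, reference_total_weight) {
  if (any(c(remnant_weight, reference_total_weight) <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  100 * remnant_weight / reference_total_weight
}

#' Reference liver weights for the emulated hepatectomy design
#'
#' Group-mean explanted liver weights used as simulation defaults and in the
#' worked examples: the control record carries the mean lobe-wise dissection
#' of the intact Sprague-Dawley liver (total 12.87 g), and the remnant
#' entries are the mean remnant weights two days after 70% and 90%
#' hepatectomy (8.49 g and 4.82 g).
#'
#' @return A list with elements `control` (a [liver_weight_record()]),
#'   `remnant_70_g` and `remnant_90_g`.
#' @export
reference_liver_weights <- function() {
  list(control = liver_weight_record(
         c(left_lateral = 3.98, median = 4.26, right = 2.23,
           caudate = 0.82, paracaval = 1.42),
         total_weight = 12.87, group = "control"),
       remnant_70_g = 8.49,
       remnant_90_g = 4.82)
}

#' Read / write liver weight records as CSV
#'
#' One row per animal: one column per lobe, plus `total_weight` and `group`.
#'
#' @param path CSV path.
#' @return `read_liver_weights()` returns a list of
#'   [liver_weight_record()] objects.
#' @export
read_liver_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(RAT_LIVER_LOBES, "total_weight", "group")
  if (!all(need %in% names(df))) {
    stop("liver weight CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    liver_weight_record(unlist(df[i, RAT_LIVER_LOBES]),
                        df$total_weight[i], df$group[i])
  })
}

#' @param records List of [liver_weight_record()] objects.
#' @rdname read_liver_weights
#' @export
write_liver_weights <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    cbind(as.data.frame(as.list(r$lobe_weights)),
          data.frame(total_weight = r$total_weight, group = r$group))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
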