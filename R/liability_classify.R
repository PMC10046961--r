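#' Drug-level call from four dose results
#'
#' Collapses the four per-concentration results of one drug in one culture
#' into a single call: the direction at the lowest significant concentration
#' (or `none` when no dose is significant), the fold of that concentration
#' over the drug's free Cmax (upper bound of the range; absent when no human
#' Cmax is available), the activity label (`neuronally_active` when any dose
#' is significant) and the seizure flag (a significant increase in peak
#' number).
#'
#' @param dose_results A 4-row data.frame for one drug/culture with columns
#'   `concentration`, `significant`, `direction` (see [summarize_dose()]).
#' @param record One row of [load_drug_panel()] for the drug.
#' @return A one-row data.frame: `drug`, `direction`,
#'   `lowest_significant_concentration`, `call_concentration`,
#'   `fold_over_cmax`, `activity`, `seizure_flag`.
#' @export
call_drug <- function(dose_results, record) {
  if (nrow(dose_results) != 4L)
    stop("expected 4 dose results for ", record$name[1], ", got ",
         nrow(dose_results))
  d <- dose_results[order(dose_results$concentration), , drop = FALSE]
  sig <- which(d$significant)
  if (length(sig)) {
    i <- sig[1]
    direction <- d$direction[i]
    conc <- d$concentration[i]
    lowest <- conc
  } else {
    direction <- "none"
    conc <- max(d$concentration)  # reported at the top tested dose
    lowest <- NA_real_
  }
  data.frame(
    drug = record$name[1],
    direction = direction,
    lowest_significant_concentration = lowest,
    call_concentration = conc,
    fold_over_cmax = fold_cmax(conc, record),
    activity = if (direction == "none") "non_active" else "neuronally_active",
    seizure_flag = direction == "up"
  )
}

#' Fold of a concentration over free Cmax
#'
#' Ratio of a tested concentration to the drug's free maximal therapeutic
#' plasma concentration (fCmax). The upper bound of the Cmax range is used
#' (the conservative fold); drugs without a human Cmax return `NA` and any
#' fold-threshold binning is skipped for them.
#'
#' @param concentration Concentration in uM (> 0).
#' @param record One row of [load_drug_panel()].
#' @param bound Which end of the Cmax range to use, `"high"` (default) or
#'   `"low"`.
#' @return Numeric fold, or `NA` when Cmax is absent.
#' @examples
#' panel <- load_drug_panel()
#' fold_cmax(30, subset(panel, name == "Acetaminophen"))  # ~65
#' @export
fold_cmax <- function(concentration, record, bound = c("high", "low")) {
  bound <- match.arg(bound)
  if (is.na(concentration) || concentration <= 0)
    stop("concentration must be positive")
  cmax <- if (bound == "high") record$free_cmax_high[1]
          else record$free_cmax_low[1]
  if (is.na(cmax)) return(NA_real_)
  concentration / cmax
}

#' Confusion matrix over a drug panel
#'
#' Scores drug-level calls against the clinical activity labels: a true
#' positive is a clinically neuronally active drug with a significant change
#' in peak number in either direction; a false negative is an active drug
#' with no significant change; true negatives and false positives are the
#' corresponding outcomes among the clinical negatives.
#'
#' @param calls A data.frame with columns `drug` and `direction`, one row
#'   per panel drug (e.g. from [call_drug()] or [load_significance_calls()]).
#' @param panel The drug panel from [load_drug_panel()].
#' @return A list of class `calosc_confusion`: `tp`, `tn`, `fp`, `fn`,
#'   `n_active_expected`, `n_negative_expected`.
#' @export
build_confusion <- function(calls, panel) {
  drugs <- panel[panel$clinical_class != "vehicle", , drop = FALSE]
  if (!setequal(calls$drug, drugs$name) || nrow(calls) != nrow(drugs))
    stop("calls do not match the panel: one call per panel drug required")
  idx <- match(calls$drug, drugs$name)
  active <- drugs$clinical_class[idx] == "neuronally_active"
  hit <- calls$direction != "none"
  cm <- list(
    tp = sum(active & hit),
    fn = sum(active & !hit),
    fp = sum(!active & hit),
    tn = sum(!active & !hit),
    n_active_expected = sum(active),
    n_negative_expected = sum(!active)
  )
  structure(cm, class = "calosc_confusion")
}

#' @export
print.calosc_confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d  FP %d  TN %d (%d active, %d negative expected)\n",
              x$tp, x$fn, x$fp, x$tn, x$n_active_expected,
              x$n_negative_expected))
  invisible(x)
}

#' Predictivity metrics from a confusion matrix
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, positive and
#' negative predictive values `100*TP/(TP+FP)` and `100*TN/(TN+FN)`, and the
#' overall predictivity `100*(TP+TN)/n_active_expected`. The predictivity
#' denominator (the number of expected-active drugs, not the full panel) is
#' a reverse-engineered convention: it is the only candidate among
#' {panel size, expected actives, TP+TN+FP+FN} that reproduces both printed
#' panel-level predictivity values (91% in 2D and 45% in 3D) after rounding;
#' see the methods vignette. Ratios with zero denominators are `NA`.
#'
#' @param cm A [build_confusion()] object.
#' @return A list of class `calosc_predictivity`: `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `predictivity` (all percent), plus the
#'   confusion counts.
#' @export
predictivity_metrics <- function(cm) {
  stopifnot(inherits(cm, "calosc_confusion"))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    predictivity = ratio(cm$tp + cm$tn, cm$n_active_expected),
    confusion = cm
  ), class = "calosc_predictivity")
}

#' @export
print.calosc_predictivity <- function(x, ...) {
  print(x$confusion)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s  predictivity %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              fmt(x$predictivity)))
  invisible(x)
}

#' Replay the packaged drug-level calls
#'
#' Recomputes the panel-level predictivity metrics from the packaged
#' reference tables alone (no raw fluorescence needed): the per-drug
#' significance calls for the chosen culture are scored against the clinical
#' labels and summarized.
#'
#' @param culture `"2D"` or `"3D"`.
#' @return A list with `calls` (per-drug table), `confusion` and `metrics`.
#' @examples
#' replay_table2("2D")$metrics
#' @export
replay_table2 <- function(culture = c("2D", "3D")) {
  culture <- match.arg(culture)
  panel <- load_drug_panel()
  calls <- load_significance_calls()
  calls <- calls[calls$culture == culture, , drop = FALSE]
  drugs <- panel[panel$clinical_class != "vehicle", , drop = FALSE]
  idx <- match(calls$drug, drugs$name)
  calls$fold_over_cmax <- ifelse(is.na(drugs$free_cmax_high[idx]), NA_real_,
                                 calls$call_concentration /
                                   drugs$free_cmax_high[idx])
  calls$activity <- ifelse(calls$direction == "none", "non_active",
                           "neuronally_active")
  calls$seizure_flag <- calls$direction == "up"
  cm <- build_confusion(calls, panel)
  list(calls = calls, confusion = cm, metrics = predictivity_metrics(cm))
}
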