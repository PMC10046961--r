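#' Packaged reference-drug panel
#'
#' Loads the 25-drug reference panel (plus the DMSO vehicle entry): CAS
#' number, free therapeutic Cmax (as a low/high range in uM; `NA` when no
#' human plasma value is available, as for bicuculline, dizocilpine and
#' kainic acid), the four tested concentrations (a 3x dilution series), the
#' clinical activity label and the pharmacological class. The three
#' clinical negatives are aspirin, amoxicillin and acetaminophen; the other
#' 22 drugs are neuronally active.
#'
#' @param path Optional path to an alternative delimiter-separated panel
#'   file with the same columns; defaults to the packaged fixture.
#' @return A data.frame with one row per drug plus one `vehicle` row, columns
#'   `name`, `cas`, `free_cmax_low`, `free_cmax_high`, `conc_1` .. `conc_4`,
#'   `clinical_class`, `class_note`.
#' @examples
#' panel <- load_drug_panel()
#' subset(panel, name == "Acetaminophen")
#' @export
load_drug_panel <- function(path = NULL) {
  path <- fixture_path(path, "table1_drugs.tsv")
  panel <- read_fixture(path)
  need <- c("name", "cas", "free_cmax_low", "free_cmax_high",
            paste0("conc_", 1:4), "clinical_class", "class_note")
  check_columns(panel, need, path)
  drugs <- panel[panel$clinical_class != "vehicle", , drop = FALSE]
  if (nrow(drugs) != 25L)
    stop("corrupt drug panel in ", basename(path), ": expected 25 drugs, got ",
         nrow(drugs))
  if (sum(panel$clinical_class == "vehicle") != 1L)
    stop("corrupt drug panel in ", basename(path), ": expected 1 vehicle row")
  if (!all(drugs$clinical_class %in% c("negative_control", "neuronally_active")))
    stop("corrupt drug panel in ", basename(path), ": bad clinical_class")
  conc <- as.matrix(drugs[, paste0("conc_", 1:4)])
  if (any(apply(conc, 1, function(z) any(diff(z) <= 0))))
    stop("corrupt drug panel in ", basename(path),
         ": tested concentrations not strictly increasing")
  both <- !is.na(drugs$free_cmax_low) & !is.na(drugs$free_cmax_high)
  if (any(drugs$free_cmax_low[both] > drugs$free_cmax_high[both]))
    stop("corrupt drug panel in ", basename(path), ": cmax low > high")
  panel
}

#' Packaged per-drug significance calls
#'
#' Loads the drug-level outcome table for both culture formats: for each of
#' the 25 drugs and each culture (2D monolayer, 3D spheroid), the direction
#' of the significant peak-number change (`up`, `down`, or `none` when no
#' concentration reached significance) and the concentration at which the
#' call is reported.
#'
#' @param path Optional path to an alternative file; defaults to the
#'   packaged fixture.
#' @return A data.frame with 50 rows and columns `drug`, `culture`,
#'   `direction`, `call_concentration`.
#' @examples
#' calls <- load_significance_calls()
#' subset(calls, drug == "Kainic Acid")
#' @export
load_significance_calls <- function(path = NULL) {
  path <- fixture_path(path, "table2_calls.tsv")
  calls <- read_fixture(path)
  check_columns(calls, c("drug", "culture", "direction", "call_concentration"),
                path)
  if (nrow(calls) != 50L)
    stop("corrupt call table in ", basename(path), ": expected 50 rows, got ",
         nrow(calls))
  bad <- !calls$direction %in% c("up", "down", "none") |
    !calls$culture %in% c("2D", "3D") | is.na(calls$call_concentration)
  if (any(bad))
    stop("unparseable call in ", basename(path), " for ",
         calls$drug[which(bad)[1]], " (", calls$culture[which(bad)[1]], ")")
  tab <- table(calls$drug, calls$culture)
  if (!all(tab == 1L))
    stop("corrupt call table in ", basename(path),
         ": each drug needs exactly one 2D and one 3D call")
  calls
}

#' Packaged per-dose peak-number summaries
#'
#' Loads the dose-by-dose summary of the percent change in peak number from
#' baseline: 25 drugs x 2 cultures x 4 increasing concentrations, each with
#' the mean and standard deviation of the per-well percent change and the
#' printed significance level versus same-plate vehicle (`ns`, `p<0.05`,
#' `p<0.01`). A mean of -100 means complete cessation of oscillations.
#'
#' @param path Optional path to an alternative file; defaults to the
#'   packaged fixture.
#' @return A data.frame with 200 rows and columns `drug`, `culture`,
#'   `dose_index`, `concentration`, `mean_delta_pct`, `sd_delta_pct`,
#'   `significance`.
#' @examples
#' doses <- load_dose_summaries()
#' subset(doses, drug == "4-Aminopyridine" & culture == "2D")
#' @export
load_dose_summaries <- function(path = NULL) {
  path <- fixture_path(path, "table3_deltas.tsv")
  doses <- read_fixture(path)
  check_columns(doses, c("drug", "culture", "dose_index", "concentration",
                         "mean_delta_pct", "sd_delta_pct", "significance"),
                path)
  if (nrow(doses) != 200L)
    stop("corrupt dose table in ", basename(path), ": expected 200 rows, got ",
         nrow(doses))
  if (!all(doses$significance %in% c("ns", "p<0.05", "p<0.01")))
    stop("corrupt dose table in ", basename(path), ": bad significance code")
  if (any(doses$mean_delta_pct < -100))
    stop("corrupt dose table in ", basename(path),
         ": mean below the -100% cessation floor")
  if (any(doses$sd_delta_pct < 0))
    stop("corrupt dose table in ", basename(path), ": negative SD")
  tab <- table(doses$drug, doses$culture)
  if (!all(tab == 4L))
    stop("corrupt dose table in ", basename(path),
         ": each drug/culture needs 4 doses")
  doses
}

#' Cross-table consistency report
#'
#' Compares the drug-level calls against the per-dose summaries: for each
#' drug and culture, the drug-level direction should equal the sign of the
#' mean at the lowest significant concentration (or `none` when no dose is
#' significant). The two packaged tables are stored verbatim and disagree in
#' a handful of cells (for example significant single-dose changes in
#' negative controls that the drug-level table reports as no change), so
#' mismatches are reported, never asserted away.
#'
#' @return A data.frame with one row per mismatch: `drug`, `culture`,
#'   `call_direction` (drug-level table), `dose_direction` (derived from the
#'   per-dose table). Zero rows means full agreement.
#' @examples
#' reference_consistency_report()
#' @export
reference_consistency_report <- function() {
  calls <- load_significance_calls()
  doses <- load_dose_summaries()
  out <- list()
  for (i in seq_len(nrow(calls))) {
    d <- doses[doses$drug == calls$drug[i] & doses$culture == calls$culture[i], ]
    d <- d[order(d$concentration), ]
    sig <- d$significance != "ns"
    dose_dir <- if (!any(sig)) "none" else {
      m <- d$mean_delta_pct[which(sig)[1]]
      if (m > 0) "up" else if (m < 0) "down" else "none"
    }
    if (dose_dir != calls$direction[i]) {
      out[[length(out) + 1L]] <- data.frame(
        drug = calls$drug[i], culture = calls$culture[i],
        call_direction = calls$direction[i], dose_direction = dose_dir,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    data.frame(drug = character(), culture = character(),
               call_direction = character(), dose_direction = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

fixture_path <- function(path, default) {
  if (!is.null(path)) {
    if (!file.exists(path)) stop("fixture file not found: ", path)
    return(path)
  }
  p <- system.file("extdata", default, package = "calosc")
  if (!nzchar(p) || !file.exists(p))
    stop("packaged fixture missing: ", default)
  p
}

read_fixture <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse fixture ", basename(path), ": ",
                             conditionMessage(e)))
  out
}

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fixture ", basename(path), " is missing columns: ",
         paste(miss, collapse = ", "))
  invisible(df)
}
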