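#' Projected leaf area from chamber geometry
#'
#' Leaves of narrow-leaved grasses are inserted across the chamber; the
#' projected area is the mean of the combined leaf widths measured at the
#' two chamber edges times the chamber length along the leaves.
#'
#' @param widths_edge1,widths_edge2 Combined widths of the inserted
#'   leaves at each chamber edge, mm.
#' @param chamber_length Chamber dimension spanned by the leaves, mm
#'   (default 30, the long axis of a 30 mm x 20 mm chamber).
#' @return Projected leaf area, mm2.
#' @examples
#' leaf_area(3, 5) # 120 mm2
#' @export
leaf_area <- function(widths_edge1, widths_edge2, chamber_length = 30) {
  if (any(chamber_length <= 0)) abort("`chamber_length` must be > 0.")
  if (any(widths_edge1 < 0) || any(widths_edge2 < 0)) {
    abort("edge widths must be >= 0.")
  }
  if (any(widths_edge1 == 0 & widths_edge2 == 0)) {
    abort("both edge widths are zero: no leaf in the chamber.")
  }
  (widths_edge1 + widths_edge2) / 2 * chamber_length
}

#' Default gas-exchange acceptance thresholds
#'
#' The measurement-acceptance rules: resolvable CO2 and H2O differentials
#' between reference and chamber air streams, a minimum projected leaf
#' area, a minimum flow rate, a stabilization time limit for ci, and a
#' per-month policy for tightly rolled leaves (rolled leaves were
#' unrolled only in the first campaign month; that month's rolled records
#' are excluded from later-season comparisons).
#'
#' @param min_delta_co2 Minimum CO2 differential, umol mol-1 (records at
#'   or below are rejected).
#' @param min_delta_h2o Minimum H2O differential, mmol mol-1.
#' @param min_area Minimum projected leaf area, mm2.
#' @param min_flow Minimum chamber flow rate, umol s-1.
#' @param max_stabilization_s Longest acceptable ci stabilization time, s.
#' @param chamber_length Chamber length used for leaf area, mm.
#' @param rolled_excluded_months Months in which `leaf_rolled = TRUE`
#'   records are rejected.
#' @return A named list of thresholds for [qc_filter()].
#' @export
qc_thresholds <- function(min_delta_co2 = 10, min_delta_h2o = 1,
                          min_area = 100, min_flow = 100,
                          max_stabilization_s = 180,
                          chamber_length = 30,
                          rolled_excluded_months = "Nov") {
  list(
    min_delta_co2 = min_delta_co2,
    min_delta_h2o = min_delta_h2o,
    min_area = min_area,
    min_flow = min_flow,
    max_stabilization_s = max_stabilization_s,
    chamber_length = chamber_length,
    rolled_excluded_months = rolled_excluded_months
  )
}

#' Screen gas-exchange records against the acceptance rules
#'
#' Pure rule-based screening of chamber measurements. Each rule is
#' evaluated independently; a record is kept if and only if no rule
#' fails, and every failed rule contributes its own reason code
#' (`DELTA_CO2`, `DELTA_H2O`, `AREA`, `FLOW`, `STABILIZATION`, `ROLLED`).
#'
#' @param records Data frame with columns `delta_co2` (umol mol-1),
#'   `delta_h2o` (mmol mol-1), `flow` (umol s-1), `widths_edge1`,
#'   `widths_edge2` (mm), `stabilization_s` (s), `leaf_rolled` (logical)
#'   and `month`. Extra columns are carried through.
#' @param thresholds A threshold list from [qc_thresholds()].
#' @return The records as a tibble with appended columns `leaf_area`
#'   (mm2), `keep` (logical) and `qc_reasons` (comma-separated failed
#'   rule codes, `""` when kept).
#' @examples
#' rec <- tibble::tibble(delta_co2 = c(12, 9), delta_h2o = 1.2, flow = 150,
#'                       widths_edge1 = 4, widths_edge2 = 4,
#'                       stabilization_s = 90, leaf_rolled = FALSE,
#'                       month = "Jan")
#' qc_filter(rec)
#' @export
qc_filter <- function(records, thresholds = qc_thresholds()) {
  records <- as_tibble(records)
  th <- thresholds
  area <- leaf_area(records$widths_edge1, records$widths_edge2,
                    th$chamber_length)
  fails <- list(
    DELTA_CO2 = records$delta_co2 <= th$min_delta_co2,
    DELTA_H2O = records$delta_h2o <= th$min_delta_h2o,
    AREA = area < th$min_area,
    FLOW = records$flow < th$min_flow,
    STABILIZATION = records$stabilization_s > th$max_stabilization_s,
    ROLLED = records$leaf_rolled & records$month %in% th$rolled_excluded_months
  )
  reason_mat <- do.call(cbind, fails)
  reasons <- apply(reason_mat, 1, function(r) {
    paste(names(fails)[r], collapse = ",")
  })
  records$leaf_area <- area
  records$keep <- reasons == ""
  records$qc_reasons <- reasons
  records
}

#' Summarise QC outcomes by rule
#'
#' @param screened Output of [qc_filter()].
#' @return A tibble of counts: one row per reason code plus totals of
#'   kept and rejected records.
#' @export
qc_summary <- function(screened) {
  codes <- c("DELTA_CO2", "DELTA_H2O", "AREA", "FLOW", "STABILIZATION", "ROLLED")
  counts <- purrr::map_int(codes, function(code) {
    sum(grepl(code, screened$qc_reasons, fixed = TRUE))
  })
  bind_rows(
    tibble(rule = codes, n = counts),
    tibble(rule = c("kept", "rejected"),
           n = c(sum(screened$keep), sum(!screened$keep)))
  )
}

#' Intrinsic and instantaneous water-use efficiency
#'
#' Adds the two water-use-efficiency ratios to a table of assimilation,
#' stomatal conductance and transpiration: intrinsic WUE `A/gs`
#' (umol CO2 per mol H2O of stomatal conductance) and instantaneous WUE
#' `A/E` (umol CO2 per mmol H2O transpired, i.e. mmol mol-1). A record
#' with a non-positive denominator gets `NA` for that ratio (excluded
#' from that variable downstream); `A = 0` gives zero for both.
#'
#' @param data Data frame with columns `A` (umol m-2 s-1), `gs`
#'   (mol m-2 s-1) and `E` (mmol m-2 s-1).
#' @return The input as a tibble with `A_over_gs` (umol mol-1) and
#'   `A_over_E` (mmol mol-1) appended.
#' @examples
#' derive_wue(tibble::tibble(A = 10, gs = 0.1, E = 2))
#' @export
derive_wue <- function(data) {
  data <- as_tibble(data)
  data |>
    mutate(
      A_over_gs = case_when(
        .data$A == 0 ~ 0,
        .data$gs > 0 ~ .data$A / .data$gs,
        TRUE ~ NA_real_
      ),
      A_over_E = case_when(
        .data$A == 0 ~ 0,
        .data$E > 0 ~ .data$A / .data$E,
        TRUE ~ NA_real_
      )
    )
}
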