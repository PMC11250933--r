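#' @title ICD-9 comparator flag
#' @name comparators
#' @description
#' Billing-code ARDS surrogate used as a comparator for the rule-based
#' detector: respiratory-failure diagnosis codes in any position, an
#' optional mechanical-ventilation procedure-code requirement, and an
#' optional exclusion of admissions whose primary diagnosis is an ischemic
#' heart disease / heart failure category. Codes are stored dot-stripped and
#' matched by string prefix, mirroring common ICD grouping practice.
NULL

#' ICD-9 rule configuration
#'
#' @param resp_failure_codes Respiratory-failure codes (dotted or not);
#'   default 518.51, 518.52, 518.81, 518.82.
#' @param vent_procedure_codes Mechanical-ventilation procedure codes;
#'   default 96.70, 96.71, 96.72.
#' @param hf_exclusion_codes Heart-disease category codes excluded as
#'   primary diagnosis; default 410, 411, 412, 414, 428.
#' @param require_vent_code Require a ventilation procedure code (default
#'   `FALSE`, the configuration with the highest comparator accuracy).
#' @param apply_hf_exclusion Exclude primary-heart-disease admissions
#'   (default `TRUE`).
#' @return Object of class `icd_rule_config`.
#' @export
icd_rule_config <- function(resp_failure_codes = c("518.51", "518.52",
                                                   "518.81", "518.82"),
                            vent_procedure_codes = c("96.70", "96.71", "96.72"),
                            hf_exclusion_codes = c("410", "411", "412", "414",
                                                   "428"),
                            require_vent_code = FALSE,
                            apply_hf_exclusion = TRUE) {
  strip <- function(x) gsub(".", "", x, fixed = TRUE)
  if (length(resp_failure_codes) == 0L) {
    stop("resp_failure_codes must be non-empty", call. = FALSE)
  }
  if (isTRUE(require_vent_code) && length(vent_procedure_codes) == 0L) {
    stop("vent_procedure_codes must be non-empty when require_vent_code is on",
         call. = FALSE)
  }
  if (isTRUE(apply_hf_exclusion) && length(hf_exclusion_codes) == 0L) {
    stop("hf_exclusion_codes must be non-empty when apply_hf_exclusion is on",
         call. = FALSE)
  }
  structure(list(resp_failure_codes = strip(resp_failure_codes),
                 vent_procedure_codes = strip(vent_procedure_codes),
                 hf_exclusion_codes = strip(hf_exclusion_codes),
                 require_vent_code = isTRUE(require_vent_code),
                 apply_hf_exclusion = isTRUE(apply_hf_exclusion)),
            class = "icd_rule_config")
}

prefix_match_any <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) return(FALSE)
  any(vapply(codes, function(cd) any(startsWith(cd, prefixes)), logical(1)))
}

#' ICD-9-based ARDS flag for one admission
#'
#' `TRUE` iff a respiratory-failure code is present in any diagnosis
#' position, AND (when required) a ventilation procedure code is present,
#' AND (when the exclusion is on) the primary diagnosis does not
#' prefix-match a heart-disease category code.
#'
#' @param admission An `admission_record`.
#' @param rule An [icd_rule_config()].
#' @return Logical scalar.
#' @export
icd9_ards_flag <- function(admission, rule = icd_rule_config()) {
  codes <- admission$icd_codes$code
  if (!prefix_match_any(codes, rule$resp_failure_codes)) return(FALSE)
  if (rule$require_vent_code &&
      !prefix_match_any(codes, rule$vent_procedure_codes)) return(FALSE)
  if (rule$apply_hf_exclusion) {
    primary <- codes[admission$icd_codes$is_primary]
    if (prefix_match_any(primary, rule$hf_exclusion_codes)) return(FALSE)
  }
  TRUE
}
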