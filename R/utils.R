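#' Round half away from zero
#'
#' Commercial ("half-up") rounding, unlike [base::round()]'s round-half-even.
#' Used for every displayed prescribing ratio, normalized rate and ranked
#' risk so that derived tables reproduce hand calculation.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)      # 1, where round(0.5) is 0
#' round_half_up(5.501)    # 6
#' round_half_up(0.86036, 4)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are conceptually x.5 but stored
  # as x.49999999... (e.g. ratios of integers) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang .data
NULL

# Valid code sets shared across modules
.aersrank <- new.env(parent = emptyenv())
.aersrank$roles <- c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT", "CONCOMITANT", "INTERACTING")
.aersrank$outcomes <- c("DEATH", "LIFE_THREATENING", "HOSPITALIZATION", "DISABILITY",
                        "CONGENITAL_ANOMALY", "REQUIRED_INTERVENTION", "OTHER")
.aersrank$occupations <- c("PHYSICIAN", "PHARMACIST", "OTHER_HEALTH_PROFESSIONAL",
                           "CONSUMER", "LAWYER", "UNKNOWN")

aers_roles <- function() .aersrank$roles
aers_outcomes <- function() .aersrank$outcomes
aers_occupations <- function() .aersrank$occupations

# AERS single-letter role codes as used in the legacy DRUG files
role_from_code <- function(code) {
  map <- c(PS = "PRIMARY_SUSPECT", SS = "SECONDARY_SUSPECT",
           C = "CONCOMITANT", I = "INTERACTING")
  out <- unname(map[toupper(trimws(code))])
  out[is.na(out)] <- "CONCOMITANT"
  out
}

outcome_from_code <- function(code) {
  map <- c(DE = "DEATH", LT = "LIFE_THREATENING", HO = "HOSPITALIZATION",
           DS = "DISABILITY", CA = "CONGENITAL_ANOMALY",
           RI = "REQUIRED_INTERVENTION", OT = "OTHER")
  out <- unname(map[toupper(trimws(code))])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("%d unknown outcome code(s) mapped to OTHER: %s",
                    sum(unknown),
                    paste(unique(code[unknown]), collapse = ", ")),
            call. = FALSE)
    out[unknown] <- "OTHER"
  }
  out
}

occupation_from_code <- function(code) {
  map <- c(MD = "PHYSICIAN", PH = "PHARMACIST", OT = "OTHER_HEALTH_PROFESSIONAL",
           CN = "CONSUMER", LW = "LAWYER")
  code <- toupper(trimws(code))
  out <- unname(map[code])
  unknown <- is.na(out) & !is.na(code) & code != ""
  if (any(unknown)) {
    warning(sprintf("%d unknown occupation code(s) mapped to UNKNOWN: %s",
                    sum(unknown),
                    paste(unique(code[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  out[is.na(out)] <- "UNKNOWN"
  out
}
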