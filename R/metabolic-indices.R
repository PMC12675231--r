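# Derived metabolic indices and four-group metabolic obesity phenotyping.

#' Homeostatic Model Assessment of Insulin Resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (uU/mL) x glucose (mmol/L) / 22.5`.
#'
#' @param glucose Fasting glucose in mmol/L. Vectorised.
#' @param insulin Fasting insulin in uU/mL. Vectorised.
#' @return Numeric vector of HOMA-IR values (unitless, > 0).
#' @examples
#' homa_ir(glucose = 5.1, insulin = 13.18)
#' @export
homa_ir <- function(glucose, insulin) {
  .check_positive(glucose, "glucose")
  .check_positive(insulin, "insulin")
  insulin * glucose / 22.5
}

#' Hepatic Steatosis Index (HSI)
#'
#' `HSI = 8 * ALT/AST + BMI + 2 * [female] + 2 * [diabetes]`. Values at or
#' above 36 flag elevated NAFLD risk.
#'
#' @param alt ALT in U/L.
#' @param ast AST in U/L (must be > 0).
#' @param bmi Body-mass index in kg/m^2.
#' @param sex Character vector, `"female"` or `"male"`.
#' @param diabetes Logical; defaults to `FALSE` (non-diabetic cohort).
#' @return Numeric vector of HSI values; always exceeds `bmi`.
#' @export
hsi <- function(alt, ast, bmi, sex, diabetes = FALSE) {
  .check_positive(alt, "alt")
  .check_positive(ast, "ast")
  .check_positive(bmi, "bmi")
  sex <- .check_sex(sex)
  8 * alt / ast + bmi + 2 * (sex == "female") + 2 * as.numeric(diabetes)
}

#' Visceral Adiposity Index (VAI)
#'
#' Sex-specific composite of waist circumference, BMI, triglycerides and
#' HDL cholesterol:
#' males `(WC / (39.68 + 1.88 BMI)) * (TG / 1.03) * (1.31 / HDL)`,
#' females `(WC / (36.58 + 1.89 BMI)) * (TG / 0.81) * (1.52 / HDL)`.
#' A metabolically reference individual scores 1. Homogeneous of degree 1
#' in TG and degree -1 in HDL.
#'
#' @param wc Waist circumference in cm.
#' @param bmi Body-mass index in kg/m^2.
#' @param tg Triglycerides in mmol/L.
#' @param hdl HDL cholesterol in mmol/L.
#' @param sex `"female"` or `"male"`.
#' @return Numeric vector of VAI values (> 0).
#' @export
vai <- function(wc, bmi, tg, hdl, sex) {
  .check_positive(wc, "wc"); .check_positive(bmi, "bmi")
  .check_positive(tg, "tg"); .check_positive(hdl, "hdl")
  sex <- .check_sex(sex)
  ifelse(sex == "male",
         (wc / (39.68 + 1.88 * bmi)) * (tg / 1.03) * (1.31 / hdl),
         (wc / (36.58 + 1.89 * bmi)) * (tg / 0.81) * (1.52 / hdl))
}

#' Atherogenic index
#'
#' Computed as `(TC - HDL) / HDL`, i.e. non-HDL cholesterol relative to HDL.
#'
#' @param tc Total cholesterol in mmol/L.
#' @param hdl HDL cholesterol in mmol/L (> 0).
#' @return Numeric vector; 0 when TC equals HDL.
#' @export
atherogenic_index <- function(tc, hdl) {
  .check_positive(hdl, "hdl")
  if (any(!is.finite(tc))) stop("`tc` must be finite", call. = FALSE)
  (tc - hdl) / hdl
}

#' Classify metabolic obesity phenotype
#'
#' Assigns one of MHNW, MUNW, MUOW, MUO from BMI, HOMA-IR and HSI.
#' "Metabolically unhealthy" means HOMA-IR >= 2.5 or HSI >= 36, independent
#' of BMI. BMI classes: normal weight 18.5-24.9, overweight 25-29.9,
#' obese >= 30. Metabolically healthy overweight or obese participants do
#' not belong to any of the four study phenotypes and are labelled
#' `"unclassified"`; four-group analyses exclude them.
#'
#' @param bmi Body-mass index in kg/m^2 (>= 18.5, the eligibility bound).
#' @param homa HOMA-IR values, e.g. from [homa_ir()].
#' @param hsi_value HSI values, e.g. from [hsi()].
#' @param homa_cut,hsi_cut Metabolic-health cutoffs (defaults 2.5 and 36).
#' @return Factor with levels `MHNW, MUNW, MUOW, MUO, unclassified`.
#' @examples
#' classify_phenotype(bmi = c(22, 22, 32), homa = c(1.2, 3.5, 3.5),
#'                    hsi_value = c(30, 30, 44))
#' @export
classify_phenotype <- function(bmi, homa, hsi_value,
                               homa_cut = 2.5, hsi_cut = 36) {
  if (any(bmi < 18.5)) {
    stop("BMI below 18.5 kg/m^2 is outside study eligibility", call. = FALSE)
  }
  unhealthy <- homa >= homa_cut | hsi_value >= hsi_cut
  lab <- ifelse(bmi < 25,
                ifelse(unhealthy, "MUNW", "MHNW"),
                ifelse(!unhealthy, "unclassified",
                       ifelse(bmi < 30, "MUOW", "MUO")))
  factor(lab, levels = phenotype_levels(include_unclassified = TRUE))
}

#' Phenotype factor levels
#'
#' @param include_unclassified Append the `"unclassified"` level used for
#'   metabolically healthy overweight/obese participants.
#' @return Character vector of level names in severity order.
#' @export
phenotype_levels <- function(include_unclassified = FALSE) {
  lv <- c("MHNW", "MUNW", "MUOW", "MUO")
  if (include_unclassified) c(lv, "unclassified") else lv
}

#' Append derived indices and phenotype to a cohort table
#'
#' Column-wise convenience wrapper: computes HOMA-IR, HSI, VAI and the
#' atherogenic index from the canonical cohort columns and appends them,
#' together with the classified phenotype, as `homa_ir`, `hsi`, `vai`,
#' `atherogenic_index` and `phenotype_classified`.
#'
#' @param cohort Data frame with columns `glucose`, `insulin`, `alt`,
#'   `ast`, `bmi`, `wc`, `tg`, `hdl`, `tc`, `sex`.
#' @return The cohort with five appended columns.
#' @export
add_metabolic_indices <- function(cohort) {
  need <- c("glucose", "insulin", "alt", "ast", "bmi", "wc", "tg", "hdl",
            "tc", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cohort$homa_ir <- homa_ir(cohort$glucose, cohort$insulin)
  cohort$hsi <- hsi(cohort$alt, cohort$ast, cohort$bmi, cohort$sex)
  cohort$vai <- vai(cohort$wc, cohort$bmi, cohort$tg, cohort$hdl, cohort$sex)
  cohort$atherogenic_index <- atherogenic_index(cohort$tc, cohort$hdl)
  cohort$phenotype_classified <-
    classify_phenotype(cohort$bmi, cohort$homa_ir, cohort$hsi)
  cohort
}

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

.check_sex <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male"))) {
    stop('`sex` must be "female" or "male"', call. = FALSE)
  }
  sex
}
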