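# Clinical group classification along the AD continuum, driven by the
# subjective-complaint question, MoCA, CDR and the education-stratified
# Logical Memory (LM) cutoffs, evaluated CDR-first. The same rules are
# inverted by the covariate generator so synthetic records round-trip to
# their generating group.

COMPLAINTS <- c("none", "yes_no_worry", "yes_worry")
GROUPS <- c("CH", "SCD", "eMCI", "lMCI", "AD")

# education-stratified LM cutoffs: impaired upper bound, borderline range,
# and the "intact" threshold used by the SCD/CH rows
lm_cuts <- function(education_years) {
  if (education_years < 0) stop("education_years must be >= 0")
  if (education_years >= 16) list(imp = 8L, bord = c(9L, 11L), intact = 9L)
  else if (education_years >= 8) list(imp = 4L, bord = c(5L, 9L), intact = 5L)
  else list(imp = 2L, bord = c(3L, 6L), intact = 3L)
}

#' Education-stratified Logical Memory band
#'
#' Maps an LM story-recall score to the impaired band (AD/lMCI rows), the
#' borderline band (eMCI row) or the normal band, using cutoffs that
#' depend on years of education (>=16, 8-15, 0-7). The borderline and
#' normal criteria overlap by construction; the band function gives the
#' borderline range precedence and the classifier resolves the overlap
#' through CDR.
#'
#' @param education_years completed years of education (>= 0).
#' @param lm_score Logical Memory score (>= 0).
#' @return one of `"impaired"`, `"borderline"`, `"normal"`.
#' @export
lm_band <- function(education_years, lm_score) {
  if (lm_score < 0) stop("lm_score must be >= 0")
  cuts <- lm_cuts(education_years)
  if (lm_score <= cuts$imp) "impaired"
  else if (lm_score >= cuts$bord[1] && lm_score <= cuts$bord[2]) "borderline"
  else "normal"
}

#' Build a clinical record
#'
#' @param complaint answer to the subjective memory-decline question:
#'   `"none"`, `"yes_no_worry"` or `"yes_worry"`.
#' @param moca MoCA score, 0-30.
#' @param cdr Clinical Dementia Rating: 0, 0.5 or 1.0.
#' @param lm_score Logical Memory score (>= 0).
#' @param education_years completed years of education.
#' @param gai,gds anxiety / depression inventory scores (>= 0).
#' @return a `clinical_record` list.
#' @export
clinical_record <- function(complaint, moca, cdr, lm_score, education_years,
                            gai = 0L, gds = 0L) {
  complaint <- match.arg(complaint, COMPLAINTS)
  if (!moca %in% 0:30) stop("moca must be an integer in 0..30")
  if (!cdr %in% c(0, 0.5, 1.0)) stop("cdr must be 0, 0.5 or 1.0")
  if (lm_score < 0 || education_years < 0 || gai < 0 || gds < 0)
    stop("scores and education must be >= 0")
  structure(list(complaint = complaint, moca = as.integer(moca), cdr = cdr,
                 lm_score = as.integer(lm_score),
                 education_years = as.integer(education_years),
                 gai = as.integer(gai), gds = as.integer(gds)),
            class = "clinical_record")
}

#' Classify a participant into a clinical group
#'
#' Deterministic, CDR-first rules:
#' * CDR 1.0, a "yes" complaint, MoCA 13-25 and impaired LM: `AD`.
#' * CDR 0.5, a "yes" complaint, impaired LM, MoCA 20-25: `lMCI`.
#' * CDR 0.5, a "yes" complaint, borderline LM, MoCA 20-26: `eMCI`.
#' * CDR 0, MoCA >= 26, LM at or above the education-stratified intact
#'   threshold: `SCD` when the complaint is worried, `CH` otherwise.
#' * Anything else: `UNCLASSIFIED`.
#'
#' The CDR-first ordering makes the five rules mutually exclusive even
#' where the LM bands overlap; every record maps to exactly one label.
#'
#' @param rec a [clinical_record()].
#' @return one of `"CH"`, `"SCD"`, `"eMCI"`, `"lMCI"`, `"AD"`,
#'   `"UNCLASSIFIED"`.
#' @export
classify_participant <- function(rec) {
  stopifnot(inherits(rec, "clinical_record"))
  cuts <- lm_cuts(rec$education_years)
  band <- lm_band(rec$education_years, rec$lm_score)
  has_complaint <- rec$complaint %in% c("yes_no_worry", "yes_worry")
  if (rec$cdr == 1.0) {
    if (has_complaint && rec$moca >= 13 && rec$moca <= 25 && band == "impaired")
      return("AD")
    return("UNCLASSIFIED")
  }
  if (rec$cdr == 0.5) {
    if (has_complaint && band == "impaired" && rec$moca >= 20 && rec$moca <= 25)
      return("lMCI")
    if (has_complaint && band == "borderline" && rec$moca >= 20 && rec$moca <= 26)
      return("eMCI")
    return("UNCLASSIFIED")
  }
  # CDR 0
  if (rec$moca >= 26 && rec$lm_score >= cuts$intact) {
    if (rec$complaint == "yes_worry") return("SCD")
    return("CH")
  }
  "UNCLASSIFIED"
}

#' Classify a cohort table
#'
#' Applies [classify_participant()] row-wise to a phenotype table with
#' columns `complaint`, `moca`, `cdr`, `lm_score`, `education_years`.
#'
#' @param table a data frame (e.g. from [make_cohort()]).
#' @return the table with a `classified_group` column appended.
#' @export
classify_cohort <- function(table) {
  needed <- c("complaint", "moca", "cdr", "lm_score", "education_years")
  if (!all(needed %in% names(table)))
    stop("cohort table lacks columns: ",
         paste(setdiff(needed, names(table)), collapse = ", "))
  table$classified_group <- vapply(seq_len(nrow(table)), function(i) {
    classify_participant(clinical_record(table$complaint[i], table$moca[i],
                                         table$cdr[i], table$lm_score[i],
                                         table$education_years[i]))
  }, "")
  table
}

# truncated-normal draw by rejection (narrow truncation only)
rtrunc <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, mean))
}

# Published per-group covariate moments (age / anxiety / depression /
# MoCA / delayed recall) and female fractions.
COHORT_MOMENTS <- list(
  age = list(CH = c(70, 6.3), SCD = c(71, 6.4), eMCI = c(73, 8.4),
             lMCI = c(76, 6.9), AD = c(75, 7.7)),
  gai = list(CH = c(1.3, 2.5), SCD = c(2.9, 3.5), eMCI = c(3.1, 4.6),
             lMCI = c(4.6, 7.5), AD = c(1.6, 2.5)),
  gds = list(CH = c(2.2, 2.9), SCD = c(5.6, 4.4), eMCI = c(6.6, 5.3),
             lMCI = c(7.1, 6.5), AD = c(4.6, 2.6)),
  moca = list(CH = c(28.0, 1.94), SCD = c(27.7, 1.38), eMCI = c(25.2, 1.82),
              lMCI = c(23.1, 3.09), AD = c(17.2, 5.36)),
  ravlt = list(CH = c(11.2, 2.3), SCD = c(9.5, 2.7), eMCI = c(7.9, 3.1),
               lMCI = c(3.4, 2.4), AD = c(0.6, 1.2)),
  female_frac = c(CH = 17 / 29, SCD = 37 / 66, eMCI = 11 / 22,
                  lMCI = 4 / 8, AD = 6 / 12),
  moca_range = list(CH = c(26, 30), SCD = c(26, 30), eMCI = c(20, 26),
                    lMCI = c(20, 25), AD = c(13, 25)),
  cdr = c(CH = 0, SCD = 0, eMCI = 0.5, lMCI = 0.5, AD = 1.0)
)

#' Draw one classification-consistent clinical record for a group
#'
#' Covariates follow the published per-group moments; MoCA, CDR, LM and
#' the complaint are drawn inside the target group's classification
#' region so the record round-trips through [classify_participant()].
#' Uses the current RNG stream.
#'
#' @param group one of CH, SCD, eMCI, lMCI, AD.
#' @return a list of covariates (age, sex, education_years, moca, cdr,
#'   lm_score, gai, gds, ravlt, complaint).
#' @export
gen_clinical_record <- function(group) {
  group <- match.arg(group, GROUPS)
  m <- COHORT_MOMENTS
  age <- rtrunc(m$age[[group]][1], m$age[[group]][2], 65, 95)
  sex <- if (runif(1) < m$female_frac[[group]]) "F" else "M"
  edu_bracket <- sample(c("high", "mid", "low"), 1,
                        prob = c(0.40, 0.55, 0.05))
  education_years <- switch(edu_bracket,
                            high = sample(16:20, 1),
                            mid = sample(8:15, 1),
                            low = sample(4:7, 1))
  cuts <- lm_cuts(education_years)
  lm_score <- switch(group,
    CH = , SCD = min(25L, cuts$intact + as.integer(round(rtrunc(6, 3, 0, 20)))),
    eMCI = sample(cuts$bord[1]:cuts$bord[2], 1),
    lMCI = , AD = sample(0:cuts$imp, 1))
  mr <- m$moca_range[[group]]
  moca <- as.integer(round(rtrunc(m$moca[[group]][1], m$moca[[group]][2],
                                  mr[1], mr[2])))
  complaint <- switch(group,
    CH = sample(c("none", "yes_no_worry"), 1),
    SCD = "yes_worry",
    sample(c("yes_no_worry", "yes_worry"), 1))
  list(age = age, sex = sex, education_years = education_years,
       moca = moca, cdr = m$cdr[[group]], lm_score = lm_score,
       gai = as.integer(round(rtrunc(m$gai[[group]][1], m$gai[[group]][2], 0, 30))),
       gds = as.integer(round(rtrunc(m$gds[[group]][1], m$gds[[group]][2], 0, 30))),
       ravlt = as.integer(round(rtrunc(m$ravlt[[group]][1], m$ravlt[[group]][2], 0, 15))),
       complaint = complaint)
}
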