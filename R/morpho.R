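# Normative morphometry: structure volumes from label fields, per-measure
# linear covariate adjustment trained on cognitively healthy subjects,
# adjusted Z-scores with a direction convention (negative = worse), the
# segmentation QC exclusion rule, and composite scores.

#' Structure volume from a label field
#'
#' @param labels integer label field.
#' @param structure structure name or label code.
#' @param voxel_size voxel edge length in mm.
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
region_volume <- function(labels, structure, voxel_size = 1) {
  code <- structure_code(structure)
  sum(labels == code) * voxel_size^3
}

#' Fit normative adjustment models on healthy controls
#'
#' Ordinary least squares of each raw measure on its covariates, trained
#' on CN subjects only; stores the coefficients and the
#' degrees-of-freedom-corrected residual SD used to scale Z-scores.
#' Grading measures adjust for age and sex; volume measures additionally
#' for estimated intracranial volume (`eicv`).
#'
#' @param training data frame of CN subjects holding the covariates and
#'   raw measure columns.
#' @param measures character vector of measure column names.
#' @param covariates named list mapping each measure to its covariate
#'   columns; defaults to age+sex for `snipe_*` and age+sex+eicv for
#'   `vol_*` measures.
#' @param min_n minimum training sample size.
#' @return a `normative_model` list, one fit per measure.
#' @export
fit_normative <- function(training, measures, covariates = NULL, min_n = 20L) {
  if (nrow(training) < min_n)
    stop("refusing to fit normative model on fewer than ", min_n, " subjects")
  if (is.null(covariates))
    covariates <- setNames(lapply(measures, function(m) {
      if (grepl("^vol_", m)) c("age", "sex", "eicv") else c("age", "sex")
    }), measures)
  fits <- list()
  for (m in measures) {
    cv <- covariates[[m]]
    miss <- setdiff(c(m, cv), names(training))
    if (length(miss))
      stop("training table lacks columns: ", paste(miss, collapse = ", "))
    df <- training[, c(m, cv)]
    df <- df[complete.cases(df), , drop = FALSE]
    if (nrow(df) < min_n)
      stop("fewer than ", min_n, " complete training rows for ", m)
    fml <- stats::as.formula(paste(m, "~", paste(cv, collapse = " + ")))
    fit <- lm(fml, data = df)
    if (any(is.na(coef(fit)))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop("rank-deficient normative design for ", m,
           "; collinear terms: ", paste(bad, collapse = ", "))
    }
    sigma <- summary(fit)$sigma
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate residual SD for ", m)
    fits[[m]] <- list(fit = fit, covariates = cv, residual_sd = sigma,
                      n = nrow(df))
  }
  structure(list(fits = fits, measures = measures), class = "normative_model")
}

#' Covariate-adjusted Z-score
#'
#' `Z = (raw - predicted) / residual SD`, optionally sign-flipped so
#' that negative always means "more AD-like" (used for grading scores,
#' where the raw scale runs 1 = healthy to 2 = AD).
#'
#' @param raw raw measure value(s).
#' @param covariates data frame (or coercible row) with the model's
#'   covariate columns.
#' @param model a `normative_model`.
#' @param measure which measure's fit to use.
#' @param flip_sign multiply the Z by -1.
#' @return data frame with `raw`, `z` and `flipped`.
#' @export
z_adjust <- function(raw, covariates, model, measure, flip_sign = FALSE) {
  stopifnot(inherits(model, "normative_model"))
  f <- model$fits[[measure]]
  if (is.null(f)) stop("no normative fit for measure ", measure)
  covariates <- as.data.frame(covariates)
  miss <- setdiff(f$covariates, names(covariates))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  pred <- predict(f$fit, newdata = covariates)
  z <- (raw - pred) / f$residual_sd
  if (flip_sign) z <- -z
  data.frame(raw = raw, z = as.numeric(z), flipped = flip_sign)
}

#' Segmentation QC exclusion rule
#'
#' Counts voxels labelled as the structure in exactly one of the
#' estimated and reference fields (symmetric difference); the structure
#' is excluded when the count reaches the threshold.
#'
#' @param estimated,reference integer label fields on the same grid.
#' @param structure structure name or code.
#' @param threshold exclusion threshold in voxels.
#' @return list with `excluded` and `error_voxels`.
#' @export
qc_exclude <- function(estimated, reference, structure, threshold = 100L) {
  if (!identical(dim(estimated), dim(reference))) stop("grid mismatch")
  code <- structure_code(structure)
  e <- estimated == code
  r <- reference == code
  count <- sum(xor(e, r))
  list(excluded = count >= threshold, error_voxels = count)
}

#' Composite Z-score
#'
#' Combination recipes for adjusted scores on a common direction
#' convention: `mean_all` averages all region Zs of one modality,
#' `mean_bilateral_snipe` averages the four grading Zs (bilateral HPC +
#' EC), and `combined` averages an atrophy composite with a grading
#' composite.
#'
#' @param z named numeric vector of adjusted Z-scores (recipes
#'   `mean_all`, `mean_bilateral_snipe`) or length-2 vector
#'   `c(atrophy_composite, snipe_composite)` for `combined`.
#' @param recipe combination rule.
#' @param excluded logical vector flagging regions excluded by QC; any
#'   TRUE is an error.
#' @return scalar composite Z.
#' @export
composite_score <- function(z, recipe = c("mean_all", "mean_bilateral_snipe",
                                          "combined"),
                            excluded = rep(FALSE, length(z))) {
  recipe <- match.arg(recipe)
  if (length(z) == 0) stop("empty score set; composite undefined")
  if (any(excluded)) stop("excluded regions cannot enter a composite")
  if (recipe == "mean_bilateral_snipe" && length(z) != 4)
    stop("mean_bilateral_snipe expects the four bilateral HPC/EC scores")
  if (recipe == "combined" && length(z) != 2)
    stop("combined expects c(atrophy_composite, snipe_composite)")
  mean(z)
}

#' Adjust a cohort's raw measures to normative Z-scores
#'
#' Applies [z_adjust()] measure-wise over a cohort table, flipping the
#' sign of grading (`snipe_*`) measures so negative = more AD-like,
#' matching the convention that the zero line is normality.
#'
#' @param table cohort table holding covariates and raw measure columns.
#' @param model a `normative_model`.
#' @param measures measures to adjust (default: the model's).
#' @return long data frame: subject_id, group, measure, raw, z, flipped.
#' @export
adjust_cohort <- function(table, model, measures = model$measures) {
  out <- lapply(measures, function(m) {
    zz <- z_adjust(table[[m]], table, model, m,
                   flip_sign = grepl("^snipe_", m))
    data.frame(subject_id = table$subject_id, group = table$group,
               measure = m, raw = zz$raw, z = zz$z, flipped = zz$flipped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
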