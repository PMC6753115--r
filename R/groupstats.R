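# Group-comparison battery: one-way ANOVA with Tukey HSD post-hocs for
# the main outcomes, Benjamini-Hochberg FDR across region batteries,
# Cohen's d effect sizes, chi-square for categorical characteristics,
# and the symptom-by-complaint moderation model. Classical machinery is
# delegated to base R; this module owns the contracts and the report.

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two observations")
  groups
}

#' One-way ANOVA
#'
#' Classical (equal-variance) between/within decomposition.
#'
#' @param values numeric outcome.
#' @param groups group labels.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- check_groups(values, groups)
  fit <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted pairwise tests; unbalanced designs use the
#' Tukey-Kramer variant.
#'
#' @inheritParams anova_oneway
#' @return data frame with `group1`, `group2`, `diff` (group1 - group2),
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- check_groups(values, groups)
  df <- data.frame(y = values, g = groups)
  tk <- TukeyHSD(aov(y ~ g, data = df))$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 1),
             group2 = vapply(pairs, `[`, "", 2),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' `(n-1)`-weighted pooled SD.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return d; `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need n >= 2")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) {
    warning("zero pooled SD; effect size undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR step-up
#'
#' Rejects all ordered p-values up to the largest index `i` with
#' `p(i) <= i * q / m`.
#'
#' @param p raw p-values in \[0, 1\], all finite.
#' @param q target false discovery rate.
#' @return an `fdr_result`: `p` (input order), `p_adj` (BH-adjusted),
#'   `reject` (input order), `critical_index` (0 when none), `q`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  crit <- which(ps <= seq_len(m) * q / m)
  k <- if (length(crit)) max(crit) else 0L
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  structure(list(p = p, p_adj = p.adjust(p, method = "BH"),
                 reject = reject, critical_index = k, q = q),
            class = "fdr_result")
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts matrix of nonnegative counts with nondegenerate margins.
#' @return list with `X2`, `p`, `df`.
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margins (empty row or column)")
  fit <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(fit$expected == 0)) stop("zero expected cell count")
  list(X2 = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Symptom-by-complaint moderation model
#'
#' Linear model `biomarker ~ group * symptom` for a two-level complaint
#' factor (CH vs SCD); reports the interaction coefficient. When the
#' symptom score is constant the interaction is dropped and flagged.
#'
#' @param z biomarker Z-scores.
#' @param group two-level factor (complaint group).
#' @param symptom numeric symptom score (e.g. anxiety or depression
#'   inventory).
#' @param min_per_group minimum subjects per group.
#' @return list with `estimate`, `se`, `t`, `p`, `dropped`.
#' @export
interaction_model <- function(z, group, symptom, min_per_group = 10L) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < min_per_group))
    stop("need at least ", min_per_group, " subjects per group")
  if (var(symptom) < 1e-24) {
    return(list(estimate = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, dropped = TRUE))
  }
  fit <- lm(z ~ group * symptom)
  cf <- summary(fit)$coefficients
  term <- grep(":", rownames(cf), value = TRUE)
  if (length(term) != 1 || any(is.na(coef(fit))))
    stop("collinear moderation design")
  list(estimate = cf[term, 1], se = cf[term, 2], t = cf[term, 3],
       p = cf[term, 4], dropped = FALSE)
}

#' Group-gradient report for adjusted scores
#'
#' Per measure: group means/SDs, the omnibus one-way ANOVA, all Tukey
#' pairwise comparisons, and Cohen's d of each group against the
#' reference group, with a star flag where the Tukey-adjusted p against
#' the reference falls below `alpha`.
#'
#' @param scores long data frame with `group`, `measure`, `z` (as from
#'   [adjust_cohort()]).
#' @param reference reference group name.
#' @param alpha star threshold on the Tukey-adjusted p.
#' @return list of data frames: `omnibus`, `pairwise`, `vs_reference`,
#'   `group_means`.
#' @export
gradient_report <- function(scores, reference = "CH", alpha = 0.05) {
  if (!reference %in% scores$group) stop("reference group absent: ", reference)
  # canonical clinical ordering where it applies, so the report reads
  # CH..AD regardless of how the table was stored
  glev <- unique(as.character(scores$group))
  if (all(glev %in% GROUPS)) glev <- intersect(GROUPS, glev)
  omnibus <- list(); pairwise <- list(); vs_ref <- list(); gm <- list()
  for (m in unique(scores$measure)) {
    sm <- scores[scores$measure == m, ]
    g <- droplevels(factor(sm$group, levels = glev))
    an <- anova_oneway(sm$z, g)
    omnibus[[m]] <- data.frame(measure = m, F = an$F, p = an$p)
    tk <- tukey_hsd(sm$z, g)
    tk$measure <- m
    pairwise[[m]] <- tk
    gm[[m]] <- do.call(rbind, lapply(levels(g), function(lv) {
      data.frame(measure = m, group = lv, mean_z = mean(sm$z[g == lv]),
                 sd_z = sd(sm$z[g == lv]), n = sum(g == lv))
    }))
    refz <- sm$z[g == reference]
    vs_ref[[m]] <- do.call(rbind, lapply(setdiff(levels(g), reference),
      function(lv) {
        pr <- tk[(tk$group1 == lv & tk$group2 == reference) |
                   (tk$group1 == reference & tk$group2 == lv), ]
        data.frame(measure = m, group = lv,
                   d_vs_ref = cohens_d(sm$z[g == lv], refz),
                   p_tukey = pr$p_adj[1], star = pr$p_adj[1] < alpha)
      }))
  }
  list(omnibus = do.call(rbind, omnibus),
       pairwise = do.call(rbind, pairwise),
       vs_reference = do.call(rbind, vs_ref),
       group_means = do.call(rbind, gm))
}
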