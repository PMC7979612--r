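#' GAP point table
#'
#' The gender/age/physiology point assignments used to stage chronic ILD.
#' Returned as an editable list so alternative transcriptions can be passed
#' to [gap_points()].
#'
#' Points: gender female 0 / male 1; age (years) <=60: 0, 61-65: 1, >65: 2;
#' FVC %predicted >=75: 0, 50-74: 1, <50: 2; DLCO %predicted >55: 0,
#' 36-55: 1, <=35: 2, cannot perform: 3. Stage I = 0-3 points,
#' II = 4-5, III = 6-8.
#'
#' @return A list with components `gender`, `age_breaks`, `fvc_breaks`,
#'   `dlco_breaks`, `dlco_cannot_perform`, `stage_breaks`.
#' @export
gap_table <- function() {
  list(
    gender = c(female = 0L, male = 1L),
    # age: one extra point for each threshold strictly exceeded (60, 65 y)
    age  = list(thresholds = c(60, 65), points = c(0L, 1L, 2L)),
    # FVC: one extra point for each threshold fallen strictly below (75, 50)
    fvc  = list(thresholds = c(75, 50), points = c(0L, 1L, 2L)),
    # DLCO: thresholds 55 (inclusive below scores) and 35
    dlco = list(thresholds = c(55, 35), points = c(0L, 1L, 2L)),
    dlco_cannot_perform = 3L,
    stage_breaks = list(bounds = c(3, 5, 8), stages = c(1L, 2L, 3L))
  )
}

#' GAP index points and stage
#'
#' Computes the composite gender-age-physiology score and stage for one
#' patient record.
#'
#' @param gender `"female"` or `"male"`.
#' @param age Age in years (> 0).
#' @param fvc_pct FVC as percent predicted (> 0).
#' @param dlco_pct DLCO as percent predicted (> 0), or `NA` if the patient
#'   cannot perform the test.
#' @param table Point table, see [gap_table()].
#' @return List with integer `points` (0-8) and `stage` (1-3).
#' @examples
#' gap_points("female", 58, fvc_pct = 98, dlco_pct = 79)  # 0 points, stage 1
#' gap_points("male", 68, fvc_pct = 65, dlco_pct = 40)    # 5 points, stage 2
#' @export
gap_points <- function(gender, age, fvc_pct, dlco_pct, table = gap_table()) {
  gender <- match.arg(gender, c("female", "male"))
  if (!is.finite(age) || age <= 0 || age > 120) stop("age out of range")
  if (!is.finite(fvc_pct) || fvc_pct <= 0 || fvc_pct > 250) stop("fvc_pct out of range")
  pts <- table$gender[[gender]]
  pts <- pts + table$age$points[1L + sum(age > table$age$thresholds)]
  pts <- pts + table$fvc$points[1L + sum(fvc_pct < table$fvc$thresholds)]
  if (is.na(dlco_pct)) {
    pts <- pts + table$dlco_cannot_perform
  } else {
    if (!is.finite(dlco_pct) || dlco_pct <= 0 || dlco_pct > 250)
      stop("dlco_pct out of range")
    # DLCO > 55 scores 0; 36-55 scores 1; <= 35 scores 2
    pts <- pts + table$dlco$points[1L + sum(dlco_pct <= table$dlco$thresholds)]
  }
  stage <- table$stage_breaks$stages[which(pts <= table$stage_breaks$bounds)[1]]
  list(points = as.integer(pts), stage = as.integer(stage))
}

#' Six-lobe-adjusted coarseness score
#'
#' Per-lobe fibrosis coarseness grades (0 normal, 1 ground-glass, 2 fine
#' reticulation, 3 coarse reticulation, 4 honeycombing) are summed and
#' rescaled to a six-lobe equivalent: `sum(grades) / n_involved * 6`, where
#' `n_involved` is the number of lobes with a nonzero grade. All-normal
#' lungs score 0. The score therefore lies in [0, 24] and equals six times
#' the mean grade of the involved lobes.
#'
#' @param grades Integer vector of per-lobe grades in 0..4 (length >= 1).
#' @return The adjusted coarseness score.
#' @examples
#' coarseness_score(c(1, 2, 3, 0, 0, 0))  # (6 / 3) * 6 = 12
#' @export
coarseness_score <- function(grades) {
  if (length(grades) < 1 || any(is.na(grades)) ||
      any(grades != as.integer(grades)) || any(grades < 0 | grades > 4))
    stop("grades must be integers in 0..4")
  n_ild <- sum(grades > 0)
  if (n_ild == 0) return(0)
  sum(grades) / n_ild * 6
}

#' Fibrosis extent class
#'
#' Dichotomizes the visually estimated fibrosis extent at 20% of the lung:
#' strictly more than 20% is severe, otherwise mild (the 20% boundary is
#' assigned to mild since "more than 20%" is strict).
#'
#' @param extent_fraction Fraction of lung involved, in [0, 1].
#' @return `"mild"` or `"severe"` (character, vectorized).
#' @export
extent_class <- function(extent_fraction) {
  if (any(!is.finite(extent_fraction)) ||
      any(extent_fraction < 0 | extent_fraction > 1))
    stop("extent_fraction must be in [0, 1]")
  ifelse(extent_fraction > 0.20, "severe", "mild")
}

#' Per-variable group comparison
#'
#' Compares every column of a cohort table between two groups: continuous
#' variables with the unpaired two-sided Wilcoxon rank-sum test, categorical
#' variables (factor/character/logical) with the chi-squared test without
#' continuity correction, falling back to Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param table Data frame of variables to compare.
#' @param grouping Factor-like vector with exactly two levels, one entry per
#'   row of `table`.
#' @return Data frame with columns `variable`, `type`, `test`, `statistic`,
#'   `p_value`.
#' @export
group_compare <- function(table, grouping) {
  grouping <- factor(grouping)
  stopifnot(nlevels(grouping) == 2L, nrow(table) == length(grouping))
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      ht <- suppressWarnings(stats::wilcox.test(x ~ grouping, exact = FALSE))
      data.frame(variable = v, type = "continuous", test = "wilcoxon_rank_sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      tab <- table(factor(x), grouping)
      exp_cells <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
      if (any(exp_cells < 5)) {
        ht <- stats::fisher.test(tab)
        data.frame(variable = v, type = "categorical", test = "fisher_exact",
                   statistic = NA_real_, p_value = ht$p.value)
      } else {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(variable = v, type = "categorical", test = "chi_squared",
                   statistic = unname(ht$statistic), p_value = ht$p.value)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
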