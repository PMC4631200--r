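# WT-relative knockout effects and their condition specificity.

#' Thresholds for effect calling and specificity
#'
#' A knockout has an effect in a condition when its ratio to wild type is
#' strictly above `increase` or strictly below `decrease`; boundary values
#' count as no effect. When a knockout has effects in several compared
#' conditions, it is condition-specific if the spread (max - min) of the
#' effect magnitudes exceeds `spread`.
#'
#' @param increase,decrease,spread numeric thresholds (screen defaults
#'   1.1, 0.8, 0.3).
#' @return list of class `"effect_thresholds"`.
#' @export
effect_thresholds <- function(increase = 1.1, decrease = 0.8, spread = 0.3) {
  stopifnot(decrease < increase, increase > 0, decrease > 0, spread >= 0)
  structure(list(increase = increase, decrease = decrease, spread = spread),
            class = "effect_thresholds")
}

#' Ratio of a strain's reporter level to wild type
#'
#' @param mat an `"expression_matrix"`.
#' @param strain,condition cell to evaluate.
#' @return the dimensionless ratio strain / WT.
#' @export
effect_ratio <- function(mat, strain, condition) {
  stopifnot(inherits(mat, "expression_matrix"))
  wt <- mat$wt[[condition]]
  if (is.null(wt) || is.na(wt)) stop("WT value missing for condition ", condition)
  if (wt == 0) stop("WT value is zero for condition ", condition)
  unname(mat$values[strain, condition] / wt)
}

#' Classify one WT-relative ratio
#'
#' @param ratio non-negative ratio to WT (0 can arise from clipped
#'   autofluorescence correction and classifies as a decrease).
#' @param thresholds an [effect_thresholds()].
#' @return `"increase"`, `"decrease"` or `"none"` (strict inequalities;
#'   exactly 1.1 or 0.8 is `"none"`). Vectorized.
#' @export
classify_effect <- function(ratio, thresholds = effect_thresholds()) {
  stopifnot(all(ratio >= 0 | is.na(ratio)))
  out <- rep("none", length(ratio))
  out[!is.na(ratio) & ratio > thresholds$increase] <- "increase"
  out[!is.na(ratio) & ratio < thresholds$decrease] <- "decrease"
  out[is.na(ratio)] <- NA_character_
  out
}

#' Per-strain, per-condition effect profiles
#'
#' Computes the ratio to wild type, its log2, and the effect label for
#' every strain and condition, plus the stress-general call: a strain with
#' an effect in at least one stress condition has a general stress effect
#' whose magnitude is the maximum over its effect-bearing stress conditions
#' (ratio for increases; magnitudes of mixed directions are compared as
#' distance from 1).
#'
#' @param mat an `"expression_matrix"`.
#' @param thresholds an [effect_thresholds()].
#' @param stress_conditions conditions counted as stresses.
#' @return list with `profile` (long data frame: strain, condition, ratio,
#'   log2_ratio, label) and `stress` (per strain: stress_effect flag,
#'   stress_magnitude).
#' @export
effect_profiles <- function(mat, thresholds = effect_thresholds(),
                            stress_conditions = c("heat", "KCl", "diamide")) {
  stopifnot(inherits(mat, "expression_matrix"))
  strains <- setdiff(rownames(mat$values), c(mat$wt_strain, "noGFP"))
  conditions <- colnames(mat$values)
  prof <- expand.grid(strain = strains, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prof$ratio <- mapply(function(s, cond) effect_ratio(mat, s, cond),
                       prof$strain, prof$condition)
  prof$log2_ratio <- log2(prof$ratio)
  prof$label <- classify_effect(prof$ratio, thresholds)

  stress_conditions <- intersect(stress_conditions, conditions)
  stress <- data.frame(strain = strains, stress_effect = FALSE,
                       stress_magnitude = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(strains)) {
    p <- prof[prof$strain == strains[i] &
                prof$condition %in% stress_conditions, ]
    eff <- p[!is.na(p$label) & p$label != "none", ]
    if (nrow(eff)) {
      stress$stress_effect[i] <- TRUE
      if (length(unique(eff$label)) == 1) {
        mag <- if (eff$label[1] == "increase") max(eff$ratio) else min(eff$ratio)
      } else {
        mag <- eff$ratio[which.max(abs(eff$ratio - 1))]
      }
      stress$stress_magnitude[i] <- mag
    }
  }
  list(profile = prof, stress = stress)
}

# Specificity rule for one direction within a compared condition set.
specificity_one_direction <- function(conditions, ratios, direction, spread) {
  if (length(conditions) == 1) return(conditions)
  if (max(ratios) - min(ratios) <= spread) return("common")
  avg <- mean(ratios)
  if (direction == "increase") conditions[ratios > avg] else conditions[ratios < avg]
}

#' Condition specificity of one strain's effects
#'
#' A strain with an effect in exactly one compared condition is specific to
#' it. With effects in several conditions of the same direction, the effect
#' magnitudes (the ratios) are compared: if their spread exceeds the
#' threshold, the strain is specific to the conditions above the mean (for
#' increases) or below it (for decreases); otherwise the effect is common.
#' Mixed directions are handled per direction and the labels pooled.
#'
#' @param ratios named vector of ratios over the compared conditions
#'   (>= 2 conditions).
#' @param thresholds an [effect_thresholds()].
#' @return character vector: the specific conditions, `"common"`, or
#'   `"no_effect"`.
#' @export
assign_specificity <- function(ratios, thresholds = effect_thresholds()) {
  if (length(ratios) < 2) stop("specificity needs >= 2 compared conditions")
  labels <- classify_effect(ratios, thresholds)
  eff <- which(!is.na(labels) & labels != "none")
  if (length(eff) == 0) return("no_effect")
  out <- character(0)
  for (dir in unique(labels[eff])) {
    sel <- eff[labels[eff] == dir]
    out <- c(out, specificity_one_direction(names(ratios)[sel], ratios[sel],
                                            dir, thresholds$spread))
  }
  unique(out)
}

#' Venn-region counts of stress-condition specificity
#'
#' Assigns every strain with at least one stress-condition effect to
#' exactly one region of the stress Venn diagram: the set of conditions it
#' is specific to, or the all-conditions centre for common effects, and
#' counts strains per region.
#'
#' @param mat an `"expression_matrix"`.
#' @param thresholds an [effect_thresholds()].
#' @param stress_conditions the compared stress conditions.
#' @return list with `counts` (named integer vector per region; region
#'   names are `+`-joined condition sets, `common` for the centre) and
#'   `assignment` (per-strain region).
#' @export
summarize_specificity <- function(mat, thresholds = effect_thresholds(),
                                  stress_conditions = c("heat", "KCl", "diamide")) {
  stopifnot(inherits(mat, "expression_matrix"))
  stress_conditions <- intersect(stress_conditions, colnames(mat$values))
  strains <- setdiff(rownames(mat$values), c(mat$wt_strain, "noGFP"))
  region <- character(0)
  for (s in strains) {
    ratios <- vapply(stress_conditions,
                     function(cond) effect_ratio(mat, s, cond), numeric(1))
    names(ratios) <- stress_conditions
    spec <- assign_specificity(ratios, thresholds)
    if (identical(spec, "no_effect")) next
    key <- if ("common" %in% spec && length(spec) == 1) "common" else
      paste(sort(setdiff(spec, "common")), collapse = "+")
    if (key == "") key <- "common"
    region[s] <- key
  }
  counts <- if (length(region)) table(region) else table(character(0))
  list(counts = counts, assignment = region)
}
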