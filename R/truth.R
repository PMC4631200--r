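# Ground-truth generative model of the screen: per-gene additive and
# multiplicative knockout components, Msn2/4-dependent fractions, per-condition
# wild-type baselines, and the noise model used by the event-level simulators.

#' Sampling configuration for a synthetic screen truth table
#'
#' Ranges and noise parameters for [make_truth()]. Defaults describe a
#' realistic reporter screen: knockout multiplicative components between
#' 0.3x and 3x, additive components between -30% and +50% of the
#' condition baseline, Msn2/4-dependent fractions spanning slightly beyond
#' \[0, 1\] so that cooperative (>1) and negative regimes occur, per-cell
#' log-GFP spread of 0.3, and a 5% between-replicate coefficient of
#' variation.
#'
#' @param m_range range for the multiplicative component m (dimensionless).
#' @param a_frac_range range for the additive component as a fraction of the
#'   condition's wild-type baseline.
#' @param d_frac_range range for the Msn2/4-dependent fraction of each
#'   knockout's effect.
#' @param baseline_range range for per-condition wild-type baselines (GFP a.u.).
#' @param autofluorescence autofluorescence offset added to every event
#'   (GFP a.u.).
#' @param msn24_residual residual baseline of the msn2 msn4 double mutant as a
#'   fraction of the wild-type baseline; the KCl-specific value reflects the
#'   HOG-pathway contribution that bypasses Msn2/4.
#' @param msn24_residual_kcl residual fraction used for conditions whose name
#'   contains "kcl" (case-insensitive).
#' @param replicate_cv between-replicate coefficient of variation of a well's
#'   median (dimensionless).
#' @param cell_sd standard deviation of per-cell log GFP (natural log scale).
#' @param outlier_fraction fraction of scatter events drawn from the uniform
#'   outlier box rather than the dense cell cloud.
#' @return a list of class `"truth_config"`.
#' @export
truth_config <- function(m_range = c(0.3, 3),
                         a_frac_range = c(-0.3, 0.5),
                         d_frac_range = c(-0.5, 1.5),
                         baseline_range = c(100, 1000),
                         autofluorescence = 20,
                         msn24_residual = 0.2,
                         msn24_residual_kcl = 0.3,
                         replicate_cv = 0.05,
                         cell_sd = 0.3,
                         outlier_fraction = 0.1) {
  stopifnot(length(m_range) == 2, m_range[1] <= m_range[2], m_range[1] >= 0,
            length(baseline_range) == 2, length(a_frac_range) == 2,
            length(d_frac_range) == 2,
            replicate_cv >= 0, cell_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  if (any(baseline_range <= 0)) {
    stop("baseline_range must be strictly positive")
  }
  structure(list(
    m_range = m_range, a_frac_range = a_frac_range,
    d_frac_range = d_frac_range, baseline_range = baseline_range,
    autofluorescence = autofluorescence,
    msn24_residual = msn24_residual,
    msn24_residual_kcl = msn24_residual_kcl,
    replicate_cv = replicate_cv, cell_sd = cell_sd,
    outlier_fraction = outlier_fraction
  ), class = "truth_config")
}

#' Generate a ground-truth table for a synthetic screen
#'
#' Samples, per gene and condition, a multiplicative component `m`, an
#' additive component `a` and an Msn2/4-dependent fraction `d_frac`, plus a
#' wild-type baseline and autofluorescence offset per condition. The single
#' knockout's expected reporter level is `wt_baseline * m + a`, so its total
#' effect decomposes as `a + wt_baseline * (m - 1)` by construction. The
#' table is the hidden truth against which every downstream stage can be
#' checked.
#'
#' @param genes character vector of gene identifiers (non-empty). The
#'   reserved names `WT` and `noGFP` may not be used as genes.
#' @param conditions character vector of condition names (non-empty).
#' @param config a [truth_config()].
#' @param seed integer seed; the same seed and config give an identical table.
#' @return a list of class `"truth_table"` with elements `effects` (data
#'   frame: gene, condition, m, a, d_frac), `conditions` (data frame:
#'   condition, wt_baseline, autofluorescence, msn24_residual), `noise`,
#'   `config` and `seed`.
#' @export
make_truth <- function(genes, conditions, config = truth_config(), seed = 1) {
  if (length(genes) == 0) stop("at least one gene is required")
  if (length(conditions) == 0) stop("at least one condition is required")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (any(genes %in% c("WT", "noGFP"))) {
    stop("'WT' and 'noGFP' are reserved strain names, not genes")
  }
  stopifnot(inherits(config, "truth_config"))

  with_seed(seed, {
    cond <- data.frame(
      condition = conditions,
      wt_baseline = stats::runif(length(conditions),
                                 config$baseline_range[1],
                                 config$baseline_range[2]),
      autofluorescence = config$autofluorescence,
      msn24_residual = ifelse(grepl("kcl", conditions, ignore.case = TRUE),
                              config$msn24_residual_kcl,
                              config$msn24_residual),
      stringsAsFactors = FALSE
    )
    eff <- expand.grid(gene = genes, condition = conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(eff)
    eff$m <- stats::runif(n, config$m_range[1], config$m_range[2])
    base <- cond$wt_baseline[match(eff$condition, cond$condition)]
    eff$a <- stats::runif(n, config$a_frac_range[1], config$a_frac_range[2]) * base
    eff$d_frac <- stats::runif(n, config$d_frac_range[1], config$d_frac_range[2])

    structure(list(
      effects = eff,
      conditions = cond,
      interactions = data.frame(gene_x = character(0), gene_y = character(0),
                                condition = character(0), delta = numeric(0),
                                stringsAsFactors = FALSE),
      noise = list(replicate_cv = config$replicate_cv,
                   cell_sd = config$cell_sd,
                   outlier_fraction = config$outlier_fraction),
      config = config,
      seed = seed
    ), class = "truth_table")
  })
}

#' Inject a genetic interaction into the generative truth
#'
#' Adds `delta` (GFP a.u.) to the expected level of every genotype deleting
#' both genes, on top of the neutral combined-model expectation
#' `baseline * m_x * m_y + a_x + a_y`. Used to plant known interactions
#' (e.g. pure masking pairs, where `delta` is chosen so the double equals
#' one of the singles) when testing interaction detection.
#'
#' @param truth a [make_truth()] table.
#' @param gene_x,gene_y interacting genes (order irrelevant).
#' @param condition condition the interaction acts in.
#' @param delta deviation of the double from the neutral expectation (a.u.).
#' @return the modified truth table.
#' @export
inject_interaction <- function(truth, gene_x, gene_y, condition, delta) {
  stopifnot(inherits(truth, "truth_table"))
  truth_row(truth, gene_x, condition)
  truth_row(truth, gene_y, condition)
  truth$interactions <- rbind(truth$interactions, data.frame(
    gene_x = gene_x, gene_y = gene_y, condition = condition, delta = delta,
    stringsAsFactors = FALSE))
  truth
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Synthetic screen truth table: %d genes x %d conditions (seed %d)\n",
              length(unique(x$effects$gene)), nrow(x$conditions), x$seed))
  invisible(x)
}

truth_row <- function(truth, gene, condition) {
  i <- which(truth$effects$gene == gene & truth$effects$condition == condition)
  if (length(i) != 1) stop(sprintf("gene '%s' unknown to the truth table", gene))
  truth$effects[i, ]
}

truth_condition <- function(truth, condition) {
  i <- which(truth$conditions$condition == condition)
  if (length(i) != 1) stop(sprintf("condition '%s' unknown to the truth table", condition))
  truth$conditions[i, ]
}

#' Expected reporter level of a genotype under the generative model
#'
#' For k deleted genes the expected GFP is
#' `wt_baseline * prod(m_i) + sum(a_i)`. When both `msn2` and `msn4` are
#' deleted, the baseline is replaced by the residual msn2 msn4 baseline
#' (a configured fraction of wild type) and each remaining gene contributes
#' only the Msn2/4-independent part `(1 - d_frac) * F` of its total
#' wild-type-relative effect `F = a + wt_baseline * (m - 1)`. The `noGFP`
#' control has expectation 0 (autofluorescence is added only at the event
#' level). Deleting `msn2` without `msn4` (or vice versa) treats it as an
#' ordinary gene of the truth table.
#'
#' @param genotype character vector of deleted genes; `character(0)` or
#'   `"WT"` means wild type, `"noGFP"` the untagged control.
#' @param condition condition name present in the truth table.
#' @param truth a [make_truth()] table.
#' @return expected GFP level (a.u.), autofluorescence not included.
#' @export
expected_gfp <- function(genotype, condition, truth) {
  stopifnot(inherits(truth, "truth_table"))
  cnd <- truth_condition(truth, condition)
  genotype <- setdiff(genotype, "WT")
  if (length(genotype) == 0) return(cnd$wt_baseline)
  if (identical(genotype, "noGFP")) return(0)
  if (any(genotype == "noGFP")) stop("'noGFP' cannot be combined with deletions")

  if (all(c("msn2", "msn4") %in% genotype)) {
    others <- setdiff(genotype, c("msn2", "msn4"))
    value <- cnd$msn24_residual * cnd$wt_baseline
    for (g in others) {
      r <- truth_row(truth, g, condition)
      f_total <- r$a + cnd$wt_baseline * (r$m - 1)
      value <- value + (1 - r$d_frac) * f_total
    }
    return(value)
  }

  m_prod <- 1
  a_sum <- 0
  for (g in genotype) {
    r <- truth_row(truth, g, condition)
    m_prod <- m_prod * r$m
    a_sum <- a_sum + r$a
  }
  value <- cnd$wt_baseline * m_prod + a_sum
  ia <- truth$interactions
  if (nrow(ia)) {
    hit <- ia$condition == condition &
      ia$gene_x %in% genotype & ia$gene_y %in% genotype
    value <- value + sum(ia$delta[hit])
  }
  value
}
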