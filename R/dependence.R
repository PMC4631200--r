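# Msn2/4-dependence score: how much of a knockout's effect on the reporter
# is routed through Msn2/4, measured by comparing the knockout with and
# without the msn2 msn4 background.

#' Msn2/4-dependence score of a knockout
#'
#' Compares the reporter level of the single knockout with the triple
#' mutant (knockout plus msn2 msn4):
#' \deqn{D_X = \frac{GFP_{\Delta X} - GFP_{\Delta X \Delta msn2 \Delta msn4}}
#'                 {GFP_{\Delta X} - GFP_{\Delta msn2 \Delta msn4}}}
#' `D_X = 1` when the triple equals the msn2 msn4 double (the knockout's
#' effect is fully Msn2/4 dependent); `0 <= D_X < 1` when part of the
#' effect bypasses Msn2/4 (only `D_X * 100` percent of the effect is
#' Msn2/4 dependent); `D_X > 1` when the triple drops below the msn2 msn4
#' double (cooperativity with Msn2/4); and `D_X < 0` when deleting Msn2/4
#' on the knockout background increases reporter activity relative to the
#' knockout. The score is undefined (flagged, no number emitted) when the
#' knockout and the msn2 msn4 double are too close for the ratio to be
#' meaningful.
#'
#' @param gfp_wt wild-type reporter level (a.u.).
#' @param gfp_x single-knockout level.
#' @param gfp_msn24 msn2 msn4 double-mutant level.
#' @param gfp_x_msn24 triple-mutant level.
#' @param floor_frac undefined below `floor_frac * gfp_wt` of denominator
#'   magnitude (default 0.02).
#' @param dependent_tol half-width of the band around 1 labelled
#'   `"dependent"`.
#' @return one-row data frame: `d`, `regime` (`dependent`,
#'   `partially_independent`, `cooperative`, `negative` or `undefined`)
#'   plus the four inputs. Vectorized over the four GFP arguments.
#' @export
dependence_score <- function(gfp_wt, gfp_x, gfp_msn24, gfp_x_msn24,
                             floor_frac = 0.02, dependent_tol = 0.05) {
  n <- max(length(gfp_wt), length(gfp_x), length(gfp_msn24),
           length(gfp_x_msn24))
  gfp_wt <- rep_len(gfp_wt, n); gfp_x <- rep_len(gfp_x, n)
  gfp_msn24 <- rep_len(gfp_msn24, n); gfp_x_msn24 <- rep_len(gfp_x_msn24, n)
  denom <- gfp_x - gfp_msn24
  defined <- abs(denom) >= floor_frac * gfp_wt
  d <- ifelse(defined, (gfp_x - gfp_x_msn24) / denom, NA_real_)
  regime <- rep("undefined", n)
  regime[defined & d < 0] <- "negative"
  regime[defined & d >= 0 & d < 1 - dependent_tol] <- "partially_independent"
  regime[defined & abs(d - 1) <= dependent_tol] <- "dependent"
  regime[defined & d > 1 + dependent_tol] <- "cooperative"
  data.frame(d = d, regime = regime,
             gfp_wt = gfp_wt, gfp_x = gfp_x, gfp_msn24 = gfp_msn24,
             gfp_x_msn24 = gfp_x_msn24, stringsAsFactors = FALSE)
}

#' Dependence scores for all scored genes of an expression matrix
#'
#' Looks up, per condition, the wild type, the `msn2:msn4` double and each
#' gene's single and triple mutants and evaluates [dependence_score()].
#' Genes whose triple-mutant strain is absent are skipped.
#'
#' @param mat an `"expression_matrix"` whose rownames follow [strain_id()]
#'   conventions.
#' @param genes genes to score (default: every gene with a triple present).
#' @param conditions conditions to score (default: all).
#' @param ... passed to [dependence_score()].
#' @return data frame: gene, condition, d, regime and the four inputs.
#' @export
dependence_table <- function(mat, genes = NULL,
                             conditions = colnames(mat$values), ...) {
  stopifnot(inherits(mat, "expression_matrix"))
  rn <- rownames(mat$values)
  if (is.null(genes)) {
    singles <- rn[!grepl(":", rn) & !rn %in% c(mat$wt_strain, "noGFP")]
    genes <- singles[vapply(singles, function(g)
      strain_id(c(g, "msn2", "msn4")) %in% rn, logical(1))]
    genes <- setdiff(genes, c("msn2", "msn4"))
  }
  msn24 <- strain_id(c("msn2", "msn4"))
  if (!msn24 %in% rn) stop("matrix lacks the msn2:msn4 double mutant")
  out <- list()
  for (cond in conditions) {
    for (g in genes) {
      triple <- strain_id(c(g, "msn2", "msn4"))
      if (!g %in% rn || !triple %in% rn) next
      row <- dependence_score(mat$wt[[cond]],
                              mat$values[g, cond],
                              mat$values[msn24, cond],
                              mat$values[triple, cond], ...)
      row <- cbind(data.frame(gene = g, condition = cond,
                              stringsAsFactors = FALSE), row)
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
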