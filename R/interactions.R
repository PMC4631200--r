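# Genetic-interaction models over the double-knockout matrix. Each single
# knockout has a total effect F = GFP_dX - GFP_WT and a multiplicative ratio
# M = GFP_dX / GFP_WT. The neutral expectations for a double are:
#   additive        WT + F_X + F_Y
#   multiplicative  WT * M_X * M_Y
#   combined        WT * m_X * m_Y + a_X + a_Y,
# the combined components constrained per gene by
#   a_X + WT * (m_X - 1) = F_X,
# so that each knockout's additive and multiplicative parts sum to its
# measured total effect. Substituting the constraint leaves an unconstrained
# bilinear least-squares problem in u = m - 1:
#   observed - additive_expectation = WT * u_X * u_Y + residual,
# solved by bounded Levenberg-Marquardt with an analytic Jacobian from
# three starts (additive, multiplicative, midpoint).

# Collect the doubles of the matrix for one condition, with single lookups.
collect_pairs <- function(mat, condition, pairs = NULL) {
  rn <- rownames(mat$values)
  if (is.null(pairs)) {
    doubles <- rn[vapply(rn, function(s) length(genotype_of(s)) == 2, logical(1))]
    pairs <- do.call(rbind, lapply(doubles, genotype_of))
  }
  pairs <- as.matrix(pairs)
  keep <- logical(nrow(pairs))
  obs <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    dbl <- strain_id(pairs[i, ])
    keep[i] <- all(c(pairs[i, ], dbl) %in% rn) &&
      is.finite(mat$values[dbl, condition]) &&
      all(is.finite(mat$values[pairs[i, ], condition]))
    if (keep[i]) obs[i] <- mat$values[dbl, condition]
  }
  list(pairs = pairs[keep, , drop = FALSE], observed = obs[keep],
       skipped = sum(!keep))
}

#' Single-knockout components for one condition
#'
#' @param mat an `"expression_matrix"`.
#' @param condition condition name.
#' @param genes genes to tabulate (default: all single-knockout rows).
#' @return data frame: gene, gfp, `f` (additive total effect, a.u.) and
#'   `m_ratio` (multiplicative ratio).
#' @export
knockout_components <- function(mat, condition, genes = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  rn <- rownames(mat$values)
  if (is.null(genes)) {
    genes <- rn[!grepl(":", rn) & !rn %in% c(mat$wt_strain, "noGFP")]
  }
  wt <- mat$wt[[condition]]
  if (!is.finite(wt) || wt <= 0) stop("WT value must be positive")
  gfp <- mat$values[genes, condition]
  data.frame(gene = genes, gfp = unname(gfp), f = unname(gfp - wt),
             m_ratio = unname(gfp / wt), stringsAsFactors = FALSE)
}

#' Fraction of double-knockout variance explained
#'
#' `1 - sum((obs - exp)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,expected numeric vectors over the same pairs (>= 2).
#' @return R squared (dimensionless; can be negative for a bad model).
#' @export
variance_explained <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) stop("zero variance among observed doubles")
  1 - sum((observed - expected)^2) / sstot
}

finish_fit <- function(model, mat, condition, pc, expected, comp, extra = list()) {
  score <- pc$observed - expected
  wt <- mat$wt[[condition]]
  fit <- c(list(
    model = model, condition = condition,
    pairs = data.frame(gene_x = pc$pairs[, 1], gene_y = pc$pairs[, 2],
                       observed = pc$observed, expected = expected,
                       score = score, norm_score = score / wt,
                       stringsAsFactors = FALSE),
    components = comp,
    r2 = if (length(pc$observed) >= 2 &&
               stats::var(pc$observed) > 0)
      variance_explained(pc$observed, expected) else NA_real_,
    sse = sum(score^2),
    n_pairs = length(score),
    n_skipped = pc$skipped,
    wt = wt), extra)
  class(fit) <- "interaction_fit"
  fit
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("%s interaction model [%s]: %d doubles, R^2 = %.3f\n",
              x$model, x$condition, x$n_pairs, x$r2))
  invisible(x)
}

#' Fit the additive interaction model
#'
#' Expected double value `WT + F_X + F_Y`; the interaction score of a pair
#' is observed minus expected.
#'
#' @param mat an `"expression_matrix"` with [strain_id()] rownames.
#' @param condition condition name.
#' @param pairs optional two-column gene-pair table (default: all doubles
#'   present; pairs lacking a single are skipped).
#' @return an `"interaction_fit"`.
#' @export
fit_additive <- function(mat, condition, pairs = NULL) {
  pc <- collect_pairs(mat, condition, pairs)
  comp <- knockout_components(mat, condition,
                              genes = unique(c(pc$pairs)))
  wt <- mat$wt[[condition]]
  f <- stats::setNames(comp$f, comp$gene)
  expected <- wt + f[pc$pairs[, 1]] + f[pc$pairs[, 2]]
  finish_fit("additive", mat, condition, pc, unname(expected), comp)
}

#' Fit the multiplicative interaction model
#'
#' Expected double value `WT * M_X * M_Y`.
#'
#' @inheritParams fit_additive
#' @return an `"interaction_fit"`.
#' @export
fit_multiplicative <- function(mat, condition, pairs = NULL) {
  pc <- collect_pairs(mat, condition, pairs)
  comp <- knockout_components(mat, condition, genes = unique(c(pc$pairs)))
  wt <- mat$wt[[condition]]
  m <- stats::setNames(comp$m_ratio, comp$gene)
  expected <- wt * m[pc$pairs[, 1]] * m[pc$pairs[, 2]]
  finish_fit("multiplicative", mat, condition, pc, unname(expected), comp)
}

#' Fit the combined additive + multiplicative interaction model
#'
#' Decomposes each knockout's measured total effect into an additive part
#' `a` and a multiplicative part `m` under the per-gene sum constraint
#' `a + WT * (m - 1) = F`, by minimizing the squared differences between
#' observed doubles and `WT * m_X * m_Y + a_X + a_Y`. The constraint is
#' substituted, leaving a bounded bilinear least-squares problem in
#' `u = m - 1` solved by Levenberg-Marquardt from three starts (additive
#' `u = 0`, multiplicative `u = M - 1`, and their midpoint); the best
#' solution wins, which also guarantees the combined fit never does worse
#' than either nested model. Genes appearing in no double keep the
#' additive solution (`a = F`, `m = 1`) and are flagged.
#'
#' @inheritParams fit_additive
#' @param m_bounds bounds on the multiplicative component.
#' @param control `minpack.lm::nls.lm.control()` settings.
#' @return an `"interaction_fit"` whose `components` carry `a`, `m`, the
#'   constraint residual, and a `no_doubles` flag; `diagnostics` records
#'   the start used and optimizer status.
#' @export
fit_combined <- function(mat, condition, pairs = NULL, m_bounds = c(0, 10),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-15, ptol = 1e-15)) {
  pc <- collect_pairs(mat, condition, pairs)
  if (nrow(pc$pairs) < 1) stop("no doubles available to fit")
  genes <- sort(unique(c(pc$pairs)))
  comp <- knockout_components(mat, condition, genes = genes)
  wt <- mat$wt[[condition]]
  f <- stats::setNames(comp$f, comp$gene)
  ix <- match(pc$pairs[, 1], genes)
  iy <- match(pc$pairs[, 2], genes)
  # residual target: observed minus the additive expectation
  d <- pc$observed - (wt + f[pc$pairs[, 1]] + f[pc$pairs[, 2]])
  d <- unname(d)

  # pad with structural zero residuals when doubles are fewer than genes
  # (the underdetermined case): Levenberg-Marquardt needs >= as many
  # residuals as parameters, and zero rows leave the objective unchanged
  n_pad <- max(0, length(genes) - length(d))
  resid_fn <- function(u) c(d - wt * u[ix] * u[iy], numeric(n_pad))
  jac_fn <- function(u) {
    J <- matrix(0, length(d) + n_pad, length(u))
    J[cbind(seq_along(d), ix)] <- J[cbind(seq_along(d), ix)] - wt * u[iy]
    J[cbind(seq_along(d), iy)] <- J[cbind(seq_along(d), iy)] - wt * u[ix]
    J
  }

  u_mult <- pmin(pmax(stats::setNames(comp$m_ratio, comp$gene)[genes] - 1,
                      m_bounds[1] - 1), m_bounds[2] - 1)
  starts <- list(additive = rep(0, length(genes)),
                 multiplicative = unname(u_mult),
                 midpoint = unname(u_mult) / 2)

  best <- NULL
  notes <- character(0)
  for (s in names(starts)) {
    # optimizer chatter (e.g. maxiter on flat solution manifolds of
    # degenerate pure-model data) goes to diagnostics, not the console
    fit <- withCallingHandlers(
      minpack.lm::nls.lm(par = starts[[s]], fn = resid_fn, jac = jac_fn,
                         lower = rep(m_bounds[1] - 1, length(genes)),
                         upper = rep(m_bounds[2] - 1, length(genes)),
                         control = control),
      warning = function(w) {
        notes <<- c(notes, sprintf("%s: %s", s, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    sse <- sum(resid_fn(fit$par)^2)
    if (!is.finite(sse)) next
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(par = fit$par, sse = sse, start = s, info = fit$info,
                   message = fit$message, niter = fit$niter)
    }
  }
  if (is.null(best)) stop("combined-model optimization failed to converge")

  u <- best$par
  comp$m <- 1 + u
  comp$a <- comp$f - wt * u
  comp$constraint_residual <- comp$a + wt * (comp$m - 1) - comp$f
  comp$no_doubles <- FALSE

  # genes of the matrix absent from every double: additive fallback
  all_singles <- knockout_components(mat, condition)
  lone <- setdiff(all_singles$gene, genes)
  if (length(lone)) {
    lone_rows <- all_singles[all_singles$gene %in% lone, ]
    lone_rows$m <- 1
    lone_rows$a <- lone_rows$f
    lone_rows$constraint_residual <- 0
    lone_rows$no_doubles <- TRUE
    comp <- rbind(comp, lone_rows)
  }

  expected <- wt * (1 + u[ix]) * (1 + u[iy]) +
    (f[pc$pairs[, 1]] - wt * u[ix]) + (f[pc$pairs[, 2]] - wt * u[iy])
  finish_fit("combined", mat, condition, pc, unname(expected), comp,
             extra = list(diagnostics = list(
               start = best$start, info = best$info, message = best$message,
               niter = best$niter, notes = notes,
               max_constraint_residual = max(abs(comp$constraint_residual)))))
}

#' Correlate combined-model components with Msn2/4 dependence
#'
#' Splits each gene's total effect `F` into its Msn2/4-dependent part
#' `D * F` and independent part `(1 - D) * F`, then reports the Pearson
#' correlation (with two-sided p-value) of the multiplicative component
#' `m` against the dependent effect and of the additive component `a`
#' against the independent effect.
#'
#' @param components the `components` data frame of a [fit_combined()]
#'   (columns gene, f, a, m).
#' @param dependence a [dependence_table()] (or any data frame with gene,
#'   condition, d) for the same matrix.
#' @param condition condition to correlate in.
#' @return data frame with rows `multiplicative_vs_dependent` and
#'   `additive_vs_independent`: `r`, `p`, `n`.
#' @export
component_dependence_correlation <- function(components, dependence,
                                             condition) {
  dep <- dependence[dependence$condition == condition & !is.na(dependence$d), ]
  common <- intersect(components$gene, dep$gene)
  if (length(common) < 3) stop("need >= 3 genes with both quantities defined")
  ci <- match(common, components$gene)
  di <- match(common, dep$gene)
  f <- components$f[ci]
  dep_effect <- dep$d[di] * f
  indep_effect <- (1 - dep$d[di]) * f
  one <- function(x, y, label) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance")
    ct <- stats::cor.test(x, y)
    data.frame(pair = label, r = unname(ct$estimate), p = ct$p.value,
               n = length(x), stringsAsFactors = FALSE)
  }
  rbind(one(components$m[ci], dep_effect, "multiplicative_vs_dependent"),
        one(components$a[ci], indep_effect, "additive_vs_independent"))
}
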