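# Shared builders for synthetic screens used across test files.

# Evaluate `code` under a fixed seed without disturbing the outer RNG.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Truth table with degenerate (pinned) component values for analytic tests.
pinned_truth <- function(genes, conditions, m = 1, a = 0, d_frac = 0.5,
                         baseline = 100, seed = 1, ...) {
  cfg <- truth_config(m_range = c(m, m), a_frac_range = c(a, a) / baseline,
                      d_frac_range = c(d_frac, d_frac),
                      baseline_range = c(baseline, baseline), ...)
  make_truth(genes, conditions, cfg, seed = seed)
}

# Standard query x target screen: strain ids and the unordered pair list.
# Queries are included in the target set, so the pair graph contains
# triangles and the combined-model decomposition is identifiable.
screen_design <- function(n_query = 8, n_extra_target = 6) {
  queries <- sprintf("q%02d", seq_len(n_query))
  targets <- c(queries, sprintf("t%02d", seq_len(n_extra_target)))
  pairs <- do.call(rbind, lapply(queries, function(q)
    do.call(rbind, lapply(setdiff(targets, q), function(t) c(q, t)))))
  pairs <- unique(t(apply(pairs, 1, sort)))
  list(queries = queries, targets = targets, pairs = pairs,
       strains = c("WT", targets, apply(pairs, 1, strain_id)))
}

# Truth for a screen whose Msn2/4-dependent fraction matches each gene's
# multiplicative share of its total effect, so dependence decomposition and
# combined-model components are generatively linked.
matched_truth <- function(genes, condition = "KCl", seed = 1) {
  tr <- make_truth(c(genes, "msn2", "msn4"), condition,
                   truth_config(m_range = c(0.5, 2.5),
                                a_frac_range = c(-0.2, 0.4),
                                baseline_range = c(200, 200)),
                   seed = seed)
  b <- tr$conditions$wt_baseline[1]
  idx <- tr$effects$gene %in% genes
  f_tot <- tr$effects$a[idx] + b * (tr$effects$m[idx] - 1)
  share <- ifelse(abs(f_tot) > 1e-8, b * (tr$effects$m[idx] - 1) / f_tot, 0.5)
  tr$effects$d_frac[idx] <- pmin(pmax(share, -0.5), 1.5)
  tr
}
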