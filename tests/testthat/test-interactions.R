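# Additive, multiplicative and combined genetic-interaction models.

# matrix for WT=100, X=150, Y=80 with a configurable double value
toy_matrix <- function(xy, condition = "heat") {
  v <- matrix(c(100, 150, 80, xy), ncol = 1,
              dimnames = list(c("WT", "x", "y", strain_id(c("x", "y"))),
                              condition))
  expression_matrix(v)
}

test_that("additive and multiplicative expectations match hand arithmetic", {
  add <- fit_additive(toy_matrix(130), "heat")
  expect_equal(add$pairs$expected, 130)
  expect_equal(add$pairs$score, 0)  # observed equals expected: no interaction

  mult <- fit_multiplicative(toy_matrix(120), "heat")
  expect_equal(mult$pairs$expected, 100 * 1.5 * 0.8)
  expect_equal(mult$pairs$score, 0)

  # a gene with M = 1 leaves every partner's value unchanged
  v <- matrix(c(100, 100, 80, 80), ncol = 1,
              dimnames = list(c("WT", "x", "y", strain_id(c("x", "y"))), "heat"))
  m1 <- fit_multiplicative(expression_matrix(v), "heat")
  expect_equal(m1$pairs$expected, 80)
})

test_that("variance explained matches an independent brute-force computation", {
  expect_equal(variance_explained(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(variance_explained(c(1, 2, 3), rep(2, 3)), 0)
  obs <- with_seed_local(1, rnorm(10, 100, 20))
  exp_v <- with_seed_local(2, obs + rnorm(10, 0, 5))
  brute <- 1 - sum((obs - exp_v)^2) / sum((obs - mean(obs))^2)
  expect_equal(variance_explained(obs, exp_v), brute)
  expect_error(variance_explained(rep(1, 3), rep(1, 3)), "zero variance")
})

test_that("purely additive or multiplicative screens are fit exactly", {
  des <- screen_design(6, 4)
  # additive truth: m = 1 everywhere
  tr_add <- pinned_truth(des$targets, "heat", m = 1, a = 0, baseline = 200)
  tr_add$effects$a <- with_seed_local(3, runif(nrow(tr_add$effects), -40, 80))
  mat_add <- truth_matrix(tr_add, des$strains, "heat")
  f_add <- fit_additive(mat_add, "heat", pairs = des$pairs)
  expect_equal(f_add$r2, 1)
  expect_equal(max(abs(f_add$pairs$score)), 0, tolerance = 1e-9)

  # multiplicative truth: a = 0 everywhere
  tr_mul <- pinned_truth(des$targets, "heat", m = 1, a = 0, baseline = 200)
  tr_mul$effects$m <- with_seed_local(4, runif(nrow(tr_mul$effects), 0.4, 2.5))
  mat_mul <- truth_matrix(tr_mul, des$strains, "heat")
  f_mul <- fit_multiplicative(mat_mul, "heat", pairs = des$pairs)
  expect_equal(f_mul$r2, 1)

  # the combined fit collapses onto the true nested model
  c_add <- fit_combined(mat_add, "heat", pairs = des$pairs)
  expect_equal(c_add$r2, f_add$r2, tolerance = 1e-6)
  c_mul <- fit_combined(mat_mul, "heat", pairs = des$pairs)
  fitted_m <- c_mul$components$m[match(des$targets, c_mul$components$gene)]
  true_m <- tr_mul$effects$m[match(des$targets, tr_mul$effects$gene)]
  expect_equal(fitted_m, true_m, tolerance = 1e-6)
})

test_that("the combined model recovers mixed components from noiseless doubles", {
  des <- screen_design(8, 6)
  tr <- make_truth(des$targets, "KCl",
                   truth_config(m_range = c(0.3, 3),
                                a_frac_range = c(-0.3, 0.5)), seed = 21)
  mat <- truth_matrix(tr, des$strains, "KCl")
  fit <- fit_combined(mat, "KCl", pairs = des$pairs)
  comp <- fit$components[!fit$components$no_doubles, ]
  true_m <- tr$effects$m[match(comp$gene, tr$effects$gene)]
  true_a <- tr$effects$a[match(comp$gene, tr$effects$gene)]
  expect_equal(comp$m, true_m, tolerance = 1e-6)
  expect_equal(comp$a, true_a, tolerance = 1e-4)
  expect_lt(max(abs(fit$pairs$score)), 1e-6 * mat$wt[["KCl"]])
  # sum constraint holds to optimizer tolerance
  expect_lt(fit$diagnostics$max_constraint_residual, 1e-8 * mat$wt[["KCl"]])
})

test_that("combined expectation decomposes into the additive part plus WT (m-1)(m-1)", {
  des <- screen_design(5, 3)
  tr <- make_truth(des$targets, "heat", seed = 9)
  mat <- simulate_screen_matrix(tr, des$strains, "heat", cv = 0.05, seed = 2)
  fit <- fit_combined(mat, "heat", pairs = des$pairs)
  add <- fit_additive(mat, "heat", pairs = des$pairs)
  wt <- mat$wt[["heat"]]
  m <- setNames(fit$components$m, fit$components$gene)
  lhs <- fit$pairs$expected
  rhs <- add$pairs$expected +
    wt * (m[fit$pairs$gene_x] - 1) * (m[fit$pairs$gene_y] - 1)
  expect_equal(lhs, unname(rhs), tolerance = 1e-10)
})

test_that("nesting: the combined fit never does worse than either pure model", {
  des <- screen_design(5, 4)
  for (seed in 1:6) {
    tr <- make_truth(des$targets, "heat", seed = seed)
    mat <- simulate_screen_matrix(tr, des$strains, "heat", cv = 0.05,
                                  seed = seed + 100)
    sse_c <- fit_combined(mat, "heat", pairs = des$pairs)$sse
    sse_a <- fit_additive(mat, "heat", pairs = des$pairs)$sse
    sse_m <- fit_multiplicative(mat, "heat", pairs = des$pairs)$sse
    expect_lte(sse_c, min(sse_a, sse_m) + 1e-6)
  }
})

test_that("genes with no doubles fall back to the additive solution", {
  v <- matrix(c(100, 150, 80, 130, 220), ncol = 1,
              dimnames = list(c("WT", "x", "y", strain_id(c("x", "y")), "z"),
                              "heat"))
  fit <- fit_combined(expression_matrix(v), "heat")
  z <- fit$components[fit$components$gene == "z", ]
  expect_true(z$no_doubles)
  expect_equal(z$m, 1)
  expect_equal(z$a, 120)
})

test_that("component-dependence correlations behave on constructed data", {
  # perfectly linear relation
  comp <- data.frame(gene = letters[1:6], f = c(10, 20, 30, 40, 50, 60),
                     m = 1 + (1:6) / 10, a = (1:6) * 5)
  dep <- data.frame(gene = letters[1:6], condition = "KCl",
                    d = seq(0.2, 0.7, by = 0.1))
  dep$d <- (comp$m - 1) * 10 / comp$f * 10  # dependent effect proportional to m
  res <- component_dependence_correlation(comp, dep, "KCl")
  expect_equal(res$r[res$pair == "multiplicative_vs_dependent"], 1,
               tolerance = 1e-9)

  # shuffling the pairing destroys the correlation
  dep_shuf <- dep
  dep_shuf$d <- with_seed_local(8, sample(dep$d))
  comp2 <- data.frame(gene = sprintf("g%d", 1:30),
                      f = with_seed_local(1, runif(30, 20, 120)))
  comp2$m <- 1 + with_seed_local(2, runif(30, -0.5, 1.5))
  comp2$a <- with_seed_local(3, runif(30, -30, 60))
  dep2 <- data.frame(gene = comp2$gene, condition = "KCl",
                     d = comp2$f * 0 + (comp2$m - 1) * 100 / comp2$f)
  dep2$d <- with_seed_local(9, sample(dep2$d))
  res2 <- component_dependence_correlation(comp2, dep2, "KCl")
  expect_gt(min(res2$p), 0.05)
  expect_error(component_dependence_correlation(comp[1:2, ], dep, "KCl"),
               ">= 3")
})
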