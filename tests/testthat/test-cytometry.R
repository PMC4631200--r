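# Event stream -> expression matrix: demultiplexing, gating, medians,
# autofluorescence correction, replicate averaging.

test_that("partition_wells recovers simulated well boundaries", {
  tr <- make_truth(c("g1", "g2"), "heat", seed = 1)
  layout <- plate_layout(c("WT", "g1", "g2"), "heat", 1)
  st <- simulate_plate_stream(layout, tr, events_per_well = 100,
                              gap_seconds = 5, seed = 3, spacing = 0.01)
  assign <- partition_wells(st, 3)
  expect_equal(as.vector(table(assign)), c(100, 100, 100))
  # hidden labels recovered exactly
  expect_equal(as.integer(factor(st$well, levels = unique(st$well))),
               as.integer(assign))
})

test_that("partition_wells handles degenerate inputs per contract", {
  ev <- data.frame(time = 1:10)
  expect_equal(as.integer(partition_wells(ev, 1)), rep(1L, 10))
  # uniform spacing: a valid 2-partition at the earliest largest spacing
  a2 <- partition_wells(ev, 2)
  expect_equal(as.integer(a2), c(1L, rep(2L, 9)))
  expect_equal(attr(a2, "boundaries"), 1L)
  # fewer events than wells: trailing wells empty
  a5 <- partition_wells(data.frame(time = c(0, 10)), 5)
  expect_equal(as.integer(a5), c(1L, 2L))
  expect_error(partition_wells(data.frame(time = c(3, 1, 2)), 2), "sorted")
})

test_that("partition_wells is invariant to time shift and positive scaling", {
  for (seed in 1:5) {
    t <- with_seed_local(seed, sort(runif(200, 0, 100)))
    ev <- data.frame(time = t)
    base <- as.integer(partition_wells(ev, 7))
    expect_identical(as.integer(partition_wells(data.frame(time = t + 55.5), 7)),
                     base)
    expect_identical(as.integer(partition_wells(data.frame(time = t * 3.7), 7)),
                     base)
  }
})

test_that("the density gate keeps the dense cloud and drops outliers", {
  tr <- make_truth("g1", "heat", seed = 2)
  dense <- simulate_event_table("WT", "heat", tr, 1000, seed = 5,
                                outlier_fraction = 0)
  out <- simulate_event_table("WT", "heat", tr, 100, seed = 6,
                              outlier_fraction = 1)
  ev <- rbind(dense, out)
  gated <- gate_events(ev, retain_fraction = 0.9, resolution = 64)
  expect_equal(attr(gated, "n_retained"), 990, tolerance = 0.03)
  # the gate removes nearly all outliers while sparing the cell cloud:
  # at 990/1100 retained, ~10 removed events are necessarily dense-cloud
  # cells, so removal purity is bounded near 100/110
  outlier_recall <- (sum(ev$is_outlier) - sum(gated$is_outlier)) /
    sum(ev$is_outlier)
  expect_gte(outlier_recall, 0.95)
  dense_removed <- sum(!ev$is_outlier) - sum(!gated$is_outlier)
  expect_lte(dense_removed, 15)
})

test_that("gate edge cases: full retention, point mass, realized fraction bound", {
  ev <- data.frame(fsc = rnorm(500, 5e4, 3e3), ssc = rnorm(500, 3e4, 2e3),
                   gfp = rlnorm(500, 5, 0.3))
  g1 <- gate_events(ev, retain_fraction = 1)
  expect_equal(nrow(g1), 500)

  point <- data.frame(fsc = rep(1, 50), ssc = rep(1, 50), gfp = rep(2, 50))
  expect_equal(nrow(gate_events(point, 0.5, 64)), 50)

  for (rf in c(0.5, 0.75, 0.9)) {
    g <- gate_events(ev, rf, 32)
    expect_gte(attr(g, "realized_fraction"), rf)
    # overshoot bounded by one bin's mass
    bins <- table(cut(ev$fsc, 32), cut(ev$ssc, 32))
    expect_lte(attr(g, "realized_fraction"), rf + max(bins) / nrow(ev))
  }
  expect_error(gate_events(ev, 1.5), "retain_fraction")
  expect_error(gate_events(ev[0, ], 0.9), "empty")
})

test_that("well medians are exact order statistics", {
  expect_equal(well_median_gfp(data.frame(gfp = c(1, 2, 3))), 2)
  expect_equal(well_median_gfp(data.frame(gfp = c(1, 2, 3, 10))), 2.5)
  expect_true(is.na(well_median_gfp(data.frame(gfp = numeric(0)))))
  # log-normal sample median approaches the analytic median exp(meanlog)
  x <- with_seed_local(1, rlnorm(10000, meanlog = log(200), sdlog = 0.3))
  expect_lt(abs(well_median_gfp(data.frame(gfp = x)) - 200) / 200, 0.02)
})

test_that("autofluorescence correction subtracts and clips", {
  expect_equal(correct_autofluorescence(120, 20), 100)
  expect_equal(correct_autofluorescence(15, 20), 0)
  expect_equal(correct_autofluorescence(7.5, 0), 7.5)
})

test_that("replicate averaging and reproducibility behave analytically", {
  wells <- data.frame(strain = c("WT", "WT"), condition = "heat",
                      replicate = 1:2, median_gfp = c(100, 110))
  mat <- aggregate_replicates(wells)
  expect_equal(unname(mat$values["WT", "heat"]), 105)

  # identical replicate vectors correlate perfectly
  base <- data.frame(strain = c("WT", "a", "b", "c"), condition = "heat",
                     median_gfp = c(100, 150, 80, 230))
  wells2 <- rbind(transform(base, replicate = 1), transform(base, replicate = 2))
  mat2 <- aggregate_replicates(wells2)
  expect_equal(mat2$reproducibility$pearson_log, 1)

  # two replicates at 5% CV over 1,566 strains reproduce tightly
  n <- 1566
  meds <- with_seed_local(3, exp(rnorm(n, log(100), 0.6)))
  noisy <- function(seed) with_seed_local(seed, meds * exp(rnorm(n, 0, 0.05)))
  wells3 <- rbind(
    data.frame(strain = c("WT", sprintf("s%d", 1:(n - 1))), condition = "heat",
               replicate = 1, median_gfp = noisy(4)),
    data.frame(strain = c("WT", sprintf("s%d", 1:(n - 1))), condition = "heat",
               replicate = 2, median_gfp = noisy(5)))
  mat3 <- aggregate_replicates(wells3)
  expect_gte(mat3$reproducibility$pearson_log, 0.95)

  expect_error(aggregate_replicates(transform(base, replicate = 1,
                                              strain = letters[1:4])), "WT")
})

test_that("the full chain recovers expected levels within replicate noise", {
  genes <- sprintf("g%d", 1:6)
  cfg <- truth_config(m_range = c(0.5, 2), a_frac_range = c(0, 0.3),
                      replicate_cv = 0.05)
  tr <- make_truth(genes, "heat", cfg, seed = 10)
  strains <- c("WT", "noGFP", genes, strain_id(c("g1", "g2")),
               strain_id(c("g3", "g4")))
  n_reps <- 2
  wells <- list()
  for (r in seq_len(n_reps)) {
    layout <- plate_layout(strains, "heat", r)
    st <- simulate_plate_stream(layout, tr, events_per_well = 500,
                                gap_seconds = 5, seed = 100 + r)
    wells[[r]] <- measure_wells(st, layout)
  }
  mat <- aggregate_replicates(correct_wells(do.call(rbind, wells)))
  tol <- 3 * (0.05 / sqrt(n_reps))
  for (s in setdiff(strains, "noGFP")) {
    expected <- max(expected_gfp(genotype_of(s), "heat", tr), 0)
    expect_lt(abs(mat$values[s, "heat"] - expected) / expected, tol,
              label = sprintf("chain error for %s", s))
  }
})
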