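# Generative model: truth tables, expected reporter levels, event and
# stream simulation, localization pulses.

test_that("make_truth validates inputs and samples inside the stated ranges", {
  expect_error(make_truth(character(0), "heat"), "at least one gene")
  expect_error(make_truth("g1", character(0)), "at least one condition")
  expect_error(truth_config(baseline_range = c(-1, 10)), "positive")
  expect_error(make_truth(c("WT", "g1"), "heat"), "reserved")

  cfg <- truth_config(m_range = c(0.3, 3), a_frac_range = c(-0.3, 0.5))
  tr <- make_truth(sprintf("g%02d", 1:86), letters[1:5], cfg, seed = 7)
  expect_equal(nrow(tr$effects), 86 * 5)
  expect_equal(nrow(tr$conditions), 5)
  expect_true(all(tr$effects$m >= 0.3 & tr$effects$m <= 3))
  base <- tr$conditions$wt_baseline[match(tr$effects$condition,
                                          tr$conditions$condition)]
  expect_true(all(tr$effects$a >= -0.3 * base & tr$effects$a <= 0.5 * base))
  expect_true(all(tr$conditions$wt_baseline > 0))
})

test_that("truth tables are byte-identical under the same seed", {
  tr1 <- make_truth(sprintf("g%02d", 1:86), letters[1:5], seed = 7)
  tr2 <- make_truth(sprintf("g%02d", 1:86), letters[1:5], seed = 7)
  expect_identical(tr1, tr2)
  tr3 <- make_truth(sprintf("g%02d", 1:86), letters[1:5], seed = 8)
  expect_false(identical(tr1$effects$m, tr3$effects$m))
})

test_that("expected_gfp implements the combined composition rule", {
  # identity perturbation: m = 1, a = 0 leaves the baseline untouched
  tr0 <- pinned_truth("g1", "heat", m = 1, a = 0)
  expect_equal(expected_gfp("g1", "heat", tr0), 100)
  expect_equal(expected_gfp("WT", "heat", tr0), 100)
  expect_equal(expected_gfp(character(0), "heat", tr0), 100)
  expect_equal(expected_gfp("noGFP", "heat", tr0), 0)

  tr <- pinned_truth("g1", "heat", m = 1.5, a = 0)
  expect_equal(expected_gfp("g1", "heat", tr), 150)

  # doubles compose as baseline * m1 * m2 + a1 + a2
  tr2 <- pinned_truth(c("g1", "g2"), "heat", m = 1.5, a = 10)
  expect_equal(expected_gfp(c("g1", "g2"), "heat", tr2),
               100 * 1.5 * 1.5 + 20)
  expect_error(expected_gfp("nope", "heat", tr2), "unknown")
})

test_that("a fully Msn2/4-dependent knockout's triple equals the msn2 msn4 double", {
  tr <- pinned_truth(c("g1", "msn2", "msn4"), "heat", m = 2, a = 30, d_frac = 1)
  msn24 <- expected_gfp(c("msn2", "msn4"), "heat", tr)
  expect_equal(msn24, 0.2 * 100)  # residual fraction of wild type
  expect_equal(expected_gfp(c("g1", "msn2", "msn4"), "heat", tr), msn24)
  # partially dependent: independent part of the effect persists
  tr05 <- pinned_truth(c("g1", "msn2", "msn4"), "heat", m = 2, a = 30,
                       d_frac = 0.5)
  f_total <- 30 + 100 * (2 - 1)
  expect_equal(expected_gfp(c("g1", "msn2", "msn4"), "heat", tr05),
               20 + 0.5 * f_total)
  # msn2 alone is an ordinary knockout from the table
  expect_equal(expected_gfp("msn2", "heat", tr05), 100 * 2 + 30)
  # KCl-like conditions carry the larger residual baseline
  trk <- pinned_truth("g1", "KCl", m = 1, a = 0)
  expect_equal(trk$conditions$msn24_residual, 0.3)
})

test_that("injected interactions shift only the co-deleted genotype", {
  tr <- pinned_truth(c("g1", "g2", "g3"), "heat", m = 1.2, a = 5)
  neutral <- expected_gfp(c("g1", "g2"), "heat", tr)
  tr <- inject_interaction(tr, "g1", "g2", "heat", delta = 33)
  expect_equal(expected_gfp(c("g1", "g2"), "heat", tr), neutral + 33)
  expect_equal(expected_gfp(c("g1", "g3"), "heat", tr),
               100 * 1.2 * 1.2 + 10)
})

test_that("simulated event tables match their analytic medians", {
  tr <- make_truth("g1", "heat", seed = 2)
  offset <- tr$conditions$autofluorescence
  ev <- simulate_event_table("WT", "heat", tr, 5000, seed = 1)
  expect_equal(nrow(ev), 5000)
  exp_med <- offset + expected_gfp("WT", "heat", tr)
  expect_lt(abs(median(ev$gfp) - exp_med) / exp_med, 0.05)
  expect_false(is.unsorted(ev$time, strictly = TRUE))

  ctrl <- simulate_event_table("noGFP", "heat", tr, 5000, seed = 1)
  expect_lt(abs(median(ctrl$gfp) - offset) / offset, 0.05)

  # convergence: single-KO median approaches expected_gfp at large n
  big <- simulate_event_table("g1", "heat", tr, 50000, seed = 3)
  exp_big <- offset + expected_gfp("g1", "heat", tr)
  expect_lt(abs(median(big$gfp) - exp_big) / exp_big, 0.02)

  expect_identical(simulate_event_table("g1", "heat", tr, 100, seed = 9),
                   simulate_event_table("g1", "heat", tr, 100, seed = 9))
  expect_error(simulate_event_table("g1", "heat", tr, 0), "n_events")
})

test_that("zero outlier fraction keeps all events inside the dense ellipse", {
  tr <- make_truth("g1", "heat", seed = 2)
  ev <- simulate_event_table("WT", "heat", tr, 2000, seed = 4,
                             outlier_fraction = 0)
  d2 <- stressGI:::scatter_mahalanobis2(ev$fsc, ev$ssc)
  expect_true(all(d2 <= qchisq(0.999, df = 2)))
  expect_false(any(ev$is_outlier))
})

test_that("plate streams are ordered bursts separated by the configured gap", {
  tr <- make_truth(c("g1", "g2"), "heat", seed = 2)
  layout <- plate_layout(c("WT", "g1", "g2"), "heat", 1)
  st <- simulate_plate_stream(layout, tr, events_per_well = 100,
                              gap_seconds = 5, seed = 1, spacing = 0.01)
  expect_equal(nrow(st), 300)
  expect_false(is.unsorted(st$time))
  big_gaps <- which(diff(st$time) >= 5)
  expect_equal(length(big_gaps), 2)
  expect_equal(as.vector(table(st$well)[unique(st$well)]), c(100, 100, 100))

  # a full 96-well plate keeps monotone time and 96 bursts
  strains <- c("WT", "noGFP", sprintf("s%02d", 1:94))
  tr96 <- make_truth(sprintf("s%02d", 1:94), "heat", seed = 3)
  layout96 <- plate_layout(strains, "heat", 1)
  st96 <- simulate_plate_stream(layout96, tr96, events_per_well = 20,
                                gap_seconds = 5, seed = 1)
  expect_false(is.unsorted(st96$time))
  expect_equal(length(unique(st96$well)), 96)
  expect_error(simulate_plate_stream(layout, tr, gap_seconds = 0.001),
               "gap_seconds")
})

test_that("localization pulses follow their configured shape", {
  tps <- seq(0, 119, by = 7)
  flat <- simulate_localization_trace("WT", "KCl", tps, n_cells = 20,
                                      seed = 1, amplitude_scale = 0,
                                      noise_sd = 0)
  tr_flat <- localization_trace(flat)
  expect_equal(tr_flat$ratio, rep(1, length(tps)), tolerance = 1e-12)

  kcl <- simulate_localization_trace("WT", "KCl", tps, n_cells = 50, seed = 2)
  tr_kcl <- localization_trace(kcl)
  expect_equal(tr_kcl$time[which.max(tr_kcl$ratio)],
               tps[which.min(abs(tps - 15))])
  # KCl-like pulse returns near baseline by ~50 min
  late <- tr_kcl$ratio[tr_kcl$time >= 49][1]
  expect_lt(late, 1 + 0.25 * max(tr_kcl$ratio - 1))

  # diamide-like response stays elevated through the movie
  dia <- simulate_localization_trace("WT", "diamide", tps, n_cells = 50,
                                     seed = 2, noise_sd = 0)
  tr_dia <- localization_trace(dia)
  expect_gt(tr_dia$ratio[length(tps)], 1.5)

  expect_identical(simulate_localization_trace("WT", "KCl", tps, seed = 5),
                   simulate_localization_trace("WT", "KCl", tps, seed = 5))
  expect_error(simulate_localization_trace("WT", "KCl", c(10, 5, 20)),
               "sorted")
})
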