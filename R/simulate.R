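# Event-level simulators: cytometer event tables, timed plate streams, and
# nuclear-localization time-lapse tables. All randomness flows through the
# seed argument; internal *_impl workhorses never touch the RNG state
# themselves so composite simulators can share one stream.

# Scatter-cloud geometry. The dense cell cloud is a correlated bivariate
# normal truncated at its 99.9% Mahalanobis ellipse; outliers (debris, dead
# cells, doublets) are uniform over a box of mean +/- BOX_SD standard
# deviations per channel, the analogue of the instrument's full range.
SCATTER <- list(
  fsc_mean = 50000, fsc_sd = 1200,
  ssc_mean = 30000, ssc_sd = 700,
  # box_sd = 40 puts the cell cloud in a small region of the recorded
  # range, as on a real instrument, leaving debris genuinely sparse
  rho = 0.5, box_sd = 40,
  chisq_q = 0.995
)

# Draw n dense-cloud scatter events (truncated correlated normal).
draw_dense_scatter <- function(n) {
  lim <- stats::qchisq(SCATTER$chisq_q, df = 2)
  z1 <- numeric(n); z2 <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    a <- stats::rnorm(length(need))
    b <- stats::rnorm(length(need))
    zz2 <- SCATTER$rho * a + sqrt(1 - SCATTER$rho^2) * b
    # Mahalanobis distance of (a, zz2) under the correlated model
    d2 <- (a^2 - 2 * SCATTER$rho * a * zz2 + zz2^2) / (1 - SCATTER$rho^2)
    ok <- d2 <= lim
    z1[need[ok]] <- a[ok]
    z2[need[ok]] <- zz2[ok]
    need <- need[!ok]
  }
  data.frame(fsc = SCATTER$fsc_mean + SCATTER$fsc_sd * z1,
             ssc = SCATTER$ssc_mean + SCATTER$ssc_sd * z2)
}

draw_outlier_scatter <- function(n) {
  data.frame(
    fsc = stats::runif(n, SCATTER$fsc_mean - SCATTER$box_sd * SCATTER$fsc_sd,
                       SCATTER$fsc_mean + SCATTER$box_sd * SCATTER$fsc_sd),
    ssc = stats::runif(n, SCATTER$ssc_mean - SCATTER$box_sd * SCATTER$ssc_sd,
                       SCATTER$ssc_mean + SCATTER$box_sd * SCATTER$ssc_sd))
}

# Squared Mahalanobis distance of events from the dense-cloud centre.
scatter_mahalanobis2 <- function(fsc, ssc) {
  z1 <- (fsc - SCATTER$fsc_mean) / SCATTER$fsc_sd
  z2 <- (ssc - SCATTER$ssc_mean) / SCATTER$ssc_sd
  (z1^2 - 2 * SCATTER$rho * z1 * z2 + z2^2) / (1 - SCATTER$rho^2)
}

simulate_event_table_impl <- function(genotype, condition, truth, n_events,
                                      replicate_scale = 1,
                                      t_start = 0, spacing = 0.01,
                                      outlier_fraction = NULL) {
  # measured fluorescence cannot drop below autofluorescence: a genotype
  # whose model value is negative reads as a dark cell population
  expected <- max(expected_gfp(genotype, condition, truth) * replicate_scale, 0)
  cnd <- truth_condition(truth, condition)
  sd_cell <- truth$noise$cell_sd
  if (identical(setdiff(genotype, "WT"), "noGFP")) {
    gfp <- cnd$autofluorescence * exp(stats::rnorm(n_events, 0, sd_cell))
  } else {
    gfp <- cnd$autofluorescence +
      expected * exp(stats::rnorm(n_events, 0, sd_cell))
  }
  out_frac <- outlier_fraction %||% truth$noise$outlier_fraction
  n_out <- floor(n_events * out_frac + 0.5)
  scatter <- draw_dense_scatter(n_events)
  is_outlier <- rep(FALSE, n_events)
  if (n_out > 0) {
    idx <- sample.int(n_events, n_out)
    scatter[idx, ] <- draw_outlier_scatter(n_out)
    is_outlier[idx] <- TRUE
  }
  time <- t_start + cumsum(stats::rexp(n_events, rate = 1 / spacing))
  data.frame(fsc = scatter$fsc, ssc = scatter$ssc, gfp = gfp, time = time,
             is_outlier = is_outlier, stringsAsFactors = FALSE)
}

#' Simulate a flow-cytometry event table for one well
#'
#' Per-event GFP is the autofluorescence offset plus a log-normal draw whose
#' median equals the genotype's expected reporter level (the `noGFP` control
#' gets log-normal autofluorescence only, median equal to the offset).
#' FSC/SSC come from a dense correlated cell cloud truncated at its 99.9%
#' ellipse, with a configured fraction of uniform-box outliers; event
#' timestamps are strictly increasing.
#'
#' @param genotype character vector of deleted genes (see [expected_gfp()]).
#' @param condition condition name.
#' @param truth a [make_truth()] table.
#' @param n_events number of events (>= 1).
#' @param seed integer seed.
#' @param replicate_scale multiplicative replicate effect applied to the
#'   expected level (default 1).
#' @param t_start,spacing start time (s) and mean inter-event spacing (s).
#' @param outlier_fraction overrides the truth table's scatter outlier
#'   fraction when given.
#' @return data frame with columns `fsc`, `ssc`, `gfp`, `time` and the
#'   hidden ground-truth column `is_outlier`.
#' @export
simulate_event_table <- function(genotype, condition, truth, n_events,
                                 seed = 1, replicate_scale = 1,
                                 t_start = 0, spacing = 0.01,
                                 outlier_fraction = NULL) {
  if (n_events < 1) stop("n_events must be >= 1")
  with_seed(seed, simulate_event_table_impl(
    genotype, condition, truth, n_events,
    replicate_scale = replicate_scale, t_start = t_start, spacing = spacing,
    outlier_fraction = outlier_fraction))
}

#' Build a plate layout for a screen
#'
#' Orders one well per strain for a given condition and replicate. Strain
#' genotypes are given as strain ids (see [strain_id()]).
#'
#' @param strains character vector of strain ids (unique).
#' @param condition condition name.
#' @param replicate replicate index.
#' @param format plate format, 96 or 384 (layout must fit one plate).
#' @return data frame with columns `well`, `strain`, `condition`, `replicate`.
#' @export
plate_layout <- function(strains, condition, replicate = 1L, format = 96) {
  stopifnot(format %in% c(96, 384))
  if (anyDuplicated(strains)) stop("strain ids in a plate must be unique")
  if (length(strains) > format) {
    stop(sprintf("%d strains do not fit a %d-well plate", length(strains), format))
  }
  ncol_p <- if (format == 96) 12 else 24
  nrow_p <- format / ncol_p
  rows <- rep(LETTERS[seq_len(nrow_p)], each = ncol_p)
  cols <- rep(seq_len(ncol_p), nrow_p)
  ids <- sprintf("%s%02d", rows, cols)[seq_along(strains)]
  data.frame(well = ids, strain = strains, condition = condition,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

#' Simulate a sequentially sampled plate event stream
#'
#' Emulates an autosampler that aspirates wells in layout order and pushes
#' them to the cytometer as one continuous stream: per-well event bursts with
#' mean intra-well spacing `spacing`, separated by `gap_seconds` dead time.
#' A per-well multiplicative replicate effect `exp(N(0, cv))` models
#' between-replicate noise. Hidden truth columns (`well`, `strain`,
#' `condition`, `replicate`, `is_outlier`) are carried for testing; the
#' analysis chain uses only `fsc`, `ssc`, `gfp`, `time`.
#'
#' @param layout a [plate_layout()] (one condition/replicate per stream).
#' @param truth a [make_truth()] table.
#' @param events_per_well events per well burst.
#' @param gap_seconds inter-well time gap (s); must exceed typical intra-well
#'   spacing for demultiplexing to be possible.
#' @param seed integer seed.
#' @param spacing mean intra-well inter-event spacing (s).
#' @return event data frame for the whole stream, time strictly increasing.
#' @export
simulate_plate_stream <- function(layout, truth, events_per_well = 1000,
                                  gap_seconds = 5, seed = 1, spacing = 0.01) {
  stopifnot(nrow(layout) >= 1, events_per_well >= 1)
  if (gap_seconds <= spacing) {
    stop("gap_seconds must exceed the intra-well event spacing")
  }
  cv <- truth$noise$replicate_cv
  with_seed(seed, {
    t_clock <- 0
    parts <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      g <- genotype_of(layout$strain[i])
      scale_i <- exp(stats::rnorm(1, 0, cv))
      ev <- simulate_event_table_impl(
        g, layout$condition[i], truth, events_per_well,
        replicate_scale = scale_i, t_start = t_clock, spacing = spacing)
      ev$well <- layout$well[i]
      ev$strain <- layout$strain[i]
      ev$condition <- layout$condition[i]
      ev$replicate <- layout$replicate[i]
      parts[[i]] <- ev
      t_clock <- max(ev$time) + gap_seconds
    }
    do.call(rbind, parts)
  })
}

#' Pulse parameters for a localization trace
#'
#' Defaults are keyed by condition name: osmotic ("KCl"-like) stress gives a
#' transient nuclear pulse peaking near 15 min and returning to baseline by
#' about 45-50 min; oxidative ("diamide"-like) stress gives a lower-amplitude
#' sustained accumulation that does not return within 100 min. Other names
#' default to the pulse shape.
#'
#' @param condition condition name used to pick defaults.
#' @param baseline resting nuclear/cytoplasmic ratio.
#' @param amplitude pulse amplitude (ratio units) above baseline.
#' @param peak_minutes time of the pulse peak (pulse shape only).
#' @param shape sharpness of the gamma-like pulse (larger = faster return).
#' @param rise_minutes rise time constant (sustained shape only).
#' @param type `"pulse"` or `"sustained"`.
#' @return list of class `"loc_pulse"`.
#' @export
loc_pulse_params <- function(condition = "KCl", baseline = 1,
                             amplitude = NULL, peak_minutes = 15, shape = 3,
                             rise_minutes = 12, type = NULL) {
  diamide_like <- grepl("diamide|redox", condition, ignore.case = TRUE)
  type <- type %||% if (diamide_like) "sustained" else "pulse"
  amplitude <- amplitude %||% if (type == "sustained") 0.8 else 2
  structure(list(type = type, baseline = baseline, amplitude = amplitude,
                 peak_minutes = peak_minutes, shape = shape,
                 rise_minutes = rise_minutes),
            class = "loc_pulse")
}

pulse_ratio <- function(t, p, amplitude_scale = 1) {
  a <- p$amplitude * amplitude_scale
  if (p$type == "sustained") {
    p$baseline + a * (1 - exp(-t / p$rise_minutes))
  } else {
    x <- t / p$peak_minutes
    p$baseline + a * x^p$shape * exp(p$shape * (1 - x))
  }
}

#' Simulate a per-cell nuclear-localization time-lapse table
#'
#' Generates, per cell and timepoint, cytoplasmic and nuclear intensities
#' whose population nuclear/cytoplasmic ratio follows a configured stress
#' pulse. A mutant that abolishes nuclear accumulation is modelled with
#' `amplitude_scale = 0`.
#'
#' @param strain strain id (annotation only).
#' @param condition condition name; selects default pulse shape via
#'   [loc_pulse_params()].
#' @param timepoints sorted vector of imaging times (minutes), length >= 2.
#' @param n_cells number of cells followed.
#' @param seed integer seed.
#' @param params a [loc_pulse_params()]; defaults keyed by `condition`.
#' @param amplitude_scale scales the pulse amplitude (0 = no accumulation).
#' @param noise_sd per-cell, per-timepoint log-ratio noise (0 = noiseless).
#' @return data frame with columns `cell`, `time`, `nuclear`, `cytoplasmic`
#'   and attributes `strain`/`condition`.
#' @export
simulate_localization_trace <- function(strain, condition, timepoints,
                                        n_cells = 50, seed = 1,
                                        params = loc_pulse_params(condition),
                                        amplitude_scale = 1,
                                        noise_sd = 0.05) {
  if (length(timepoints) < 2) stop("at least two timepoints are required")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be sorted strictly increasing")
  }
  stopifnot(n_cells >= 1)
  with_seed(seed, {
    cyto_base <- 100 * exp(stats::rnorm(n_cells, 0, 0.2))
    ratio_t <- pulse_ratio(timepoints, params, amplitude_scale)
    grid <- expand.grid(cell = seq_len(n_cells), time = timepoints,
                        KEEP.OUT.ATTRS = FALSE)
    cyto <- cyto_base[grid$cell] * exp(stats::rnorm(nrow(grid), 0, noise_sd))
    ratio <- ratio_t[match(grid$time, timepoints)] *
      exp(stats::rnorm(nrow(grid), 0, noise_sd))
    out <- data.frame(cell = grid$cell, time = grid$time,
                      nuclear = cyto * ratio, cytoplasmic = cyto)
    attr(out, "strain") <- strain
    attr(out, "condition") <- condition
    out
  })
}
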