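# Raw event streams -> strain x condition expression matrix:
# well demultiplexing, density gating, median extraction, autofluorescence
# correction and replicate averaging.

check_event_table <- function(events, need_time = FALSE) {
  req <- c("fsc", "ssc", "gfp", if (need_time) "time")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  for (col in req) {
    if (!all(is.finite(events[[col]]))) stop("non-finite values in channel ", col)
  }
  invisible(events)
}

#' Demultiplex a timed event stream into wells
#'
#' Splits a time-sorted event stream into exactly `n_wells` contiguous
#' segments, choosing the segment boundaries that maximize the total
#' inter-segment time gap. Because the boundaries contribute independently
#' to that objective, the optimum is the set of the `n_wells - 1` largest
#' inter-event spacings (ties broken toward the earliest boundary), which
#' this function selects exactly. With fewer events than wells, trailing
#' wells are left empty.
#'
#' @param events event data frame with a `time` column, sorted
#'   non-decreasing (unsorted input is an error).
#' @param n_wells number of wells the stream contains (>= 1).
#' @return integer vector assigning each event to a well in 1..n_wells, with
#'   attribute `boundaries` (indices i such that a segment ends at event i).
#' @export
partition_wells <- function(events, n_wells) {
  if (!"time" %in% names(events)) stop("event table lacks a time column")
  stopifnot(n_wells >= 1)
  t <- events$time
  n <- length(t)
  if (n == 0) return(structure(integer(0), boundaries = integer(0)))
  if (is.unsorted(t)) stop("events must be sorted by time")
  k <- min(n_wells - 1, n - 1)
  if (k == 0) {
    return(structure(rep(1L, n), boundaries = integer(0)))
  }
  gaps <- diff(t)
  ord <- order(-gaps, seq_along(gaps))
  cuts <- sort(ord[seq_len(k)])
  assign <- findInterval(seq_len(n) - 1L, cuts) + 1L
  structure(as.integer(assign), boundaries = cuts)
}

#' Automatic FSC/SSC density gate
#'
#' Builds a `resolution` x `resolution` 2-D histogram of FSC vs SSC, then
#' retains events from the densest bins, adding bins in decreasing-density
#' order until the retained fraction first reaches `retain_fraction`. This
#' keeps the dense area that contains the cell population and discards the
#' sparse scattering of debris, dead cells and other atypical events. The
#' realized fraction overshoots the target by at most one bin's mass.
#'
#' @param events event data frame (columns `fsc`, `ssc` at least; all other
#'   columns are carried through).
#' @param retain_fraction target fraction of events to keep, in (0, 1\];
#'   the screen's default is 0.9.
#' @param resolution bins per axis (>= 8); the accuracy/runtime trade-off.
#' @return the gated subset of `events`, with attributes
#'   `realized_fraction`, `n_total` and `n_retained`.
#' @export
gate_events <- function(events, retain_fraction = 0.9, resolution = 64) {
  check_event_table(events)
  n <- nrow(events)
  if (n == 0) stop("cannot gate an empty event table")
  if (!(retain_fraction > 0 && retain_fraction <= 1)) {
    stop("retain_fraction must be in (0, 1]")
  }
  if (resolution < 8) stop("resolution must be >= 8")
  if (retain_fraction == 1) {
    return(structure(events, realized_fraction = 1,
                     n_total = n, n_retained = n))
  }

  bin_axis <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    b <- floor((x - r[1]) / (r[2] - r[1]) * resolution) + 1L
    pmin(b, resolution)  # put the maximum into the last bin
  }
  bi <- bin_axis(events$fsc)
  bj <- bin_axis(events$ssc)
  bin <- (bi - 1L) * resolution + bj
  counts <- tabulate(bin, nbins = resolution * resolution)
  occupied <- which(counts > 0)
  # densest first; ties by bin index for determinism
  ord <- occupied[order(-counts[occupied], occupied)]
  cum <- cumsum(counts[ord])
  n_need <- retain_fraction * n
  n_bins <- which(cum >= n_need)[1]
  keep_bins <- ord[seq_len(n_bins)]
  keep <- bin %in% keep_bins
  out <- events[keep, , drop = FALSE]
  structure(out, realized_fraction = sum(keep) / n,
            n_total = n, n_retained = sum(keep))
}

#' Median reporter fluorescence of a gated well
#'
#' Exact median of the `gfp` channel (even counts: mean of the two central
#' order statistics). An empty gated set marks a missing well (`NA`), never
#' zero.
#'
#' @param events gated event data frame.
#' @return median GFP (a.u.), or `NA_real_` for an empty well.
#' @export
well_median_gfp <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(NA_real_)
  stats::median(events$gfp)
}

#' Autofluorescence correction
#'
#' Subtracts the median of the untagged control strain; negative results are
#' clipped to zero so downstream ratios and log transforms stay defined.
#'
#' @param median_gfp well median (a.u.), possibly vectorized.
#' @param control_median median of the no-GFP control in the same plate.
#' @return corrected median(s), >= 0.
#' @export
correct_autofluorescence <- function(median_gfp, control_median) {
  stopifnot(all(is.finite(control_median)))
  pmax(median_gfp - control_median, 0)
}

#' Process one plate stream into well measurements
#'
#' Demultiplexes the stream into the layout's wells, density-gates each
#' well, and extracts the gated GFP median.
#'
#' @param stream event stream (e.g. [simulate_plate_stream()] or a CSV read
#'   with [read_event_csv()]).
#' @param layout the plate layout the stream was acquired from.
#' @param retain_fraction,resolution gate settings (see [gate_events()]).
#' @return data frame of well measurements: `well`, `strain`, `condition`,
#'   `replicate`, `median_gfp` (raw), `n_events_total`, `n_events_gated`.
#' @export
measure_wells <- function(stream, layout, retain_fraction = 0.9,
                          resolution = 64) {
  check_event_table(stream, need_time = TRUE)
  assign <- partition_wells(stream, nrow(layout))
  out <- layout
  out$median_gfp <- NA_real_
  out$n_events_total <- 0L
  out$n_events_gated <- 0L
  for (i in seq_len(nrow(layout))) {
    ev <- stream[assign == i, , drop = FALSE]
    out$n_events_total[i] <- nrow(ev)
    if (nrow(ev) == 0) next
    gated <- gate_events(ev, retain_fraction, resolution)
    out$n_events_gated[i] <- nrow(gated)
    out$median_gfp[i] <- well_median_gfp(gated)
  }
  out
}

#' Correct well measurements for autofluorescence
#'
#' Subtracts, within each condition x replicate plate, the median of that
#' plate's `noGFP` control strain from every well median.
#'
#' @param wells well-measurement data frame from [measure_wells()] (rows
#'   from several plates may be concatenated).
#' @param control_strain strain id of the untagged control.
#' @return `wells` with an added `corrected_gfp` column; control rows keep
#'   their raw median.
#' @export
correct_wells <- function(wells, control_strain = "noGFP") {
  wells$corrected_gfp <- NA_real_
  key <- interaction(wells$condition, wells$replicate, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    ctrl <- idx[wells$strain[idx] == control_strain]
    if (length(ctrl) == 0) {
      stop(sprintf("no '%s' control in plate %s", control_strain, k))
    }
    ctrl_med <- mean(wells$median_gfp[ctrl], na.rm = TRUE)
    wells$corrected_gfp[idx] <-
      correct_autofluorescence(wells$median_gfp[idx], ctrl_med)
  }
  wells
}

#' Average replicates into an expression matrix
#'
#' Means the corrected medians across replicates for every strain x
#' condition cell and computes a replicate-reproducibility report: the
#' Pearson correlation of log10 medians between each replicate pair across
#' strains, per condition.
#'
#' @param wells data frame with columns `strain`, `condition`, `replicate`
#'   and a value column (`corrected_gfp` if present, else `median_gfp`).
#' @param wt_strain strain id holding the wild-type reference.
#' @return object of class `"expression_matrix"`: list with `values`
#'   (strain x condition matrix), `wt` (named per-condition WT vector),
#'   `reproducibility` (per condition and replicate pair: n, Pearson R of
#'   log10 values), and `wells` (the input).
#' @export
aggregate_replicates <- function(wells, wt_strain = "WT") {
  value_col <- if ("corrected_gfp" %in% names(wells)) "corrected_gfp" else "median_gfp"
  v <- wells[[value_col]]
  strains <- sort(unique(wells$strain))
  conditions <- unique(wells$condition)
  values <- matrix(NA_real_, length(strains), length(conditions),
                   dimnames = list(strains, conditions))
  for (i in seq_along(strains)) {
    for (j in seq_along(conditions)) {
      sel <- wells$strain == strains[i] & wells$condition == conditions[j] &
        !is.na(v)
      if (any(sel)) values[i, j] <- mean(v[sel])
    }
  }
  if (!wt_strain %in% strains) {
    stop(sprintf("expression matrix must contain a '%s' row", wt_strain))
  }

  rep_pairs <- list()
  for (cond in conditions) {
    reps <- sort(unique(wells$replicate[wells$condition == cond]))
    if (length(reps) < 2) next
    for (p in utils::combn(reps, 2, simplify = FALSE)) {
      w1 <- wells[wells$condition == cond & wells$replicate == p[1], ]
      w2 <- wells[wells$condition == cond & wells$replicate == p[2], ]
      common <- intersect(w1$strain, w2$strain)
      x <- w1[[value_col]][match(common, w1$strain)]
      y <- w2[[value_col]][match(common, w2$strain)]
      ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
      r <- if (sum(ok) >= 3) stats::cor(log10(x[ok]), log10(y[ok])) else NA_real_
      rep_pairs[[length(rep_pairs) + 1]] <- data.frame(
        condition = cond, rep_a = p[1], rep_b = p[2], n = sum(ok),
        pearson_log = r, stringsAsFactors = FALSE)
    }
  }
  repro <- if (length(rep_pairs)) do.call(rbind, rep_pairs) else
    data.frame(condition = character(0), rep_a = integer(0),
               rep_b = integer(0), n = integer(0), pearson_log = numeric(0))

  structure(list(values = values, wt = stats::setNames(as.numeric(values[wt_strain, ]), colnames(values)),
                 wt_strain = wt_strain, reproducibility = repro,
                 wells = wells),
            class = "expression_matrix")
}

#' Assemble an expression matrix directly from strain-level values
#'
#' Convenience constructor used for analytic tests and for noiseless truth
#' matrices: takes per strain x condition values that are already corrected
#' and replicate-averaged.
#'
#' @param values strain x condition numeric matrix with dimnames.
#' @param wt_strain row holding the wild-type reference.
#' @return an `"expression_matrix"`.
#' @export
expression_matrix <- function(values, wt_strain = "WT") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!wt_strain %in% rownames(values)) {
    stop(sprintf("expression matrix must contain a '%s' row", wt_strain))
  }
  structure(list(values = values, wt = stats::setNames(as.numeric(values[wt_strain, ]), colnames(values)),
                 wt_strain = wt_strain,
                 reproducibility = NULL, wells = NULL),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d strains x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$reproducibility) && nrow(x$reproducibility)) {
    cat(sprintf("  replicate log-median Pearson R: %.3f (median over %d pairs)\n",
                stats::median(x$reproducibility$pearson_log, na.rm = TRUE),
                nrow(x$reproducibility)))
  }
  invisible(x)
}

#' Expected reporter level of every genotype, as an expression matrix
#'
#' Evaluates [expected_gfp()] for each strain and condition of the truth
#' table — the noiseless limit of the full cytometry chain.
#'
#' @param truth a [make_truth()] table.
#' @param strains strain ids to include (must contain `"WT"`).
#' @param conditions conditions to include (default: all in the truth).
#' @return an `"expression_matrix"` of expected values.
#' @export
truth_matrix <- function(truth, strains, conditions = truth$conditions$condition) {
  vals <- matrix(NA_real_, length(strains), length(conditions),
                 dimnames = list(strains, conditions))
  for (s in strains) {
    g <- genotype_of(s)
    for (cond in conditions) {
      vals[s, cond] <- expected_gfp(g, cond, truth)
    }
  }
  expression_matrix(vals)
}

#' Simulate a replicate-averaged screen matrix without event-level detail
#'
#' Fast path for model-fitting studies: each well median is the expected
#' level times a log-normal replicate effect `exp(N(0, cv))`; replicates are
#' averaged. `cv = 0` reproduces [truth_matrix()] exactly.
#'
#' @param truth a [make_truth()] table.
#' @param strains strain ids (must contain `"WT"`).
#' @param conditions conditions to include.
#' @param n_reps replicates per strain x condition.
#' @param cv between-replicate CV; defaults to the truth table's.
#' @param seed integer seed.
#' @return an `"expression_matrix"`.
#' @export
simulate_screen_matrix <- function(truth, strains,
                                   conditions = truth$conditions$condition,
                                   n_reps = 2, cv = truth$noise$replicate_cv,
                                   seed = 1) {
  tm <- truth_matrix(truth, strains, conditions)$values
  with_seed(seed, {
    vals <- tm
    for (j in seq_len(ncol(vals))) {
      noise <- matrix(exp(stats::rnorm(nrow(vals) * n_reps, 0, cv)),
                      nrow(vals), n_reps)
      vals[, j] <- tm[, j] * rowMeans(noise)
    }
    expression_matrix(vals)
  })
}
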