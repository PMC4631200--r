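# Transcription-factor nuclear-localization dynamics: per-cell N/C ratio,
# per-timepoint population summary, area under the ratio time course, and
# repeat averaging.

#' Per-cell nuclear-to-cytoplasmic ratio
#'
#' @param nuclear,cytoplasmic per-cell intensities (a.u.).
#' @param background optional background intensity subtracted from both
#'   channels before the ratio.
#' @return ratio per cell; cells whose (background-subtracted) cytoplasmic
#'   intensity is not positive are dropped as `NA`, with the dropped count
#'   in attribute `n_dropped`.
#' @export
nc_ratio <- function(nuclear, cytoplasmic, background = 0) {
  stopifnot(length(nuclear) == length(cytoplasmic))
  nuc <- nuclear - background
  cyt <- cytoplasmic - background
  bad <- !is.finite(cyt) | cyt <= 0
  out <- ifelse(bad, NA_real_, nuc / cyt)
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Population summary of per-cell ratios at one timepoint
#'
#' The mean over cells by default; the median is selectable (both summaries
#' appear in the field's reporting conventions).
#'
#' @param ratios per-cell ratios (NAs from dropped cells ignored).
#' @param method `"mean"` or `"median"`.
#' @return one summary ratio.
#' @export
timepoint_summary <- function(ratios, method = c("mean", "median")) {
  method <- match.arg(method)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0) stop("no surviving cells at this timepoint")
  if (method == "mean") mean(ratios) else stats::median(ratios)
}

#' Area under a localization time course
#'
#' Trapezoid integral of the summary N/C ratio over time — the amount of
#' time the factor spent in the nucleus. No baseline subtraction by
#' default; `baseline = TRUE` subtracts the first timepoint's ratio and
#' clips at zero before integrating.
#'
#' @param timepoints sorted times (minutes), length >= 2.
#' @param ratios summary ratio per timepoint.
#' @param baseline subtract the t\[1\] ratio before integrating?
#' @return AUC (ratio x minutes).
#' @export
trace_auc <- function(timepoints, ratios, baseline = FALSE) {
  if (length(timepoints) < 2) stop("need >= 2 timepoints")
  if (is.unsorted(timepoints, strictly = TRUE)) stop("timepoints must be sorted")
  stopifnot(length(timepoints) == length(ratios))
  y <- if (baseline) pmax(ratios - ratios[1], 0) else ratios
  trapz_integral(timepoints, y)
}

#' Summarize a per-cell time-lapse table into a localization trace
#'
#' @param cells data frame with columns `cell`, `time`, `nuclear`,
#'   `cytoplasmic` (e.g. from [simulate_localization_trace()] or a CSV).
#' @param method per-timepoint summary, `"mean"` (default) or `"median"`.
#' @param background background intensity for [nc_ratio()].
#' @param baseline passed to [trace_auc()].
#' @return object of class `"localization_trace"`: data frame `time`,
#'   `ratio`, `n_cells` with attributes `auc`, `strain`, `condition`,
#'   `method`.
#' @export
localization_trace <- function(cells, method = "mean", background = 0,
                               baseline = FALSE) {
  stopifnot(all(c("cell", "time", "nuclear", "cytoplasmic") %in% names(cells)))
  tps <- sort(unique(cells$time))
  ratio <- numeric(length(tps))
  n_cells <- integer(length(tps))
  for (i in seq_along(tps)) {
    sub <- cells[cells$time == tps[i], ]
    r <- nc_ratio(sub$nuclear, sub$cytoplasmic, background)
    ratio[i] <- timepoint_summary(r, method)
    n_cells[i] <- sum(is.finite(r))
  }
  out <- data.frame(time = tps, ratio = ratio, n_cells = n_cells)
  attr(out, "auc") <- trace_auc(tps, ratio, baseline)
  attr(out, "strain") <- attr(cells, "strain")
  attr(out, "condition") <- attr(cells, "condition")
  attr(out, "method") <- method
  class(out) <- c("localization_trace", "data.frame")
  out
}

#' Average localization AUCs across biological repeats
#'
#' @param aucs data frame with columns `strain`, `condition`, `repeat_index`,
#'   `auc` (one row per repeat).
#' @return list with `summary` (per strain x condition: mean AUC, n
#'   repeats) and `scatter` (first-vs-second repeat pairs for
#'   reproducibility plots).
#' @export
average_repeats <- function(aucs) {
  stopifnot(all(c("strain", "condition", "auc") %in% names(aucs)))
  key <- paste(aucs$strain, aucs$condition, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sub <- aucs[key == k, ]
    data.frame(strain = sub$strain[1], condition = sub$condition[1],
               auc = mean(sub$auc), n_repeats = nrow(sub),
               stringsAsFactors = FALSE)
  })
  scatter <- lapply(unique(key), function(k) {
    sub <- aucs[key == k, ]
    if (nrow(sub) < 2) return(NULL)
    data.frame(strain = sub$strain[1], condition = sub$condition[1],
               auc_rep1 = sub$auc[1], auc_rep2 = sub$auc[2],
               stringsAsFactors = FALSE)
  })
  scatter <- scatter[!vapply(scatter, is.null, logical(1))]
  list(summary = do.call(rbind, rows),
       scatter = if (length(scatter)) do.call(rbind, scatter) else NULL)
}
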