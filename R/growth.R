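# Dilution-series planner: choose the dilution constant X for an X:2X:4X:8X
# split so that as many strains as possible, despite unknown doubling times,
# land in the target OD window after the final growth period.

#' Optimize the dilution constant for an X:2X:4X:8X series
#'
#' Each strain grows exponentially, `OD(t) = OD0 * 2^(t / dt)`, with an
#' unknown doubling time `dt` uniform over `doubling_time_range`. After
#' splitting at dilution `k * X` (k in 1, 2, 4, 8) and growing for
#' `growth_hours`, source k reads `od * 2^(growth_hours / dt) / (k * X)`.
#' A strain succeeds under X if at least one source ends inside
#' `od_target_range`. The planner scans a log-spaced grid of candidate X
#' values and returns the one maximizing the expected number of successful
#' strains (ties broken toward the smallest X).
#'
#' @param od_measured positive OD per well at the time of the split.
#' @param doubling_time_range `c(lo, hi)` hours; the screen's typical range
#'   is 1.5-3.5 h.
#' @param od_target_range target OD window `c(lo, hi)` at experiment onset.
#' @param growth_hours final growth period (h).
#' @param x_grid candidate dilution constants (default 200 log-spaced points
#'   in \[2, 512\]).
#' @param dt_points resolution of the doubling-time integration grid.
#' @return object of class `"dilution_plan"`: `x` (chosen constant),
#'   `series` (X, 2X, 4X, 8X), `success` (per-strain success probability at
#'   the chosen X), `expected_success` (their mean), and the scanned `grid`
#'   with its objective.
#' @export
plan_dilution <- function(od_measured,
                          doubling_time_range = c(1.5, 3.5),
                          od_target_range = c(0.2, 0.6),
                          growth_hours = 10,
                          x_grid = NULL, dt_points = 201) {
  if (length(od_measured) == 0) stop("empty OD vector")
  if (any(od_measured <= 0)) stop("ODs must be positive")
  stopifnot(length(doubling_time_range) == 2,
            doubling_time_range[1] > 0,
            doubling_time_range[1] <= doubling_time_range[2],
            growth_hours > 0)
  if (od_target_range[1] > od_target_range[2]) {
    stop("inverted od_target_range")
  }
  if (is.null(x_grid)) {
    x_grid <- exp(seq(log(2), log(512), length.out = 200))
  }

  dts <- if (doubling_time_range[1] == doubling_time_range[2]) {
    doubling_time_range[1]
  } else {
    seq(doubling_time_range[1], doubling_time_range[2], length.out = dt_points)
  }
  growth <- 2^(growth_hours / dts)              # fold growth per doubling time
  series_k <- c(1, 2, 4, 8)

  success_at <- function(x) {
    vapply(od_measured, function(od) {
      final <- od * growth                      # undiluted final OD over dt grid
      ok <- rep(FALSE, length(final))
      for (k in series_k) {
        v <- final / (k * x)
        ok <- ok | (v >= od_target_range[1] & v <= od_target_range[2])
      }
      mean(ok)
    }, numeric(1))
  }

  objective <- vapply(x_grid, function(x) sum(success_at(x)), numeric(1))
  best <- which(objective >= max(objective) - 1e-12)[1]  # smallest X on ties
  x_best <- x_grid[best]
  succ <- success_at(x_best)
  structure(list(x = x_best, series = x_best * series_k,
                 success = succ, expected_success = mean(succ),
                 grid = data.frame(x = x_grid, objective = objective)),
            class = "dilution_plan")
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf("Dilution plan: X = %.2f (series %s); expected success %.1f%%\n",
              x$x, paste(sprintf("%.1f", x$series), collapse = ":"),
              100 * x$expected_success))
  invisible(x)
}

#' Choose the best dilution source per well after the final OD read
#'
#' Among the four dilution sources of a well, picks the one whose final OD
#' lies inside the target range and closest to the range midpoint; wells
#' with no in-range source remain empty (`NA`).
#'
#' @param final_ods numeric matrix or data frame, wells x 4 sources.
#' @param od_target_range target OD window `c(lo, hi)`.
#' @return data frame per well: `source` (1-4 or NA) and `od` (chosen OD or
#'   NA).
#' @export
select_sources <- function(final_ods, od_target_range = c(0.2, 0.6)) {
  final_ods <- as.matrix(final_ods)
  if (ncol(final_ods) != 4) stop("expected four OD sources per well")
  mid <- mean(od_target_range)
  pick <- apply(final_ods, 1, function(v) {
    in_range <- which(v >= od_target_range[1] & v <= od_target_range[2])
    if (length(in_range) == 0) return(NA_integer_)
    in_range[which.min(abs(v[in_range] - mid))]
  })
  data.frame(source = as.integer(pick),
             od = final_ods[cbind(seq_len(nrow(final_ods)),
                                  ifelse(is.na(pick), 1L, pick))] *
       ifelse(is.na(pick), NA_real_, 1))
}
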