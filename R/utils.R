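# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#' `seed = NULL` leaves the RNG untouched.
#'
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical strain identifier for a genotype
#'
#' A genotype is the set of deleted genes. Identifiers are the sorted gene
#' names joined by `":"`; the empty genotype is `"WT"`. The reserved name
#' `"noGFP"` labels the untagged autofluorescence control.
#'
#' @param genotype character vector of deleted genes (possibly empty).
#' @return single character strain id.
#' @examples
#' strain_id(c("msn4", "msn2"))  # "msn2:msn4"
#' strain_id(character(0))       # "WT"
#' @export
strain_id <- function(genotype) {
  genotype <- setdiff(genotype, "WT")
  if (length(genotype) == 0) return("WT")
  if (identical(genotype, "noGFP")) return("noGFP")
  paste(sort(genotype), collapse = ":")
}

#' Split a strain identifier back into its genotype
#' @param id strain id as produced by [strain_id()].
#' @return character vector of deleted genes (empty for `"WT"`).
#' @export
genotype_of <- function(id) {
  if (id %in% c("WT", "noGFP")) return(if (id == "WT") character(0) else "noGFP")
  strsplit(id, ":", fixed = TRUE)[[1]]
}

# trapezoid integral; t sorted ascending
trapz_integral <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
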