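# Masking epistasis: a double mutant that phenocopies one of its singles,
# called per condition and consolidated across stress conditions.

#' Call masking epistasis for one gene pair in one condition
#'
#' A pair is eligible when its two single-knockout effects (relative to
#' wild type) differ by at least `eligibility_frac` of the larger effect
#' magnitude. For an eligible pair, the knockout Y masks X
#' (call `"Y_over_X"`) when the double resembles the Y single:
#' `|GFP_xy - GFP_y| <= delta * |GFP_x - GFP_y|`; symmetrically for
#' `"X_over_Y"`. If both sides qualify the smaller normalized distance
#' wins. One normalized-distance rule is applied to same-sign and
#' opposite-sign pairs alike.
#'
#' @param gfp_wt,gfp_x,gfp_y,gfp_xy reporter levels (a.u., non-negative) of
#'   wild type, the two singles and the double.
#' @param eligibility_frac minimum effect difference as a fraction of the
#'   larger effect (default 0.2).
#' @param delta resemblance tolerance as a fraction of the single-single
#'   distance (default 0.25).
#' @return one-row data frame: `call` (`Y_over_X`, `X_over_Y` or `none`),
#'   `eligible`, the two normalized distances, and the inputs.
#' @export
call_epistasis <- function(gfp_wt, gfp_x, gfp_y, gfp_xy,
                           eligibility_frac = 0.2, delta = 0.25) {
  stopifnot(all(c(gfp_wt, gfp_x, gfp_y, gfp_xy) >= 0))
  e_x <- gfp_x - gfp_wt
  e_y <- gfp_y - gfp_wt
  eligible <- abs(e_x - e_y) >= eligibility_frac * max(abs(e_x), abs(e_y)) &&
    (abs(e_x) > 0 || abs(e_y) > 0)
  sep <- abs(gfp_x - gfp_y)
  dist_to_y <- if (sep > 0) abs(gfp_xy - gfp_y) / sep else Inf
  dist_to_x <- if (sep > 0) abs(gfp_xy - gfp_x) / sep else Inf
  call <- "none"
  if (eligible) {
    y_over_x <- dist_to_y <= delta
    x_over_y <- dist_to_x <= delta
    if (y_over_x && x_over_y) {
      call <- if (dist_to_y <= dist_to_x) "Y_over_X" else "X_over_Y"
    } else if (y_over_x) {
      call <- "Y_over_X"
    } else if (x_over_y) {
      call <- "X_over_Y"
    }
  }
  data.frame(call = call, eligible = eligible,
             dist_to_y = dist_to_y, dist_to_x = dist_to_x,
             gfp_wt = gfp_wt, gfp_x = gfp_x, gfp_y = gfp_y, gfp_xy = gfp_xy,
             stringsAsFactors = FALSE)
}

#' Epistasis calls for every double of an expression matrix
#'
#' Finds all two-gene strains whose singles are present and evaluates
#' [call_epistasis()] per pair and condition.
#'
#' @param mat an `"expression_matrix"` with [strain_id()] rownames.
#' @param conditions conditions to call in.
#' @param pairs optional two-column matrix/data frame of gene pairs;
#'   default: all doubles present in the matrix.
#' @param ... passed to [call_epistasis()].
#' @return data frame: gene_x, gene_y, condition plus the call columns.
#' @export
epistasis_table <- function(mat, conditions = colnames(mat$values),
                            pairs = NULL, ...) {
  stopifnot(inherits(mat, "expression_matrix"))
  rn <- rownames(mat$values)
  if (is.null(pairs)) {
    doubles <- rn[vapply(rn, function(s) length(genotype_of(s)) == 2, logical(1))]
    pairs <- do.call(rbind, lapply(doubles, genotype_of))
  }
  pairs <- as.matrix(pairs)
  out <- list()
  for (cond in conditions) {
    for (i in seq_len(nrow(pairs))) {
      gx <- pairs[i, 1]; gy <- pairs[i, 2]
      dbl <- strain_id(c(gx, gy))
      if (!all(c(gx, gy, dbl) %in% rn)) next
      row <- call_epistasis(mat$wt[[cond]], mat$values[gx, cond],
                            mat$values[gy, cond], mat$values[dbl, cond], ...)
      out[[length(out) + 1]] <- cbind(
        data.frame(gene_x = gx, gene_y = gy, condition = cond,
                   stringsAsFactors = FALSE), row)
    }
  }
  do.call(rbind, out)
}

#' Cross-condition consensus of epistasis calls
#'
#' A pair gets a consensus direction when it is called in at least two of
#' the stress conditions and every called direction agrees; conflicting
#' directions over two or more called conditions give
#' `"direction_changed"`; anything else is `"none"`.
#'
#' @param calls named character vector of per-condition calls
#'   (`Y_over_X`, `X_over_Y` or `none`), e.g. over heat, KCl and diamide.
#' @return list: `consensus` and `supporting` (the called conditions).
#' @export
consensus_epistasis <- function(calls) {
  called <- calls[!is.na(calls) & calls != "none"]
  if (length(called) < 2) {
    return(list(consensus = "none", supporting = names(called)))
  }
  dirs <- unique(called)
  list(consensus = if (length(dirs) == 1) dirs else "direction_changed",
       supporting = names(called))
}

#' Consensus matrix over all pairs
#'
#' @param calls output of [epistasis_table()] restricted to the stress
#'   conditions of interest.
#' @param stress_conditions conditions entering the consensus.
#' @return data frame per pair: gene_x, gene_y, consensus,
#'   n_supporting, supporting (comma-joined).
#' @export
consensus_table <- function(calls,
                            stress_conditions = c("heat", "KCl", "diamide")) {
  calls <- calls[calls$condition %in% stress_conditions, ]
  key <- paste(calls$gene_x, calls$gene_y, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- calls[key == k, ]
    v <- sub$call
    names(v) <- sub$condition
    cons <- consensus_epistasis(v)
    out[[length(out) + 1]] <- data.frame(
      gene_x = sub$gene_x[1], gene_y = sub$gene_y[1],
      consensus = cons$consensus,
      n_supporting = length(cons$supporting),
      supporting = paste(cons$supporting, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
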