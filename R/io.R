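# Plain-text readers/writers for the pipeline's interchange formats:
# CSV event tables, TSV result tables, YAML configs and truth tables.

#' Read a CSV event table
#'
#' Expects at least the channel columns `fsc`, `ssc`, `gfp` and (for
#' streams) `time`; extra columns are kept. Column names are matched
#' case-insensitively and the aliases `fsc-a`/`ssc-a`/`gfp-a`/`fl1`
#' are accepted.
#'
#' @param path CSV file path.
#' @return event data frame.
#' @export
read_event_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(ev))
  nm[nm %in% c("fsc-a", "fsc_a", "fsc.a")] <- "fsc"
  nm[nm %in% c("ssc-a", "ssc_a", "ssc.a")] <- "ssc"
  nm[nm %in% c("gfp-a", "gfp_a", "gfp.a", "fl1", "fl1-a", "fl1.a")] <- "gfp"
  names(ev) <- nm
  check_event_table(ev)
  ev
}

#' Write an event table to CSV
#' @param events event data frame.
#' @param path destination path.
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#' @param x data frame.
#' @param path destination path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an expression matrix as TSV (strains x conditions)
#' @param mat an `"expression_matrix"`.
#' @param path destination path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(strain = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Serialize / restore a truth table through YAML
#'
#' @param truth a [make_truth()] table.
#' @param path YAML file path.
#' @return `read_truth_yaml()` returns the restored `"truth_table"`.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  obj <- list(effects = truth$effects, conditions = truth$conditions,
              interactions = truth$interactions,
              noise = truth$noise,
              config = unclass(truth$config), seed = truth$seed)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  as_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  structure(list(effects = as_df(obj$effects),
                 conditions = as_df(obj$conditions),
                 interactions = if (length(obj$interactions$gene_x))
                   as_df(obj$interactions)
                 else data.frame(gene_x = character(0), gene_y = character(0),
                                 condition = character(0), delta = numeric(0)),
                 noise = obj$noise,
                 config = structure(obj$config, class = "truth_config"),
                 seed = obj$seed),
            class = "truth_table")
}
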