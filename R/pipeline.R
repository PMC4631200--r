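# End-to-end orchestration: simulate -> demultiplex/gate/median ->
# expression matrix -> effects, dependence, epistasis, interaction models,
# localization -> result tables on disk.

#' Configuration for a full synthetic screen run
#'
#' Defaults reproduce the screen's structure at desk scale: five conditions
#' (one growth, three stresses, one post-diauxic), query genes crossed to a
#' target set that includes the queries themselves (which makes the
#' combined-model decomposition identifiable), triples of every query with
#' msn2 msn4, 2 replicates, and the screen's processing thresholds.
#'
#' @param query_genes,target_genes gene sets; doubles are all unordered
#'   query x target pairs (queries are crossed to each other when they
#'   appear in both sets).
#' @param conditions condition names.
#' @param stress_conditions subset treated as stresses.
#' @param n_replicates replicates per plate.
#' @param events_per_well events per well burst.
#' @param gap_seconds inter-well stream gap (s).
#' @param retain_fraction,resolution density-gate settings.
#' @param thresholds an [effect_thresholds()].
#' @param eligibility_frac,delta epistasis-call parameters.
#' @param truth_config a [truth_config()].
#' @param loc_timepoints localization imaging grid (minutes; default 7-min
#'   intervals over ~2 h).
#' @param loc_cells,loc_repeats localization cells per image and repeats.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `"screen_config"`.
#' @export
screen_config <- function(query_genes = sprintf("q%02d", 1:6),
                          target_genes = c(sprintf("q%02d", 1:6),
                                           sprintf("t%02d", 1:8)),
                          conditions = c("log", "heat", "KCl", "diamide",
                                         "post-diauxic"),
                          stress_conditions = c("heat", "KCl", "diamide"),
                          n_replicates = 2,
                          events_per_well = 300,
                          gap_seconds = 5,
                          retain_fraction = 0.9,
                          resolution = 64,
                          thresholds = effect_thresholds(),
                          eligibility_frac = 0.2,
                          delta = 0.25,
                          truth_config = stressGI::truth_config(),
                          loc_timepoints = seq(0, 119, by = 7),
                          loc_cells = 40,
                          loc_repeats = 2,
                          seed = 1) {
  stopifnot(length(query_genes) >= 1, length(conditions) >= 1,
            n_replicates >= 1, events_per_well >= 1,
            retain_fraction > 0, retain_fraction <= 1, resolution >= 8,
            eligibility_frac > 0, eligibility_frac < 1,
            delta > 0, delta < 1)
  structure(list(query_genes = query_genes, target_genes = target_genes,
                 conditions = conditions,
                 stress_conditions = intersect(stress_conditions, conditions),
                 n_replicates = n_replicates,
                 events_per_well = events_per_well,
                 gap_seconds = gap_seconds,
                 retain_fraction = retain_fraction, resolution = resolution,
                 thresholds = thresholds,
                 eligibility_frac = eligibility_frac, delta = delta,
                 truth_config = truth_config,
                 loc_timepoints = loc_timepoints, loc_cells = loc_cells,
                 loc_repeats = loc_repeats, seed = seed),
            class = "screen_config")
}

#' Round-trip a screen config through YAML
#' @param config a [screen_config()].
#' @param path YAML file path.
#' @export
write_screen_config <- function(config, path) {
  obj <- unclass(config)
  obj$thresholds <- unclass(obj$thresholds)
  obj$truth_config <- unclass(obj$truth_config)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$thresholds <- do.call(effect_thresholds, obj$thresholds)
  obj$truth_config <- do.call(truth_config, obj$truth_config)
  do.call(screen_config, obj)
}

#' The strain list of a configured screen
#'
#' Wild type, the untagged control, every single knockout, the msn2 msn4
#' double, all query x target doubles, and a triple (query + msn2 msn4)
#' for every query gene.
#'
#' @param config a [screen_config()].
#' @return character vector of strain ids.
#' @export
screen_strains <- function(config) {
  genes <- unique(c(config$query_genes, config$target_genes, "msn2", "msn4"))
  doubles <- unique(unlist(lapply(config$query_genes, function(q)
    vapply(setdiff(config$target_genes, q), function(t)
      strain_id(c(q, t)), character(1)))))
  triples <- vapply(config$query_genes, function(q)
    strain_id(c(q, "msn2", "msn4")), character(1))
  unique(c("WT", "noGFP", genes, strain_id(c("msn2", "msn4")),
           doubles, triples))
}

#' The unordered gene pairs assayed by a configured screen
#' @param config a [screen_config()].
#' @return two-column character matrix of gene pairs.
#' @export
screen_pairs <- function(config) {
  ids <- grep(":", screen_strains(config), value = TRUE)
  ids <- ids[vapply(ids, function(s) length(genotype_of(s)) == 2, logical(1))]
  ids <- setdiff(ids, strain_id(c("msn2", "msn4")))
  do.call(rbind, lapply(ids, genotype_of))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) stop_stage(name, conditionMessage(e)))
}

#' Run the full synthetic screen pipeline
#'
#' Simulates ground truth and plate streams, demultiplexes and gates them,
#' builds the replicate-averaged expression matrix, and runs every
#' analysis stage: condition-specific effects, Msn2/4-dependence scores,
#' epistasis calls and cross-condition consensus, the three interaction
#' models, and localization AUCs. With `output_dir` set, all result tables
#' are written as TSV/JSON plus a deterministic run manifest; identical
#' config and seed give identical outputs.
#'
#' @param config a [screen_config()].
#' @param output_dir directory for result files (created; `NULL` = no
#'   files).
#' @return (invisibly) a results bundle: `truth`, `wells`, `matrix`,
#'   `effects`, `specificity`, `dependence`, `epistasis`, `consensus`,
#'   `fits` (per condition: additive/multiplicative/combined),
#'   `dependence_correlation`, `localization`, `config`.
#' @export
run_screen <- function(config = screen_config(), output_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  strains <- screen_strains(config)

  truth <- stage("simulate", make_truth(
    unique(c(config$query_genes, config$target_genes, "msn2", "msn4")),
    config$conditions, config$truth_config, seed = config$seed))

  wells <- stage("process", {
    acc <- list()
    plate_i <- 0
    for (cond in config$conditions) {
      for (rep_i in seq_len(config$n_replicates)) {
        plate_i <- plate_i + 1
        layout <- plate_layout(strains, cond, rep_i,
                               format = if (length(strains) <= 96) 96 else 384)
        stream <- simulate_plate_stream(
          layout, truth, events_per_well = config$events_per_well,
          gap_seconds = config$gap_seconds,
          seed = config$seed + 1000L + plate_i)
        acc[[plate_i]] <- measure_wells(stream, layout,
                                        config$retain_fraction,
                                        config$resolution)
      }
    }
    correct_wells(do.call(rbind, acc))
  })

  mat <- stage("aggregate", aggregate_replicates(wells))

  eff <- stage("effects", effect_profiles(mat, config$thresholds,
                                          config$stress_conditions))
  spec <- if (length(config$stress_conditions) >= 2) {
    stage("effects", summarize_specificity(mat, config$thresholds,
                                           config$stress_conditions))
  } else {
    list(counts = table(character(0)), assignment = character(0))
  }
  dep <- stage("dependence", dependence_table(mat))

  epi <- stage("epistasis", epistasis_table(
    mat, conditions = config$stress_conditions, pairs = screen_pairs(config),
    eligibility_frac = config$eligibility_frac, delta = config$delta))
  cons <- stage("epistasis", consensus_table(epi, config$stress_conditions))

  fits <- stage("interactions", {
    out <- list()
    for (cond in config$conditions) {
      out[[cond]] <- list(additive = fit_additive(mat, cond),
                          multiplicative = fit_multiplicative(mat, cond),
                          combined = fit_combined(mat, cond))
    }
    out
  })

  dep_cor <- stage("interactions", {
    out <- list()
    for (cond in config$conditions) {
      res <- try(component_dependence_correlation(
        fits[[cond]]$combined$components, dep, cond), silent = TRUE)
      if (!inherits(res, "try-error")) {
        res$condition <- cond
        out[[cond]] <- res
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })

  loc <- stage("localization", {
    loc_conditions <- intersect(c("KCl", "diamide"), config$conditions)
    if (length(loc_conditions) == 0) loc_conditions <- config$conditions[1]
    loc_strains <- c("WT", config$query_genes)
    aucs <- list()
    k <- 0
    for (cond in loc_conditions) {
      for (s in loc_strains) {
        for (r in seq_len(config$loc_repeats)) {
          k <- k + 1
          cells <- simulate_localization_trace(
            s, cond, config$loc_timepoints, n_cells = config$loc_cells,
            seed = config$seed + 5000L + k)
          tr <- localization_trace(cells)
          aucs[[k]] <- data.frame(strain = s, condition = cond,
                                  repeat_index = r, auc = attr(tr, "auc"),
                                  stringsAsFactors = FALSE)
        }
      }
    }
    average_repeats(do.call(rbind, aucs))
  })

  bundle <- list(truth = truth, wells = wells, matrix = mat,
                 effects = eff, specificity = spec, dependence = dep,
                 epistasis = epi, consensus = cons, fits = fits,
                 dependence_correlation = dep_cor, localization = loc,
                 config = config)

  if (!is.null(output_dir)) {
    stage("report", write_screen_outputs(bundle, output_dir))
  }
  invisible(bundle)
}

write_screen_outputs <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  write_tsv(bundle$wells, p("well_measurements.tsv"))
  write_expression_tsv(bundle$matrix, p("expression_matrix.tsv"))
  write_tsv(bundle$matrix$reproducibility, p("replicate_reproducibility.tsv"))
  write_tsv(bundle$effects$profile, p("effect_profiles.tsv"))
  jsonlite::write_json(as.list(bundle$specificity$counts),
                       p("specificity_venn.json"), auto_unbox = TRUE)
  write_tsv(bundle$dependence, p("dependence_scores.tsv"))
  write_tsv(bundle$epistasis, p("epistasis_calls.tsv"))
  write_tsv(bundle$consensus, p("epistasis_consensus.tsv"))
  for (cond in names(bundle$fits)) {
    for (model in names(bundle$fits[[cond]])) {
      fit <- bundle$fits[[cond]][[model]]
      write_tsv(fit$pairs, p(sprintf("interactions_%s_%s.tsv", model, cond)))
    }
    write_tsv(bundle$fits[[cond]]$combined$components,
              p(sprintf("components_%s.tsv", cond)))
  }
  fit_report <- lapply(bundle$fits, function(x)
    lapply(x, function(f) list(r2 = f$r2, sse = f$sse, n_pairs = f$n_pairs)))
  jsonlite::write_json(fit_report, p("fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$dependence_correlation)) {
    write_tsv(bundle$dependence_correlation, p("dependence_correlations.tsv"))
  }
  write_tsv(bundle$localization$summary, p("localization_auc.tsv"))
  manifest <- list(
    package = "stressGI",
    version = as.character(utils::packageVersion("stressGI")),
    seed = bundle$config$seed,
    conditions = bundle$config$conditions,
    n_strains = nrow(bundle$matrix$values),
    n_wells = nrow(bundle$wells))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(output_dir)
}
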