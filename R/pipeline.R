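# End-to-end orchestration: simulate or ingest -> infer estrogen state ->
# select targets -> correlate per tissue and category -> screen ->
# compare -> summarize. Every stage reads its inputs from, and writes its
# outputs to, the run directory, so stages can be re-run standalone with
# identical results.

#' Pipeline configuration
#'
#' Assembles and validates the full parameter set of [run_pipeline()].
#' Exactly one input mode is active: `"simulate"` (the synthetic cohort
#' generator provides all inputs) or `"files"` (user-supplied expression
#' TSVs, GMT, ortholog TSV and neuron-count TSV).
#'
#' A single master seed governs all stochastic stages; per-stage sub-seeds
#' are derived deterministically (cohort: seed; neuron counts:
#' seed + 1000) so stages stay reproducible in isolation.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param out_dir Run directory for all stage outputs.
#' @param seed Master integer seed.
#' @param simulation Named list of overrides for [simulation_config()]
#'   (simulate mode).
#' @param files Named list for files mode: `expression` (named list
#'   tissue -> TSV path, must include `hypothalamus`), `gene_sets` (GMT
#'   path), `set_kinds` (named vector set name -> category kind),
#'   `orthologs` (TSV path), `neuron_counts` (TSV path).
#' @param estrogen List: `weights` (named, or NULL for equal), `binning`
#'   (`"median"`/`"quantile"`), `q`.
#' @param correlation List: `pairing`, `max_pairs`, `min_n`.
#' @param screen List: `min_n`, `min_sig_fraction`, `alpha`.
#' @param comparison List: `method`, `fisher_z`, `absolute_r`.
#' @param neuron List (simulate mode): `n_background`, `n_samples`,
#'   `reference_quantile`.
#' @param ortholog_policy `"unique"` or `"all"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            out_dir = tempfile("endocor_run_"),
                            seed = 1L,
                            simulation = list(),
                            files = NULL,
                            estrogen = list(),
                            correlation = list(),
                            screen = list(),
                            comparison = list(),
                            neuron = list(),
                            ortholog_policy = c("unique", "all")) {
  mode <- match.arg(mode)
  ortholog_policy <- match.arg(ortholog_policy)
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  config <- structure(list(
    mode = mode, out_dir = out_dir, seed = as.integer(seed),
    simulation = simulation, files = files,
    estrogen = merge_defaults(estrogen,
                              list(weights = NULL, binning = "median",
                                   q = 0.5)),
    correlation = merge_defaults(correlation,
                                 list(pairing = "all_pairs",
                                      max_pairs = 50000, min_n = 3)),
    screen = merge_defaults(screen,
                            list(min_n = 30, min_sig_fraction = 0.05,
                                 alpha = 0.05)),
    comparison = merge_defaults(comparison,
                                list(method = "welch_t", fisher_z = FALSE,
                                     absolute_r = FALSE)),
    neuron = merge_defaults(neuron,
                            list(n_background = 300, n_samples = 6,
                                 reference_quantile = 0.75)),
    ortholog_policy = ortholog_policy), class = "pipeline_config")
  validate_pipeline_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' Fails before any stage runs: mode-specific inputs must be complete and
#' referenced files must exist; the hypothalamus matrix is mandatory in
#' files mode.
#'
#' @param config A `pipeline_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  if (config$mode == "simulate") {
    do.call(simulation_config, c(config$simulation,
                                 list(seed = config$seed)))
  } else {
    files <- config$files
    if (is.null(files$expression) || is.null(names(files$expression))) {
      stop("pipeline_config: files mode needs a named 'expression' list")
    }
    if (!("hypothalamus" %in% names(files$expression))) {
      stop("pipeline_config: files$expression must include 'hypothalamus'")
    }
    needed <- c(unlist(files$expression), files$gene_sets,
                files$orthologs, files$neuron_counts)
    missing <- needed[!file.exists(needed)]
    if (length(missing)) {
      stop("pipeline_config: missing input file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  if (!config$estrogen$binning %in% c("median", "quantile")) {
    stop("pipeline_config: estrogen$binning must be 'median' or 'quantile'")
  }
  invisible(config)
}

.stage_paths <- function(out_dir) {
  list(expression = function(t) file.path(out_dir,
                                          paste0("expression_", t, ".tsv")),
       availability = file.path(out_dir, "availability.tsv"),
       truth = file.path(out_dir, "truth_pairing.tsv"),
       truth_states = file.path(out_dir, "truth_states.tsv"),
       gene_sets = file.path(out_dir, "gene_sets.gmt"),
       orthologs = file.path(out_dir, "orthologs.tsv"),
       neuron_counts = file.path(out_dir, "neuron_counts.tsv"),
       metadata = file.path(out_dir, "run_metadata.yaml"),
       states = file.path(out_dir, "estrogen_states.tsv"),
       targets = file.path(out_dir, "targets.txt"),
       records = function(t) file.path(out_dir,
                                       paste0("records_", t, ".tsv")),
       screen = file.path(out_dir, "tissue_screen.tsv"),
       summary_json = file.path(out_dir, "summary.json"),
       summary_text = file.path(out_dir, "summary.txt"))
}

# Set kinds for the standard generated GMT names.
.DEFAULT_SET_KINDS <- c(ESTROGEN_RESPONSE_SIGNATURE = "signature",
                        SECRETED_PROTEINS = "secreted",
                        KNOWN_LIGANDS = "ligand",
                        PEPTIDE_HORMONES = "peptide_hormone",
                        FEEDING_BEHAVIOR = "feeding")

#' Stage 1: materialize inputs in the run directory
#'
#' Simulate mode: generates the cohort, annotations and neuron counts from
#' the master seed and writes every input file (per-tissue expression
#' TSVs, availability mask, truth tables, GMT, ortholog TSV, neuron-count
#' TSV, and a YAML metadata record echoing the full configuration).
#' Files mode: copies the referenced input files into the run directory
#' under the standard names.
#'
#' @param config A validated `pipeline_config`.
#' @return Invisibly, the tissue names materialized.
#' @export
stage_inputs <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- .stage_paths(config$out_dir)
  if (config$mode == "simulate") {
    sim_config <- do.call(simulation_config,
                          c(config$simulation, list(seed = config$seed)))
    sim <- simulate_cohort(sim_config)
    for (t in names(sim$tissues)) {
      write_expression(sim$tissues[[t]], paths$expression(t))
    }
    write_availability(sim$truth$availability, paths$availability)
    utils::write.table(sim$truth$pairing, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(states_from_truth(sim$truth), paths$truth_states,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- make_annotations(sim_config)
    write_gmt(ann$gene_sets, paths$gene_sets)
    write_ortholog_map(ann$orthologs, paths$orthologs)
    mouse_targets <- names(ann$orthologs$entries)
    nc <- simulate_neuron_counts(
      n_genes = config$neuron$n_background + length(mouse_targets),
      n_samples = config$neuron$n_samples,
      reference_quantile = config$neuron$reference_quantile,
      seed = config$seed + 1000L,
      gene_names = c(mouse_targets,
                     sprintf("Bkgd%05d", seq_len(config$neuron$n_background))),
      high_genes = mouse_targets)
    write_neuron_counts(nc, paths$neuron_counts)
    tissues <- names(sim$tissues)
  } else {
    for (t in names(config$files$expression)) {
      file.copy(config$files$expression[[t]], paths$expression(t),
                overwrite = TRUE)
    }
    file.copy(config$files$gene_sets, paths$gene_sets, overwrite = TRUE)
    file.copy(config$files$orthologs, paths$orthologs, overwrite = TRUE)
    file.copy(config$files$neuron_counts, paths$neuron_counts,
              overwrite = TRUE)
    tissues <- names(config$files$expression)
  }
  meta <- list(seed = config$seed, mode = config$mode, tissues = tissues,
               estrogen = config$estrogen,
               correlation = config$correlation, screen = config$screen,
               comparison = config$comparison,
               ortholog_policy = config$ortholog_policy)
  writeLines(yaml::as.yaml(meta), paths$metadata)
  invisible(tissues)
}

.run_tissues <- function(config) {
  paths <- .stage_paths(config$out_dir)
  if (!file.exists(paths$metadata)) {
    stop("run directory '", config$out_dir, "' has no run_metadata.yaml; ",
         "run the inputs stage first", call. = FALSE)
  }
  meta <- yaml::read_yaml(paths$metadata)
  meta$tissues
}

.set_kinds <- function(config) {
  if (config$mode == "files" && !is.null(config$files$set_kinds)) {
    unlist(config$files$set_kinds)
  } else {
    .DEFAULT_SET_KINDS
  }
}

#' Stage 2: infer per-individual estrogen state
#'
#' Reads the per-tissue expression and the signature gene set from the run
#' directory, Z-scores the signature within each tissue, aggregates with
#' the configured weights, bins, and writes `estrogen_states.tsv`.
#'
#' @param config A validated `pipeline_config` whose inputs stage has run.
#' @return Invisibly, the `estrogen_states` data.frame.
#' @export
stage_estrogen <- function(config) {
  paths <- .stage_paths(config$out_dir)
  tissues <- .run_tissues(config)
  sets <- read_gmt(paths$gene_sets, kinds = .set_kinds(config))
  signature <- Filter(function(s) s$category_kind == "signature", sets)
  if (length(signature) != 1) {
    stop("stage_estrogen: expected exactly one signature gene set, found ",
         length(signature))
  }
  z_by_tissue <- list()
  for (t in tissues) {
    expr <- read_expression(paths$expression(t), t)
    z_by_tissue[[t]] <- zscore_gene_set(expr, signature[[1]])
  }
  states <- score_individuals(z_by_tissue,
                              weights = config$estrogen$weights)
  states <- bin_individuals(states, method = config$estrogen$binning,
                            q = config$estrogen$q)
  write_states(states, paths$states)
  invisible(states)
}

#' Stage 3: select hypothalamic target genes
#'
#' Reads the neuron count table, applies the counts-above-reference
#' filter, maps the retained mouse symbols to human symbols under the
#' configured policy, and writes `targets.txt`.
#'
#' @param config A validated `pipeline_config` whose inputs stage has run.
#' @return Invisibly, the character vector of human target symbols.
#' @export
stage_targets <- function(config) {
  paths <- .stage_paths(config$out_dir)
  nc <- read_neuron_counts(paths$neuron_counts)
  high <- filter_high_expressed(nc)
  map <- read_ortholog_map(paths$orthologs)
  targets <- map_orthologs(high, map, policy = config$ortholog_policy)
  if (length(targets) == 0) {
    stop("stage_targets: no target genes survive the filter and mapping")
  }
  writeLines(targets, paths$targets)
  invisible(targets)
}

#' Stage 4: stratified cross-tissue correlation and tissue screen
#'
#' Correlates every peripheral tissue's category genes against the
#' hypothalamic targets within each estrogen stratum, writes one record
#' TSV per tissue, runs the tissue screen, and writes
#' `tissue_screen.tsv`.
#'
#' @param config A validated `pipeline_config` whose previous stages have
#'   run.
#' @return Invisibly, a list with `records_by_tissue` and `screen`.
#' @export
stage_correlate <- function(config) {
  paths <- .stage_paths(config$out_dir)
  tissues <- setdiff(.run_tissues(config), "hypothalamus")
  hypothalamus <- read_expression(paths$expression("hypothalamus"),
                                  "hypothalamus")
  sets <- read_gmt(paths$gene_sets, kinds = .set_kinds(config))
  targets <- readLines(paths$targets)
  states <- read_states(paths$states)
  expr_list <- lapply(tissues, function(t) {
    read_expression(paths$expression(t), t)
  })
  names(expr_list) <- tissues
  records_by_tissue <- correlate_categories(
    expr_list, hypothalamus, sets, targets, states,
    min_n = config$correlation$min_n,
    pairing = config$correlation$pairing,
    max_pairs = config$correlation$max_pairs)
  for (t in tissues) {
    write_records(records_by_tissue[[t]], paths$records(t))
  }
  screen <- screen_tissues(records_by_tissue,
                           min_n = config$screen$min_n,
                           min_sig_fraction = config$screen$min_sig_fraction,
                           alpha = config$screen$alpha)
  screen_df <- rbind(
    if (length(screen$kept)) {
      data.frame(tissue = screen$kept, status = "kept", reason = "",
                 detail = "", stringsAsFactors = FALSE)
    },
    if (nrow(screen$dropped)) {
      data.frame(tissue = screen$dropped$tissue, status = "dropped",
                 reason = screen$dropped$reason,
                 detail = screen$dropped$detail, stringsAsFactors = FALSE)
    })
  if (is.null(screen_df)) {
    screen_df <- data.frame(tissue = character(0), status = character(0),
                            reason = character(0), detail = character(0),
                            stringsAsFactors = FALSE)
  }
  utils::write.table(screen_df, paths$screen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(records_by_tissue = records_by_tissue, screen = screen))
}

#' Stage 5: compare strata and summarize the run
#'
#' Loads the per-tissue record tables of the screened-in tissues, runs the
#' per-category comparison (omnibus Kruskal-Wallis, BH-adjusted post hoc
#' contrasts, profile similarity) and writes `summary.json` plus the text
#' rendering `summary.txt`.
#'
#' @param config A validated `pipeline_config` whose previous stages have
#'   run.
#' @return Invisibly, the `run_summary`.
#' @export
stage_compare <- function(config) {
  paths <- .stage_paths(config$out_dir)
  screen_df <- utils::read.delim(paths$screen, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  kept <- screen_df$tissue[screen_df$status == "kept"]
  records <- if (length(kept)) {
    do.call(rbind, c(lapply(kept, function(t) {
      read_records(paths$records(t))
    }), list(make.row.names = FALSE)))
  }
  results <- list()
  if (!is.null(records) && nrow(records) > 0) {
    for (cat in sort(unique(records$category))) {
      sub <- records[records$category == cat, , drop = FALSE]
      results[[cat]] <- compare_category(
        sub, method = config$comparison$method,
        fisher_z = config$comparison$fisher_z,
        absolute_r = config$comparison$absolute_r)
    }
  }
  screen_list <- {
    dropped <- screen_df[screen_df$status == "dropped", , drop = FALSE]
    structure(list(kept = kept,
                   dropped = dropped[, c("tissue", "reason", "detail")]),
              class = "tissue_screen")
  }
  meta <- yaml::read_yaml(paths$metadata)
  summary <- summarize_run(results, screen = screen_list, config = meta,
                           all_records = records)
  write_summary(summary, paths$summary_json)
  writeLines(render_summary_text(summary), paths$summary_text)
  invisible(summary)
}

#' Run the full pipeline
#'
#' Executes the stages in order (inputs, estrogen state, target selection,
#' correlation + screen, comparison + summary), writing every intermediate
#' to the run directory. Any stage failure aborts with the stage name.
#' Re-running with an identical configuration reproduces the
#' machine-readable outputs byte for byte.
#'
#' @param config A validated [pipeline_config()].
#' @return Invisibly, a list with the `run_summary` and the output paths.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  stages <- list(inputs = stage_inputs, estrogen = stage_estrogen,
                 targets = stage_targets, correlate = stage_correlate,
                 compare = stage_compare)
  result <- NULL
  for (nm in names(stages)) {
    result <- tryCatch(stages[[nm]](config), error = function(e) {
      stop("run_pipeline: stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- .stage_paths(config$out_dir)
  invisible(list(summary = result,
                 paths = list(summary_json = paths$summary_json,
                              summary_text = paths$summary_text,
                              screen = paths$screen,
                              states = paths$states,
                              out_dir = config$out_dir)))
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()] (keys `mode`,
#' `out_dir`, `seed`, `simulation`, `files`, `estrogen`, `correlation`,
#' `screen`, `comparison`, `neuron`, `ortholog_policy`).
#'
#' @param path YAML file path.
#' @param overrides Optional named list applied on top of the file (e.g.
#'   a CLI `--seed`).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop("read_pipeline_config: file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    raw[[nm]] <- overrides[[nm]]
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}
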