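# Synthetic multi-tissue cohort generator. Emulates the structure of a
# donor-based multi-tissue expression resource: many tissues, sparse
# per-donor tissue availability, a latent high/low estrogen-signaling state
# that shifts an estrogen-responsive signature, and tissue- and
# stratum-dependent cross-tissue correlation between peripheral
# category genes and hypothalamic target genes.

.CATEGORY_KINDS <- c("secreted", "ligand", "peptide_hormone", "feeding")

.CATEGORY_PREFIX <- c(secreted = "SECR", ligand = "LIGD",
                      peptide_hormone = "PEPH", feeding = "FEED")

#' Default stratum-dependent correlation table
#'
#' Target cross-tissue correlations per (tissue, stratum, category),
#' reproducing the qualitative pattern of interest: adipose depots couple
#' to hypothalamic targets more strongly in the high-estrogen stratum,
#' skeletal muscle and stomach more strongly in the low stratum, and the
#' small intestine carries no signal (it exists to exercise the tissue
#' screen, together with its low availability).
#'
#' @param tissues Peripheral tissue names (hypothalamus excluded).
#' @param categories Category kinds; defaults to the four functional
#'   programs (secreted, ligand, peptide_hormone, feeding).
#' @return A data.frame with columns `tissue`, `stratum`, `category`, `rho`.
#' @export
default_rho_table <- function(tissues = c("adipose_subcutaneous",
                                          "adipose_visceral",
                                          "skeletal_muscle", "stomach",
                                          "small_intestine"),
                              categories = .CATEGORY_KINDS) {
  grid <- expand.grid(tissue = tissues, stratum = c("high", "low"),
                      category = categories, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rho <- numeric(nrow(grid))
  adipose <- grepl("^adipose", grid$tissue)
  lowside <- grid$tissue %in% c("skeletal_muscle", "stomach")
  rho[adipose & grid$stratum == "high"] <- 0.5
  rho[adipose & grid$stratum == "low"] <- 0.2
  rho[lowside & grid$stratum == "high"] <- 0.2
  rho[lowside & grid$stratum == "low"] <- 0.5
  grid$rho <- rho
  grid[order(grid$tissue, grid$category, grid$stratum), , drop = FALSE]
}

#' Configuration for the synthetic cohort
#'
#' Builds and validates the full parameter set of the generator. Defaults
#' describe the study conditions the package is designed around: six
#' tissues (hypothalamus plus five peripheral), sparse tissue availability
#' with the small intestine nearly unmatched, a 1 SD signature shift
#' between latent strata, and the stratum-dependent correlation pattern of
#' [default_rho_table()].
#'
#' @param n_individuals Cohort size.
#' @param tissues Tissue names; must include `"hypothalamus"` (targets
#'   live there).
#' @param availability Named vector of per-tissue sampling probabilities in
#'   (0, 1]; hypothalamus is always forced available.
#' @param estrogen_effect Signature mean shift, in SD units, for
#'   high-stratum individuals.
#' @param high_fraction Probability an individual is in the latent high
#'   state.
#' @param rho Data.frame (tissue, stratum, category, rho) of target
#'   cross-tissue correlations, each in (-1, 1).
#' @param n_genes Named counts for roles `signature`, `category` (per
#'   category), `target`, `background`.
#' @param noise_sd Expression noise SD (log-scale units).
#' @param unmapped_fraction Fraction of target genes left without an
#'   ortholog entry by [make_annotations()].
#' @param one_to_many_fraction Fraction of mapped target genes given an
#'   ambiguous (one-to-many) ortholog entry.
#' @param seed Integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 300,
                              tissues = c("hypothalamus",
                                          "adipose_subcutaneous",
                                          "adipose_visceral",
                                          "skeletal_muscle", "stomach",
                                          "small_intestine"),
                              availability = NULL,
                              estrogen_effect = 1.0,
                              high_fraction = 0.5,
                              rho = NULL,
                              n_genes = c(signature = 10, category = 16,
                                          target = 8, background = 50),
                              noise_sd = 1.0,
                              unmapped_fraction = 0,
                              one_to_many_fraction = 0,
                              seed = 1L) {
  if (is.null(availability)) {
    defaults <- c(hypothalamus = 1, adipose_subcutaneous = 0.7,
                  adipose_visceral = 0.6, skeletal_muscle = 0.7,
                  stomach = 0.5, small_intestine = 0.15)
    availability <- vapply(tissues, function(t) {
      if (t %in% names(defaults)) defaults[[t]] else 0.7
    }, numeric(1))
    names(availability) <- tissues
  }
  if (is.null(rho)) {
    rho <- default_rho_table(setdiff(tissues, "hypothalamus"))
  }
  # tolerate YAML/list-style inputs
  availability <- unlist(availability)
  n_genes <- unlist(n_genes)
  if (!is.data.frame(rho) && is.list(rho)) {
    rho <- do.call(rbind, lapply(rho, as.data.frame,
                                 stringsAsFactors = FALSE))
  }
  tissues <- as.character(unlist(tissues))
  config <- structure(
    list(n_individuals = as.integer(n_individuals), tissues = tissues,
         availability = availability, estrogen_effect = estrogen_effect,
         high_fraction = high_fraction, rho = rho, n_genes = n_genes,
         noise_sd = noise_sd, unmapped_fraction = unmapped_fraction,
         one_to_many_fraction = one_to_many_fraction,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(config)
  config
}

#' Validate a simulation configuration
#'
#' Checks every invariant and fails naming the violated field.
#'
#' @param config A `simulation_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_simulation_config <- function(config) {
  stop_field <- function(field, why) {
    stop("invalid simulation_config: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!is.numeric(config$n_individuals) || config$n_individuals < 2) {
    stop_field("n_individuals", "must be a count >= 2")
  }
  if (!("hypothalamus" %in% config$tissues)) {
    stop_field("tissues", "must include 'hypothalamus' (targets live there)")
  }
  if (anyDuplicated(config$tissues)) {
    stop_field("tissues", "contains duplicates")
  }
  av <- config$availability
  if (!all(config$tissues %in% names(av))) {
    stop_field("availability", "must cover every tissue")
  }
  if (any(!is.finite(av)) || any(av <= 0) || any(av > 1)) {
    stop_field("availability", "probabilities must lie in (0, 1]")
  }
  if (!is.finite(config$estrogen_effect)) {
    stop_field("estrogen_effect", "must be finite")
  }
  if (config$high_fraction <= 0 || config$high_fraction >= 1) {
    stop_field("high_fraction", "must lie in (0, 1)")
  }
  rho <- config$rho
  needed <- c("tissue", "stratum", "category", "rho")
  if (!is.data.frame(rho) || !all(needed %in% names(rho))) {
    stop_field("rho", "must be a data.frame with tissue/stratum/category/rho")
  }
  if (any(abs(rho$rho) >= 1)) {
    stop_field("rho", "correlations must lie strictly in (-1, 1)")
  }
  if (any(!rho$tissue %in% config$tissues)) {
    stop_field("rho", "refers to tissues absent from the tissue list")
  }
  ng <- config$n_genes
  roles <- c("signature", "category", "target", "background")
  if (!all(roles %in% names(ng)) || any(ng[roles] < 1)) {
    stop_field("n_genes", "must give positive counts for signature/category/target/background")
  }
  if (!is.finite(config$noise_sd) || config$noise_sd <= 0) {
    stop_field("noise_sd", "must be a positive real")
  }
  for (f in c("unmapped_fraction", "one_to_many_fraction")) {
    if (config[[f]] < 0 || config[[f]] >= 1) {
      stop_field(f, "must lie in [0, 1)")
    }
  }
  invisible(config)
}

# Deterministic gene namespace shared by simulate_cohort and
# make_annotations (no RNG involved).
.cohort_genes <- function(config) {
  ng <- config$n_genes
  categories <- unique(config$rho$category)
  category_genes <- lapply(categories, function(cat) {
    sprintf("%s%03d", .CATEGORY_PREFIX[[cat]], seq_len(ng[["category"]]))
  })
  names(category_genes) <- categories
  list(signature = sprintf("SIG%03d", seq_len(ng[["signature"]])),
       category = category_genes,
       target = sprintf("TGT%03d", seq_len(ng[["target"]])),
       background = sprintf("BKG%03d", seq_len(ng[["background"]])))
}

# Cycle category genes onto target genes: gene j pairs with target
# ((j - 1) mod n_target) + 1.
.pairing_table <- function(genes) {
  n_target <- length(genes$target)
  do.call(rbind, lapply(names(genes$category), function(cat) {
    periph <- genes$category[[cat]]
    data.frame(category = cat, peripheral_gene = periph,
               target_gene = genes$target[((seq_along(periph) - 1) %% n_target) + 1],
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a multi-tissue cohort with known ground truth
#'
#' Draws a latent high/low estrogen state per individual, a per-individual
#' tissue availability mask (hypothalamus always available), and log-scale
#' expression matrices per tissue:
#'
#' * signature genes are standard noise plus a mean shift of
#'   `estrogen_effect` SD in high-state individuals, in every tissue;
#' * each peripheral category gene is tied to one hypothalamic target gene
#'   through a shared standard-normal latent, with the mixing coefficient
#'   chosen per individual so the population correlation within a stratum
#'   equals the configured `rho[(tissue, stratum, category)]`;
#' * background genes are independent noise.
#'
#' @param config A validated [simulation_config()].
#' @return A list with `tissues` (named list of [tissue_expression()]
#'   objects) and `truth` (class `simulated_truth`: per-individual
#'   `estrogen_state`, long-format `pairing` table with generating rho, and
#'   the logical `availability` mask, individuals by tissues).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  individuals <- sprintf("IND%04d", seq_len(n))
  state <- ifelse(stats::runif(n) < config$high_fraction, "high", "low")
  names(state) <- individuals

  avail <- sapply(config$tissues, function(t) {
    if (t == "hypothalamus") rep(TRUE, n)
    else stats::runif(n) < config$availability[[t]]
  })
  rownames(avail) <- individuals

  genes <- .cohort_genes(config)
  pairing <- .pairing_table(genes)
  sdv <- config$noise_sd

  # shared latents: one row per target gene
  latents <- matrix(stats::rnorm(length(genes$target) * n),
                    nrow = length(genes$target),
                    dimnames = list(genes$target, individuals))

  sig_block <- function() {
    shift <- config$estrogen_effect * (state == "high")
    m <- matrix(stats::rnorm(length(genes$signature) * n),
                nrow = length(genes$signature),
                dimnames = list(genes$signature, individuals))
    sdv * (m + rep(shift, each = length(genes$signature)))
  }

  rho_for <- function(tissue, category) {
    sub <- config$rho[config$rho$tissue == tissue &
                        config$rho$category == category, , drop = FALSE]
    r <- c(high = 0, low = 0)
    r[sub$stratum] <- sub$rho
    r
  }

  tissues_out <- list()
  pairing_rows <- list()
  for (t in config$tissues) {
    if (t == "hypothalamus") {
      vals <- rbind(sdv * latents, sig_block(),
                    sdv * matrix(stats::rnorm(length(genes$background) * n),
                                 nrow = length(genes$background),
                                 dimnames = list(genes$background, individuals)))
    } else {
      cat_rows <- matrix(0, nrow(pairing), n,
                         dimnames = list(pairing$peripheral_gene, individuals))
      for (k in seq_len(nrow(pairing))) {
        r <- rho_for(t, pairing$category[k])
        rho_i <- ifelse(state == "high", r[["high"]], r[["low"]])
        eps <- stats::rnorm(n)
        cat_rows[k, ] <- sdv * (rho_i * latents[pairing$target_gene[k], ] +
                                  sqrt(1 - rho_i^2) * eps)
      }
      pairing_rows[[t]] <- do.call(rbind, lapply(c("high", "low"), function(s) {
        rr <- vapply(seq_len(nrow(pairing)), function(k) {
          rho_for(t, pairing$category[k])[[s]]
        }, numeric(1))
        cbind(data.frame(tissue = t, stringsAsFactors = FALSE),
              pairing, stratum = s, rho = rr)
      }))
      vals <- rbind(cat_rows, sig_block(),
                    sdv * matrix(stats::rnorm(length(genes$background) * n),
                                 nrow = length(genes$background),
                                 dimnames = list(genes$background, individuals)))
    }
    keep <- individuals[avail[, t]]
    tissues_out[[t]] <- tissue_expression(t, vals[, keep, drop = FALSE])
  }

  truth <- structure(
    list(estrogen_state = state,
         pairing = do.call(rbind, c(pairing_rows, list(make.row.names = FALSE))),
         availability = avail),
    class = "simulated_truth")
  list(tissues = tissues_out, truth = truth)
}

#' Simulate an overdispersed neuron count table
#'
#' Emulates bulk RNA-seq counts from a flow-enriched neuronal population:
#' gene-specific log-normal mean expression with negative-binomial
#' sampling noise per sample. The reference gene (default `Gfap`, the glial
#' marker used as the high-expression cutoff) has its mean placed at
#' `reference_quantile` of the gene-mean distribution, so the downstream
#' counts-above-reference filter retains about `1 - reference_quantile` of
#' the genes.
#'
#' @param n_genes Number of non-reference genes (>= 2).
#' @param n_samples Number of samples (columns).
#' @param reference_quantile Quantile in (0, 1) at which the reference
#'   gene's mean sits.
#' @param seed Integer RNG seed.
#' @param gene_names Optional symbols for the non-reference genes.
#' @param high_genes Optional subset of `gene_names` whose means are forced
#'   above the reference (used when the table must contain known target
#'   genes).
#' @param reference_gene Reference symbol (default `"Gfap"`).
#' @param dispersion Negative-binomial size parameter.
#' @return A list of class `neuron_counts`: integer `counts` matrix (genes
#'   by samples) and `reference_gene`.
#' @export
simulate_neuron_counts <- function(n_genes, n_samples = 6,
                                   reference_quantile = 0.75, seed = 1L,
                                   gene_names = NULL, high_genes = NULL,
                                   reference_gene = "Gfap",
                                   dispersion = 5) {
  if (n_genes < 2) {
    stop("simulate_neuron_counts: n_genes must be at least 2")
  }
  if (reference_quantile <= 0 || reference_quantile >= 1) {
    stop("simulate_neuron_counts: reference_quantile must lie in (0, 1)")
  }
  if (n_samples < 1) {
    stop("simulate_neuron_counts: n_samples must be at least 1")
  }
  set.seed(seed)
  if (is.null(gene_names)) {
    gene_names <- sprintf("Gene%05d", seq_len(n_genes))
  }
  if (length(gene_names) != n_genes || anyDuplicated(gene_names)) {
    stop("simulate_neuron_counts: gene_names must be ", n_genes,
         " unique symbols")
  }
  if (reference_gene %in% gene_names) {
    stop("simulate_neuron_counts: reference_gene collides with gene_names")
  }
  means <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
  names(means) <- gene_names
  ref_mean <- unname(stats::quantile(means, reference_quantile))
  if (!is.null(high_genes)) {
    if (!all(high_genes %in% gene_names)) {
      stop("simulate_neuron_counts: high_genes must be a subset of gene_names")
    }
    means[high_genes] <- ref_mean * exp(stats::runif(length(high_genes),
                                                     0.5, 2))
  }
  all_means <- c(means, stats::setNames(ref_mean, reference_gene))
  counts <- matrix(stats::rnbinom(length(all_means) * n_samples,
                                  mu = rep(all_means, n_samples),
                                  size = dispersion),
                   nrow = length(all_means),
                   dimnames = list(names(all_means),
                                   sprintf("S%02d", seq_len(n_samples))))
  structure(list(counts = counts, reference_gene = reference_gene),
            class = "neuron_counts")
}

#' Gene sets and ortholog map matching a simulated cohort
#'
#' Emits one gene set per functional category (secreted proteins, known
#' ligands, peptide hormones, feeding behavior) plus the
#' estrogen-responsive signature set, all consistent with the gene
#' namespace of [simulate_cohort()], and a mouse-to-human ortholog map for
#' the target genes. Mouse-style symbols are the human symbols in
#' title case. A configurable fraction of targets is left unmapped, and a
#' fraction mapped ambiguously (one mouse symbol to two human symbols),
#' for testing the mapping policies.
#'
#' @param config A validated [simulation_config()].
#' @return A list with `gene_sets` (list of [gene_set()] objects, the
#'   signature first) and `orthologs` (an [ortholog_map()]).
#' @export
make_annotations <- function(config) {
  validate_simulation_config(config)
  genes <- .cohort_genes(config)
  set_names <- c(secreted = "SECRETED_PROTEINS", ligand = "KNOWN_LIGANDS",
                 peptide_hormone = "PEPTIDE_HORMONES",
                 feeding = "FEEDING_BEHAVIOR")
  sets <- c(list(gene_set("ESTROGEN_RESPONSE_SIGNATURE", genes$signature,
                          "signature")),
            lapply(names(genes$category), function(cat) {
              gene_set(set_names[[cat]], genes$category[[cat]], cat)
            }))
  to_mouse <- function(sym) {
    paste0(substr(sym, 1, 1), tolower(substring(sym, 2)))
  }
  targets <- genes$target
  set.seed(config$seed + 17L)
  n_unmapped <- round(config$unmapped_fraction * length(targets))
  unmapped <- if (n_unmapped > 0) sample(targets, n_unmapped) else character(0)
  mapped <- setdiff(targets, unmapped)
  n_multi <- round(config$one_to_many_fraction * length(mapped))
  multi <- if (n_multi > 0) sample(mapped, n_multi) else character(0)
  entries <- lapply(mapped, function(h) {
    if (h %in% multi) c(h, paste0(h, "B")) else h
  })
  names(entries) <- to_mouse(mapped)
  list(gene_sets = sets, orthologs = ortholog_map(entries))
}

#' Estrogen-state table from simulated ground truth
#'
#' Convenience accessor turning a `simulated_truth` object into the
#' minimal individual/bin table accepted by
#' [cross_tissue_correlations()], bypassing signature-based inference.
#' Useful for validating the correlation stage against known strata.
#'
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return A data.frame with columns `individual` and `bin`.
#' @export
states_from_truth <- function(truth) {
  data.frame(individual = names(truth$estrogen_state),
             bin = unname(truth$estrogen_state), stringsAsFactors = FALSE)
}
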