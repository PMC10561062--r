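# Per-individual estrogen-signaling state: per-tissue Z-scoring of the
# estrogen-responsive signature, weighted pan-tissue aggregation, and
# binning into high/low strata.

#' Z-score a gene set within one tissue
#'
#' Standardizes each signature gene across the tissue's individuals
#' (mean 0, SD 1, denominator n - 1). Signature genes absent from the
#' tissue are skipped with a message; genes with zero variance are
#' dropped with a warning (never emitted as NaN).
#'
#' @param expr A [tissue_expression()] with at least 2 individuals.
#' @param signature A [gene_set()] of signature genes.
#' @return Numeric matrix, retained signature genes by individuals.
#' @export
zscore_gene_set <- function(expr, signature) {
  if (length(expr$individuals) < 2) {
    stop("zscore_gene_set: tissue '", expr$tissue,
         "' has fewer than 2 individuals")
  }
  present <- intersect(signature$genes, expr$genes)
  if (length(present) == 0) {
    stop("zscore_gene_set: no signature gene present in tissue '",
         expr$tissue, "'")
  }
  missing <- setdiff(signature$genes, expr$genes)
  if (length(missing)) {
    message("zscore_gene_set: ", length(missing),
            " signature gene(s) absent from tissue '", expr$tissue,
            "'; skipped")
  }
  vals <- expr$values[present, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zscore_gene_set: dropped ", sum(sds == 0),
            " zero-variance gene(s) in tissue '", expr$tissue, "'")
    vals <- vals[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(vals) == 0) {
      stop("zscore_gene_set: all signature genes constant in tissue '",
           expr$tissue, "'")
    }
  }
  (vals - rowMeans(vals)) / sds
}

#' Aggregate per-tissue signature scores per individual
#'
#' The per-tissue score of an individual is the mean Z over retained
#' signature genes in that tissue; the aggregate is the weighted mean of
#' per-tissue scores over the tissues available for that individual
#' (weights renormalized per individual to the available set). Default
#' weights are 1 for every tissue, i.e. the plain mean over available
#' tissues.
#'
#' @param z_by_tissue Named list of Z matrices from [zscore_gene_set()].
#' @param weights Optional named non-negative weights per tissue; at least
#'   one must be positive.
#' @return A data.frame of class `estrogen_states`: `individual`, one
#'   `score_<tissue>` column per tissue (NA when unavailable), and
#'   `aggregate_score`. Bins are unset until [bin_individuals()].
#' @export
score_individuals <- function(z_by_tissue, weights = NULL) {
  if (length(z_by_tissue) == 0) {
    stop("score_individuals: need at least one tissue Z matrix")
  }
  tissues <- names(z_by_tissue)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(tissues)), tissues)
  }
  if (!all(tissues %in% names(weights))) {
    stop("score_individuals: weights must cover every tissue")
  }
  weights <- weights[tissues]
  if (any(weights < 0)) {
    stop("score_individuals: weights must be non-negative")
  }
  if (sum(weights) == 0) {
    stop("score_individuals: all weights are zero")
  }
  individuals <- unique(unlist(lapply(z_by_tissue, colnames)))
  scores <- matrix(NA_real_, length(individuals), length(tissues),
                   dimnames = list(individuals, tissues))
  for (t in tissues) {
    z <- z_by_tissue[[t]]
    scores[colnames(z), t] <- colMeans(z)
  }
  w <- matrix(rep(weights, each = length(individuals)),
              nrow = length(individuals))
  w[is.na(scores)] <- 0
  denom <- rowSums(w)
  usable <- denom > 0
  if (any(!usable)) {
    warning("score_individuals: excluded ", sum(!usable),
            " individual(s) with no positively weighted tissue")
  }
  agg <- rowSums(scores * w, na.rm = TRUE) / denom
  out <- data.frame(individual = individuals, stringsAsFactors = FALSE)
  for (t in tissues) {
    out[[paste0("score_", t)]] <- scores[, t]
  }
  out$aggregate_score <- agg
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("estrogen_states", "data.frame")
  out
}

#' Bin individuals into high/low estrogen strata
#'
#' Median method (default): `bin = "high"` iff the aggregate score is
#' strictly greater than the cohort median; scores at or below the
#' threshold (including exact ties) are `"low"`, deterministically.
#' Quantile method: same rule at the q-th quantile.
#'
#' @param states An `estrogen_states` data.frame from
#'   [score_individuals()] with at least 2 rows.
#' @param method `"median"` or `"quantile"`.
#' @param q Quantile in (0, 1) for the quantile method.
#' @return The input with a `bin` column set.
#' @export
bin_individuals <- function(states, method = c("median", "quantile"),
                            q = 0.5) {
  method <- match.arg(method)
  if (nrow(states) < 2) {
    stop("bin_individuals: need at least 2 individuals")
  }
  threshold <- switch(method,
    median = stats::median(states$aggregate_score),
    quantile = {
      if (q <= 0 || q >= 1) stop("bin_individuals: q must lie in (0, 1)")
      unname(stats::quantile(states$aggregate_score, q))
    })
  states$bin <- ifelse(states$aggregate_score > threshold, "high", "low")
  message("bin_individuals: ", sum(states$bin == "high"), " high / ",
          sum(states$bin == "low"), " low (threshold ",
          format(threshold, digits = 4), ", method ", method, ")")
  states
}

#' Write / read the per-individual estrogen state table
#'
#' TSV with `individual`, per-tissue score columns (NA token `NA` when the
#' tissue is unavailable), `aggregate_score` and, when set, `bin`.
#'
#' @param states An `estrogen_states` data.frame.
#' @param path File path.
#' @return `read_states` returns the `estrogen_states` data.frame.
#' @export
write_states <- function(states, path) {
  utils::write.table(states, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("estrogen_states", "data.frame")
  df
}
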