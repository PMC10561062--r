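# Stratified cross-tissue co-correlation: biweight midcorrelation between
# peripheral category genes and hypothalamic target genes across matched
# individuals, separately per estrogen stratum, plus the tissue screen.

.RECORD_COLUMNS <- c("tissue", "category", "peripheral_gene", "target_gene",
                     "stratum", "r", "n", "p", "method")

.empty_records <- function() {
  data.frame(tissue = character(0), category = character(0),
             peripheral_gene = character(0), target_gene = character(0),
             stratum = character(0), r = numeric(0), n = integer(0),
             p = numeric(0), method = character(0), stringsAsFactors = FALSE)
}

#' Stratified cross-tissue correlation records
#'
#' For each estrogen stratum separately, correlates every selected
#' peripheral category gene against every selected hypothalamic target
#' gene by biweight midcorrelation across the stratum's matched
#' individuals (those present in both tissue matrices), and emits one
#' record per (peripheral gene, target gene, stratum) with the
#' coefficient, the matched-individual count n, and the Student-t
#' two-sided p-value.
#'
#' Pairing policy `"all_pairs"` (default) takes the full cross of category
#' genes and targets, deterministically truncated to `max_pairs` in sorted
#' (peripheral, target) order; `"matched"` restricts to an explicit
#' `pairs` table (e.g. a simulated truth pairing).
#'
#' @param peripheral,hypothalamus [tissue_expression()] objects.
#' @param category_set A [gene_set()]; its `category_kind` labels the
#'   records.
#' @param targets Character vector of hypothalamic target symbols.
#' @param states Data.frame with columns `individual` and `bin`
#'   (`"high"`/`"low"`), e.g. from [bin_individuals()] or
#'   [states_from_truth()].
#' @param min_n Minimum matched individuals per stratum for records to be
#'   emitted (floor 3; strata below it are skipped with a message).
#' @param pairing `"all_pairs"` or `"matched"`.
#' @param pairs Data.frame with `peripheral_gene`, `target_gene` (required
#'   for policy `"matched"`).
#' @param max_pairs Cap on the pair universe under `"all_pairs"`.
#' @return A data.frame of correlation records (possibly empty), columns
#'   tissue, category, peripheral_gene, target_gene, stratum, r, n, p,
#'   method.
#' @export
cross_tissue_correlations <- function(peripheral, hypothalamus,
                                      category_set, targets, states,
                                      min_n = 3,
                                      pairing = c("all_pairs", "matched"),
                                      pairs = NULL, max_pairs = 50000) {
  pairing <- match.arg(pairing)
  min_n <- max(3, min_n)
  genes_p <- intersect(category_set$genes, peripheral$genes)
  genes_t <- intersect(targets, hypothalamus$genes)
  if (length(genes_p) == 0 || length(genes_t) == 0) {
    message("cross_tissue_correlations: no overlapping ",
            if (length(genes_p) == 0) "category genes" else "target genes",
            " for tissue '", peripheral$tissue, "'; no records")
    return(.empty_records())
  }
  if (pairing == "matched") {
    if (is.null(pairs)) {
      stop("cross_tissue_correlations: pairing 'matched' needs a pairs table")
    }
    pairs <- pairs[pairs$peripheral_gene %in% genes_p &
                     pairs$target_gene %in% genes_t, , drop = FALSE]
    pair_df <- unique(pairs[, c("peripheral_gene", "target_gene")])
  } else {
    pair_df <- expand.grid(peripheral_gene = sort(genes_p),
                           target_gene = sort(genes_t),
                           stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
    pair_df <- pair_df[order(pair_df$peripheral_gene, pair_df$target_gene), ]
    if (nrow(pair_df) > max_pairs) {
      message("cross_tissue_correlations: pair universe truncated from ",
              nrow(pair_df), " to ", max_pairs, " (sorted order)")
      pair_df <- pair_df[seq_len(max_pairs), , drop = FALSE]
    }
  }
  if (nrow(pair_df) == 0) {
    return(.empty_records())
  }

  out <- list()
  n_skipped <- 0L
  for (stratum in c("high", "low")) {
    inds <- states$individual[states$bin == stratum]
    matched <- intersect(intersect(inds, peripheral$individuals),
                         hypothalamus$individuals)
    if (length(matched) == 0) {
      stop("cross_tissue_correlations: zero matched individuals in ",
           "tissue '", peripheral$tissue, "', stratum '", stratum, "'")
    }
    if (length(matched) < min_n) {
      n_skipped <- n_skipped + nrow(pair_df)
      message("cross_tissue_correlations: tissue '", peripheral$tissue,
              "', stratum '", stratum, "': matched n = ", length(matched),
              " < min_n = ", min_n, "; ", nrow(pair_df), " pair(s) skipped")
      next
    }
    used_p <- unique(pair_df$peripheral_gene)
    used_t <- unique(pair_df$target_gene)
    bm <- bicor_matrix(peripheral$values[used_p, matched, drop = FALSE],
                       hypothalamus$values[used_t, matched, drop = FALSE])
    idx <- cbind(match(pair_df$peripheral_gene, used_p),
                 match(pair_df$target_gene, used_t))
    r <- bm$r[idx]
    out[[stratum]] <- data.frame(
      tissue = peripheral$tissue, category = category_set$category_kind,
      peripheral_gene = pair_df$peripheral_gene,
      target_gene = pair_df$target_gene, stratum = stratum, r = r,
      n = length(matched), p = correlation_pvalue(r, length(matched)),
      method = bm$method[idx], stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(.empty_records())
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[, .RECORD_COLUMNS]
}

#' Correlation records for several tissues and categories
#'
#' Convenience wrapper running [cross_tissue_correlations()] for every
#' peripheral tissue against the hypothalamus, across a list of category
#' sets, returning records grouped by tissue.
#'
#' @param tissues Named list of peripheral [tissue_expression()] objects.
#' @param hypothalamus The hypothalamic [tissue_expression()].
#' @param category_sets List of [gene_set()] objects (signature sets are
#'   skipped).
#' @param targets,states,... Passed to [cross_tissue_correlations()].
#' @return Named list (by tissue) of record data.frames.
#' @export
correlate_categories <- function(tissues, hypothalamus, category_sets,
                                 targets, states, ...) {
  category_sets <- Filter(function(s) s$category_kind != "signature",
                          category_sets)
  out <- lapply(tissues, function(expr) {
    recs <- lapply(category_sets, function(set) {
      cross_tissue_correlations(expr, hypothalamus, set, targets, states,
                                ...)
    })
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  })
  names(out) <- names(tissues)
  out
}

#' Screen tissues for matching depth and signal
#'
#' A tissue is dropped when (a) it emitted no records or its minimum
#' per-stratum matched-individual count falls below `min_n`
#' ("insufficient matching" — the sparse-donor scenario), or (b) the
#' fraction of its records significant after Benjamini-Hochberg
#' adjustment (adjusted p < `alpha`, adjusted within tissue) is below
#' `min_sig_fraction` ("no significant co-correlations").
#'
#' @param records_by_tissue Named list of record data.frames.
#' @param min_n Minimum per-stratum matched n (default 30).
#' @param min_sig_fraction Minimum fraction of BH-significant records.
#' @param alpha Significance level for adjusted p-values.
#' @return A list of class `tissue_screen`: `kept` (character),
#'   `dropped` (data.frame tissue/reason/detail).
#' @export
screen_tissues <- function(records_by_tissue, min_n = 30,
                           min_sig_fraction = 0.05, alpha = 0.05) {
  kept <- character(0)
  dropped <- list()
  for (tissue in names(records_by_tissue)) {
    recs <- records_by_tissue[[tissue]]
    if (is.null(recs) || nrow(recs) == 0) {
      dropped[[tissue]] <- data.frame(
        tissue = tissue, reason = "insufficient matching",
        detail = "no records emitted", stringsAsFactors = FALSE)
      next
    }
    strata <- unique(recs$stratum)
    n_min <- min(tapply(recs$n, recs$stratum, min))
    if (length(strata) < 2 || n_min < min_n) {
      dropped[[tissue]] <- data.frame(
        tissue = tissue, reason = "insufficient matching",
        detail = paste0("min per-stratum matched n = ", n_min,
                        if (length(strata) < 2) " (a stratum missing)" else "",
                        " < ", min_n),
        stringsAsFactors = FALSE)
      next
    }
    padj <- stats::p.adjust(recs$p, method = "BH")
    sig_frac <- mean(padj < alpha)
    if (sig_frac < min_sig_fraction) {
      dropped[[tissue]] <- data.frame(
        tissue = tissue, reason = "no significant co-correlations",
        detail = sprintf("BH-significant fraction %.4f < %.4f",
                         sig_frac, min_sig_fraction),
        stringsAsFactors = FALSE)
      next
    }
    kept <- c(kept, tissue)
  }
  dropped_df <- if (length(dropped)) {
    do.call(rbind, c(dropped, list(make.row.names = FALSE)))
  } else {
    data.frame(tissue = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
  structure(list(kept = kept, dropped = dropped_df),
            class = "tissue_screen")
}

#' Write / read correlation record tables
#'
#' TSV with the fixed column order tissue, category, peripheral_gene,
#' target_gene, stratum, r, n, p, method.
#'
#' @param records Record data.frame.
#' @param path File path.
#' @return `read_records` returns the record data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.table(records[, .RECORD_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
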