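# Comparison of correlation distributions across tissue x estrogen-stratum
# cells: omnibus Kruskal-Wallis, per-tissue stratum contrasts with BH
# adjustment, and the between-stratum profile-similarity statistic.

#' Kruskal-Wallis test across tissue-by-stratum cells
#'
#' Treats each (tissue, stratum) cell of the record table as one group and
#' applies the tie-corrected Kruskal-Wallis rank test (midranks for ties)
#' to the correlation coefficients, with a chi-square reference on
#' groups - 1 degrees of freedom. This is the omnibus test for an
#' estrogen-stratum-by-tissue effect on co-correlation strength.
#'
#' @param records Correlation record data.frame with at least two
#'   non-empty (tissue, stratum) cells.
#' @return A list: `H` (statistic), `p`, `df`, and `groups` (data.frame
#'   tissue, stratum, n_records, median_r).
#' @export
kw_across_groups <- function(records) {
  if (nrow(records) == 0) {
    stop("kw_across_groups: no records")
  }
  cell <- interaction(records$tissue, records$stratum, drop = TRUE,
                      sep = ":")
  if (nlevels(cell) < 2) {
    stop("kw_across_groups: need at least 2 non-empty (tissue, stratum) groups")
  }
  kt <- stats::kruskal.test(records$r, cell)
  groups <- do.call(rbind, lapply(levels(cell), function(lv) {
    idx <- cell == lv
    parts <- strsplit(lv, ":", fixed = TRUE)[[1]]
    data.frame(tissue = parts[1], stratum = parts[2],
               n_records = sum(idx), median_r = stats::median(records$r[idx]),
               stringsAsFactors = FALSE)
  }))
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), groups = groups)
}

#' Post hoc high-vs-low contrast within one tissue
#'
#' Compares the correlation coefficients of the high and low strata for
#' one tissue: Welch two-sample t test by default (`"welch_t"`), or the
#' Wilcoxon rank-sum alternative (`"rank_sum"`). The direction is taken
#' from the sign of the mean (Welch) or median (rank-sum) difference;
#' identical strata give statistic 0, p = 1 and direction `"none"`.
#'
#' @param records Correlation record data.frame.
#' @param tissue Tissue whose records are contrasted.
#' @param method `"welch_t"` or `"rank_sum"`.
#' @return A list: `statistic`, `p`, `direction` (`"high>low"`,
#'   `"low>high"` or `"none"`), `n_high`, `n_low`.
#' @export
contrast_high_vs_low <- function(records, tissue,
                                 method = c("welch_t", "rank_sum")) {
  method <- match.arg(method)
  recs <- records[records$tissue == tissue, , drop = FALSE]
  hi <- recs$r[recs$stratum == "high"]
  lo <- recs$r[recs$stratum == "low"]
  if (length(hi) == 0 || length(lo) == 0) {
    stop("contrast_high_vs_low: stratum '",
         if (length(hi) == 0) "high" else "low",
         "' empty for tissue '", tissue, "'")
  }
  delta <- if (method == "welch_t") mean(hi) - mean(lo)
           else stats::median(hi) - stats::median(lo)
  if (length(unique(c(hi, lo))) == 1) {
    return(list(statistic = 0, p = 1, direction = "none",
                n_high = length(hi), n_low = length(lo)))
  }
  if (method == "welch_t") {
    tt <- stats::t.test(hi, lo, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(hi, lo, exact = FALSE,
                                              correct = TRUE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  direction <- if (delta > 0) "high>low" else if (delta < 0) "low>high"
               else "none"
  list(statistic = stat, p = p, direction = direction,
       n_high = length(hi), n_low = length(lo))
}

#' Profile similarity between strata
#'
#' Aligns the two strata's correlation coefficients on the
#' (tissue, category, peripheral gene, target gene) key and returns their
#' biweight midcorrelation with its Student-t p-value. A negative value
#' means the strata's cross-tissue communication profiles diverge (pairs
#' strong in one stratum are weak in the other). Unmatched keys are
#' dropped and counted in a message.
#'
#' @param records_high,records_low Record data.frames for the two strata.
#' @return A list: `r`, `p`, `n_pairs`, `method`.
#' @export
profile_similarity <- function(records_high, records_low) {
  key <- function(d) {
    paste(d$tissue, d$category, d$peripheral_gene, d$target_gene,
          sep = "|")
  }
  kh <- key(records_high)
  kl <- key(records_low)
  common <- intersect(kh, kl)
  n_dropped <- (length(kh) - length(common)) + (length(kl) - length(common))
  if (length(common) < 3) {
    stop("profile_similarity: fewer than 3 matched record keys (",
         length(common), ")")
  }
  if (n_dropped > 0) {
    message("profile_similarity: dropped ", n_dropped,
            " unmatched record(s)")
  }
  rh <- records_high$r[match(common, kh)]
  rl <- records_low$r[match(common, kl)]
  bc <- bicor(rh, rl)
  list(r = bc$r, p = correlation_pvalue(bc$r, length(common)),
       n_pairs = length(common), method = bc$method)
}

#' Full comparison for one category
#'
#' Runs the omnibus Kruskal-Wallis across (tissue, stratum) cells, the
#' per-tissue high-vs-low contrasts with Benjamini-Hochberg adjustment
#' across tissues, and the within-category profile similarity between
#' strata.
#'
#' @param records Records of one category (post-screen).
#' @param method Contrast method, see [contrast_high_vs_low()].
#' @param fisher_z Apply the Fisher z transform `atanh(r)` before the
#'   omnibus and contrasts (off by default).
#' @param absolute_r Contrast and test `|r|` instead of signed r (off by
#'   default).
#' @return A list of class `comparison_result`: `category`, `omnibus_H`,
#'   `omnibus_p`, `df`, `groups`, `contrasts` (data.frame tissue,
#'   statistic, raw_p, adjusted_p, direction, n_high, n_low) and
#'   `profile_similarity`.
#' @export
compare_category <- function(records, method = c("welch_t", "rank_sum"),
                             fisher_z = FALSE, absolute_r = FALSE) {
  method <- match.arg(method)
  if (nrow(records) == 0) {
    stop("compare_category: no records")
  }
  category <- unique(records$category)
  if (length(category) != 1) {
    stop("compare_category: records span several categories: ",
         paste(category, collapse = ", "))
  }
  work <- records
  if (absolute_r) {
    work$r <- abs(work$r)
  }
  if (fisher_z) {
    work$r <- atanh(pmax(-1 + 1e-12, pmin(1 - 1e-12, work$r)))
  }
  omnibus <- kw_across_groups(work)
  tissues <- sort(unique(work$tissue))
  contrasts <- do.call(rbind, lapply(tissues, function(t) {
    ct <- contrast_high_vs_low(work, t, method)
    data.frame(tissue = t, statistic = ct$statistic, raw_p = ct$p,
               direction = ct$direction, n_high = ct$n_high,
               n_low = ct$n_low, stringsAsFactors = FALSE)
  }))
  contrasts$adjusted_p <- stats::p.adjust(contrasts$raw_p, method = "BH")
  contrasts <- contrasts[, c("tissue", "statistic", "raw_p", "adjusted_p",
                             "direction", "n_high", "n_low")]
  ps <- profile_similarity(records[records$stratum == "high", , drop = FALSE],
                           records[records$stratum == "low", , drop = FALSE])
  structure(list(category = category, omnibus_H = omnibus$H,
                 omnibus_p = omnibus$p, df = omnibus$df,
                 groups = omnibus$groups, contrasts = contrasts,
                 profile_similarity = ps),
            class = "comparison_result")
}

#' Machine-readable run summary
#'
#' Collects per-category comparison results, the tissue screen report,
#' the overall between-stratum profile similarity across all categories,
#' and a full configuration echo (including the seed) into one
#' serializable structure. [write_summary()] stores it as JSON;
#' [read_summary()] parses it back; [render_summary_text()] produces the
#' human-readable rendering.
#'
#' @param results List of `comparison_result` objects.
#' @param screen Optional `tissue_screen` from [screen_tissues()].
#' @param config Optional configuration list to echo (must be
#'   JSON-serializable).
#' @param all_records Optional combined record data.frame used to compute
#'   the overall (cross-category) profile similarity.
#' @return A list of class `run_summary`.
#' @export
summarize_run <- function(results, screen = NULL, config = NULL,
                          all_records = NULL) {
  categories <- lapply(results, function(res) {
    list(category = res$category, omnibus_H = res$omnibus_H,
         omnibus_p = res$omnibus_p, df = res$df, groups = res$groups,
         contrasts = res$contrasts,
         profile_similarity = res$profile_similarity)
  })
  names(categories) <- vapply(results, `[[`, character(1), "category")
  overall <- NULL
  if (!is.null(all_records) && nrow(all_records) > 0) {
    overall <- tryCatch(
      profile_similarity(
        all_records[all_records$stratum == "high", , drop = FALSE],
        all_records[all_records$stratum == "low", , drop = FALSE]),
      error = function(e) NULL)
  }
  structure(list(
    n_categories = length(results),
    categories = categories,
    overall_profile_similarity = overall,
    screen = if (!is.null(screen)) {
      list(kept = screen$kept, dropped = screen$dropped)
    },
    config_echo = config), class = "run_summary")
}

#' @rdname summarize_run
#' @param summary A `run_summary`.
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname summarize_run
#' @export
read_summary <- function(path) {
  out <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  class(out) <- "run_summary"
  out
}

#' @rdname summarize_run
#' @export
render_summary_text <- function(summary) {
  lines <- c("Cross-tissue co-correlation run summary",
             paste0("categories analysed: ", summary$n_categories))
  if (!is.null(summary$screen)) {
    lines <- c(lines,
               paste0("tissues kept: ",
                      paste(summary$screen$kept, collapse = ", ")))
    dropped <- summary$screen$dropped
    if (!is.null(dropped) && nrow(dropped) > 0) {
      lines <- c(lines, vapply(seq_len(nrow(dropped)), function(i) {
        paste0("tissue dropped: ", dropped$tissue[i], " (",
               dropped$reason[i], "; ", dropped$detail[i], ")")
      }, character(1)))
    }
  }
  for (nm in names(summary$categories)) {
    cat_res <- summary$categories[[nm]]
    lines <- c(lines, "",
               sprintf("category %s: Kruskal-Wallis H = %.4g (df = %d), p = %.4g",
                       cat_res$category, cat_res$omnibus_H,
                       as.integer(cat_res$df), cat_res$omnibus_p))
    ct <- cat_res$contrasts
    if (!is.null(ct) && nrow(ct) > 0) {
      lines <- c(lines, vapply(seq_len(nrow(ct)), function(i) {
        sprintf("  %s: %s (stat %.4g, adj p %.4g)", ct$tissue[i],
                ct$direction[i], ct$statistic[i], ct$adjusted_p[i])
      }, character(1)))
    }
    ps <- cat_res$profile_similarity
    if (!is.null(ps)) {
      lines <- c(lines,
                 sprintf("  profile similarity high vs low: r = %.4g, p = %.4g (n = %d)",
                         ps$r, ps$p, as.integer(ps$n_pairs)))
    }
  }
  ov <- summary$overall_profile_similarity
  if (!is.null(ov)) {
    lines <- c(lines, "",
               sprintf("overall profile similarity: r = %.4g, p = %.4g (n = %d)",
                       ov$r, ov$p, as.integer(ov$n_pairs)))
  }
  if (!is.null(summary$config_echo$seed)) {
    lines <- c(lines, "", paste0("seed: ", summary$config_echo$seed))
  }
  lines
}
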