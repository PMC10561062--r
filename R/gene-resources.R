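# Containers and readers/writers for the standard inputs: per-tissue
# expression TSV, availability TSV, GMT gene sets, ortholog TSV, neuron
# count tables; plus the high-expression target filter and ortholog
# mapping.

#' Tissue expression container
#'
#' One tissue's genes-by-individuals matrix of log-scale expression values.
#' Gene symbols and individual IDs must be unique and all values finite.
#'
#' @param tissue Tissue name.
#' @param values Numeric matrix with gene symbols as rownames and
#'   individual IDs as colnames.
#' @return A list of class `tissue_expression` with fields `tissue`,
#'   `genes`, `individuals`, `values`.
#' @export
tissue_expression <- function(tissue, values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("tissue_expression: values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("tissue_expression: values needs gene rownames and individual colnames")
  }
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop("tissue_expression: empty matrix for tissue '", tissue, "'")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("tissue_expression: duplicate gene symbol(s): ",
         paste(unique(dup), collapse = ", "))
  }
  dupi <- colnames(values)[duplicated(colnames(values))]
  if (length(dupi)) {
    stop("tissue_expression: duplicate individual ID(s): ",
         paste(unique(dupi), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("tissue_expression: non-finite values in tissue '", tissue, "'")
  }
  structure(list(tissue = tissue, genes = rownames(values),
                 individuals = colnames(values), values = values),
            class = "tissue_expression")
}

#' @export
print.tissue_expression <- function(x, ...) {
  cat("tissue_expression '", x$tissue, "': ", length(x$genes), " genes x ",
      length(x$individuals), " individuals\n", sep = "")
  invisible(x)
}

#' Write a tissue expression matrix as TSV
#'
#' First column `gene`, remaining columns one per individual. Individuals
#' without this tissue are simply absent from the column set.
#'
#' @param expr A [tissue_expression()].
#' @param path Output file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a tissue expression TSV
#'
#' Expects a header row of individual IDs and a first column of gene
#' symbols. Malformed input is rejected, never coerced: any non-numeric
#' cell, duplicate gene symbol, or empty matrix is an error.
#'
#' @param path Input TSV path.
#' @param tissue Tissue name to attach.
#' @return A [tissue_expression()].
#' @export
read_expression <- function(path, tissue) {
  if (!file.exists(path)) {
    stop("read_expression: file not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("read_expression: empty expression matrix in ", path)
  }
  genes <- trimws(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("read_expression: duplicate gene symbol(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(apply(is.na(num) & !(raw == "NA"), 1, any))
  if (length(bad)) {
    stop("read_expression: non-numeric cell(s) in row(s) for gene(s): ",
         paste(genes[bad], collapse = ", "))
  }
  if (anyNA(num)) {
    stop("read_expression: missing values (NA) are not allowed in gene(s): ",
         paste(genes[apply(is.na(num), 1, any)], collapse = ", "))
  }
  dimnames(num) <- list(genes, colnames(df)[-1])
  tissue_expression(tissue, num)
}

#' Write / read the individual-by-tissue availability mask
#'
#' TSV with an `individual` column followed by one logical column per
#' tissue (TRUE when that individual's tissue was sampled).
#'
#' @param mask Logical matrix, individuals by tissues, with dimnames.
#' @param path File path.
#' @return `read_availability` returns the logical matrix.
#' @export
write_availability <- function(mask, path) {
  df <- data.frame(individual = rownames(mask), mask, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_availability
#' @export
read_availability <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- df[[1]]
  m
}

#' Gene set container
#'
#' @param name Set label.
#' @param genes Character vector of member symbols (non-empty; duplicates
#'   removed).
#' @param category_kind One of `signature`, `secreted`, `ligand`,
#'   `peptide_hormone`, `feeding`, `other`.
#' @return A list of class `gene_set`.
#' @export
gene_set <- function(name, genes,
                     category_kind = c("other", "signature", "secreted",
                                       "ligand", "peptide_hormone",
                                       "feeding")) {
  category_kind <- match.arg(category_kind)
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) {
    stop("gene_set: set '", name, "' is empty")
  }
  structure(list(name = name, genes = genes, category_kind = category_kind),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#' Duplicate members within a line are kept once, with a warning. An empty
#' file yields an empty list.
#'
#' @param path GMT file path.
#' @param kinds Optional named character vector mapping set names to
#'   category kinds (see [gene_set()]); unmatched sets get kind `"other"`.
#' @return A list of [gene_set()] objects.
#' @export
read_gmt <- function(path, kinds = NULL) {
  if (!file.exists(path)) {
    stop("read_gmt: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list())
  }
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("read_gmt: line ", i, " has fewer than 3 fields")
    }
    members <- trimws(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("read_gmt: duplicate member(s) in set '", fields[1],
              "' (line ", i, "); kept once")
    }
    kind <- if (!is.null(kinds) && fields[1] %in% names(kinds)) {
      kinds[[fields[1]]]
    } else {
      "other"
    }
    gene_set(fields[1], members, kind)
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$category_kind, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Ortholog map container
#'
#' Mouse symbol to set-of-human-symbols map; no empty target sets.
#'
#' @param entries Named list: mouse symbol -> character vector of human
#'   symbols.
#' @return A list of class `ortholog_map`.
#' @export
ortholog_map <- function(entries) {
  entries <- lapply(entries, function(v) unique(trimws(as.character(v))))
  empty <- names(entries)[vapply(entries, length, integer(1)) == 0]
  if (length(empty)) {
    stop("ortholog_map: empty target set for: ", paste(empty, collapse = ", "))
  }
  structure(list(entries = entries), class = "ortholog_map")
}

#' Read / write a two-column ortholog TSV
#'
#' Header `mouse_symbol<TAB>human_symbol`; one row per ortholog pair
#' (mouse symbols may repeat for one-to-many entries).
#'
#' @param path File path.
#' @param map An [ortholog_map()] (for writing).
#' @return `read_ortholog_map` returns an [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df)[1:2], c("mouse_symbol", "human_symbol"))) {
    stop("read_ortholog_map: expected header mouse_symbol<TAB>human_symbol")
  }
  entries <- split(trimws(df$human_symbol), trimws(df$mouse_symbol))
  ortholog_map(entries)
}

#' @rdname read_ortholog_map
#' @export
write_ortholog_map <- function(map, path) {
  mouse <- rep(names(map$entries),
               vapply(map$entries, length, integer(1)))
  human <- unlist(map$entries, use.names = FALSE)
  utils::write.table(
    data.frame(mouse_symbol = mouse, human_symbol = human,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map mouse symbols to human symbols
#'
#' Unmapped symbols are dropped (counted in a message). One-to-many
#' entries contribute all their targets under policy `"all"`, or are
#' dropped as ambiguous under the default policy `"unique"`. Output is
#' deduplicated, preserving first-seen order. Matching is case-sensitive
#' after whitespace trimming.
#'
#' @param genes Character vector of mouse symbols.
#' @param map An [ortholog_map()].
#' @param policy `"unique"` (default) or `"all"`.
#' @return Character vector of human symbols (possibly empty).
#' @export
map_orthologs <- function(genes, map, policy = c("unique", "all")) {
  policy <- match.arg(policy)
  genes <- trimws(as.character(genes))
  out <- character(0)
  n_unmapped <- 0L
  n_ambiguous <- 0L
  for (g in genes) {
    targets <- map$entries[[g]]
    if (is.null(targets)) {
      n_unmapped <- n_unmapped + 1L
    } else if (length(targets) > 1 && policy == "unique") {
      n_ambiguous <- n_ambiguous + 1L
    } else {
      out <- c(out, targets)
    }
  }
  if (n_unmapped > 0 || n_ambiguous > 0) {
    message("map_orthologs: dropped ", n_unmapped, " unmapped and ",
            n_ambiguous, " ambiguous symbol(s) of ", length(genes))
  }
  unique(out)
}

#' Neuron count table from a TSV
#'
#' First column `gene`, remaining columns sample counts (non-negative
#' integers).
#'
#' @param path File path.
#' @param reference_gene Reference symbol that must be present (default
#'   `"Gfap"`).
#' @param counts A `neuron_counts` object (for writing).
#' @return `read_neuron_counts` returns a `neuron_counts` object.
#' @export
read_neuron_counts <- function(path, reference_gene = "Gfap") {
  if (!file.exists(path)) {
    stop("read_neuron_counts: file not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- trimws(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    stop("read_neuron_counts: counts must be finite and non-negative")
  }
  rownames(m) <- genes
  if (!reference_gene %in% genes) {
    stop("read_neuron_counts: reference gene '", reference_gene,
         "' absent from ", path)
  }
  structure(list(counts = m, reference_gene = reference_gene),
            class = "neuron_counts")
}

#' @rdname read_neuron_counts
#' @export
write_neuron_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select highly expressed genes by the counts-above-reference filter
#'
#' Returns the genes whose mean count across samples is strictly greater
#' than the reference gene's mean count (the glial-marker cutoff used to
#' define neuron-enriched, highly expressed target genes). The reference
#' gene itself is excluded by the strict inequality; input order is
#' preserved. Invariant to rescaling all counts by a common positive
#' factor.
#'
#' @param counts A `neuron_counts` object.
#' @return Character vector of gene symbols.
#' @export
filter_high_expressed <- function(counts) {
  m <- counts$counts
  ref <- counts$reference_gene
  if (!ref %in% rownames(m)) {
    stop("filter_high_expressed: reference gene '", ref, "' absent")
  }
  means <- rowMeans(m)
  keep <- means > means[[ref]]
  keep[ref] <- FALSE
  rownames(m)[keep]
}
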