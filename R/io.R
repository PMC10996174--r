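#' Read a delimited expression matrix
#'
#' Reads a genes-by-samples matrix from tab- or comma-separated text (the
#' delimiter is auto-detected from the header line). The first column holds
#' gene identifiers, the header row sample identifiers. Rows with any
#' missing value are dropped (with a message); duplicate gene identifiers
#' (multiple probes per gene) are collapsed to their per-sample mean via
#' [collapse_probes()].
#'
#' @param path Path to the file.
#' @return A tibble whose first column is `gene` and whose remaining columns
#'   are numeric sample columns.
#' @export
read_expression <- function(path) {
  delim <- detect_delim(path)
  tbl <- suppressWarnings(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      col_types = readr::cols(
                        readr::col_character(),
                        .default = readr::col_double()
                      ))
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop("Non-numeric cell at row ", prob$row[1], ", column ", prob$col[1],
         " of ", path, call. = FALSE)
  }
  if (nrow(tbl) == 0L || ncol(tbl) < 2L) {
    stop("Expression file ", path, " is empty or has no sample columns.",
         call. = FALSE)
  }
  names(tbl)[1] <- "gene"
  n_missing <- sum(!stats::complete.cases(tbl))
  if (n_missing > 0) {
    message(n_missing, " expression row(s) with missing values dropped.")
    tbl <- tbl[stats::complete.cases(tbl), , drop = FALSE]
  }
  collapse_probes(tbl)
}

#' Collapse multiple probes of a gene to their mean
#'
#' Rows sharing a gene identifier are averaged per sample; rows with a
#' missing/empty identifier (probes without a gene symbol) are dropped.
#' First-appearance row order is preserved.
#'
#' @param expression Tibble as returned by [read_expression()] (first column
#'   gene identifiers).
#' @return A tibble with one row per gene.
#' @export
collapse_probes <- function(expression) {
  tbl <- tibble::as_tibble(expression)
  names(tbl)[1] <- "gene"
  tbl <- tbl[!is.na(tbl$gene) & tbl$gene != "", , drop = FALSE]
  if (!anyDuplicated(tbl$gene)) return(tbl)
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$gene),
    dplyr::across(dplyr::everything(), mean), .groups = "drop"
  )
  out[match(unique(tbl$gene), out$gene), , drop = FALSE]
}

#' Read an undirected edge list
#'
#' Accepts two-column (`gene_a gene_b`) or three-column STRING-style
#' (`gene_a gene_b score`) delimited text, with or without a header line.
#' Edges are canonicalized (lexicographic gene order), deduplicated, and
#' self-loops are dropped with a warning. When a score column is present an
#' optional minimum-score filter is applied before deduplication.
#'
#' @param path Path to the file.
#' @param score_threshold Keep only edges with `score >= score_threshold`;
#'   `NULL` (default) keeps all edges.
#' @return A tibble `gene_a`, `gene_b` (and `score` if present) in canonical
#'   order.
#' @export
read_network <- function(path, score_threshold = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("Network file ", path, " is empty.",
                                call. = FALSE)
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1]))
    "," else " "
  parts <- strsplit(lines, delim, fixed = FALSE)
  parts <- lapply(parts, function(p) p[nzchar(p)])
  n_col <- length(parts[[1]])
  if (!n_col %in% c(2L, 3L)) {
    stop("Line 1 of ", path, ": expected 2 or 3 columns, found ", n_col,
         call. = FALSE)
  }
  bad <- which(lengths(parts) != n_col)
  if (length(bad)) {
    stop("Line ", bad[1], " of ", path, ": expected ", n_col,
         " columns, found ", lengths(parts)[bad[1]], call. = FALSE)
  }
  tbl <- tibble::tibble(
    gene_a = vapply(parts, `[`, "", 1),
    gene_b = vapply(parts, `[`, "", 2)
  )
  has_header <- FALSE
  if (n_col == 3L) {
    score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
    if (is.na(score[1]) && length(score) > 1) { # header line
      has_header <- TRUE
      tbl <- tbl[-1, , drop = FALSE]
      score <- score[-1]
    }
    if (anyNA(score)) {
      stop("Line ", which(is.na(score))[1] + has_header, " of ", path,
           ": non-numeric score.", call. = FALSE)
    }
    tbl$score <- score
    if (!is.null(score_threshold)) {
      tbl <- tbl[tbl$score >= score_threshold, , drop = FALSE]
    }
  } else if (identical(tolower(tbl$gene_a[1]), "gene_a")) {
    tbl <- tbl[-1, , drop = FALSE]
  }
  canonical_edges(tbl)
}

#' Canonicalize an undirected edge table
#'
#' Orders the two genes of each edge lexicographically, drops self-loops
#' (with a warning) and duplicate edges, and sorts rows canonically.
#'
#' @param network Data frame whose first two columns are gene identifiers.
#' @return A tibble `gene_a`, `gene_b` (plus any extra columns kept from the
#'   first occurrence of each edge).
#' @export
canonical_edges <- function(network) {
  tbl <- tibble::as_tibble(network)
  if (ncol(tbl) < 2L) stop("An edge table needs two gene columns.",
                           call. = FALSE)
  names(tbl)[1:2] <- c("gene_a", "gene_b")
  tbl$gene_a <- as.character(tbl$gene_a)
  tbl$gene_b <- as.character(tbl$gene_b)
  loops <- tbl$gene_a == tbl$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from the network.",
            call. = FALSE)
    tbl <- tbl[!loops, , drop = FALSE]
  }
  swap <- tbl$gene_a > tbl$gene_b
  tmp <- tbl$gene_a[swap]
  tbl$gene_a[swap] <- tbl$gene_b[swap]
  tbl$gene_b[swap] <- tmp
  tbl <- tbl[!duplicated(edge_label(tbl)), , drop = FALSE]
  tbl[order(tbl$gene_a, tbl$gene_b), , drop = FALSE]
}

#' Read a sample metadata table
#'
#' Delimited table with columns `sample_id`, `cohort`
#' (`reference`/`case`), `stage`, and optionally `survival_time` (years)
#' and `event` (0/1).
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  delim <- detect_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  need <- c("sample_id", "cohort")
  if (!all(need %in% names(tbl))) {
    stop("Metadata must have columns sample_id and cohort.", call. = FALSE)
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  if ("stage" %in% names(tbl)) tbl$stage <- as.character(tbl$stage)
  tbl
}

#' Intersect expression, metadata and network into an analysis dataset
#'
#' Restricts the network to genes present in the expression matrix (genes
#' absent from the network stay in the matrix but are unused), checks
#' cohort/stage declarations, and derives the reference/case partitions in
#' declared stage order. A summary (genes kept, edges kept, samples per
#' stage) is emitted as a message.
#'
#' @param expression Expression tibble or matrix (see [ere_fit()]).
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @param network Edge tibble (see [read_network()]).
#' @param stage_order Optional explicit stage order; defaults to order of
#'   first appearance among case rows.
#' @return A list of class `ere_dataset` with elements `expression`,
#'   `metadata`, `network`, `reference_ids`, `case_ids` (a named list, one
#'   vector per stage in order), `stage_order`.
#' @export
intersect_and_partition <- function(expression, metadata, network,
                                    stage_order = NULL) {
  mat <- as_expression_matrix(expression)
  meta <- check_metadata(metadata, colnames(mat))
  edges <- canonical_edges(network)
  keep <- edges$gene_a %in% rownames(mat) & edges$gene_b %in% rownames(mat)
  if (any(!keep)) {
    message(sum(!keep), " edge(s) dropped: gene absent from expression matrix.")
  }
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("No network edge survives the gene intersection.", call. = FALSE)
  }
  case_meta <- meta[meta$cohort == "case", , drop = FALSE]
  if (is.null(stage_order)) stage_order <- unique(case_meta$stage)
  case_ids <- lapply(stage_order, function(s) {
    ids <- case_meta$sample_id[case_meta$stage == s]
    if (length(ids) == 0L) {
      stop("Declared stage '", s, "' has no samples.", call. = FALSE)
    }
    ids
  })
  names(case_ids) <- stage_order
  message("Dataset: ", length(union(edges$gene_a, edges$gene_b)),
          " network genes, ", nrow(edges), " edges, ",
          sum(meta$cohort == "reference"), " reference samples; case ",
          paste(sprintf("%s=%d", stage_order, lengths(case_ids)),
                collapse = ", "))
  structure(
    list(expression = expression_to_tibble(mat), metadata = meta,
         network = edges,
         reference_ids = meta$sample_id[meta$cohort == "reference"],
         case_ids = case_ids, stage_order = stage_order),
    class = "ere_dataset"
  )
}

#' Write tab-separated pipeline tables
#'
#' Thin wrappers over [readr::write_tsv()] so that every artifact written by
#' the package round-trips losslessly (15 significant digits) and is plain
#' tab-separated text.
#'
#' @param x Table to write (for `write_expression`, a tibble with a `gene`
#'   first column or a matrix with gene rownames).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path) {
  if (is.matrix(x)) x <- expression_to_tibble(x)
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_expression
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_expression
#' @export
write_network <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

detect_delim <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  if (length(header) == 0L) stop("File ", path, " is empty.", call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

as_expression_matrix <- function(expression) {
  if (is.matrix(expression)) {
    mat <- expression
  } else {
    tbl <- tibble::as_tibble(expression)
    mat <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(mat) <- as.character(tbl[[1]])
  }
  if (!is.numeric(mat) || !all(is.finite(mat))) {
    stop("Expression matrix must be numeric and finite.", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("Duplicate gene identifiers; collapse probes first ",
         "(see collapse_probes()).", call. = FALSE)
  }
  mat
}

expression_to_tibble <- function(mat) {
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(mat)),
                          tibble::as_tibble(mat)))
}

check_metadata <- function(metadata, sample_cols) {
  meta <- tibble::as_tibble(metadata)
  need <- c("sample_id", "cohort")
  if (!all(need %in% names(meta))) {
    stop("Metadata must have columns sample_id and cohort.", call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (!all(meta$cohort %in% c("reference", "case"))) {
    stop("`cohort` must be 'reference' or 'case'.", call. = FALSE)
  }
  absent <- setdiff(meta$sample_id, sample_cols)
  if (length(absent)) {
    stop("Metadata sample(s) absent from the expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  if (!"stage" %in% names(meta)) meta$stage <- NA_character_
  meta$stage <- as.character(meta$stage)
  if (any(meta$cohort == "case" & is.na(meta$stage))) {
    stop("Every case sample needs a stage label.", call. = FALSE)
  }
  meta
}
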