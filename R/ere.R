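#' Fit per-edge, per-sample relative entropy scores
#'
#' The workhorse of the package. For every gene, a reference probability
#' vector is fitted by Gaussian KDE over the reference cohort
#' ([kde_probability_vector()]); for every case sample, the case-cohort
#' probability of each gene's observed value is fitted the same way over the
#' case cohort in scope. Each network edge \eqn{\langle i, j\rangle} and case
#' sample \eqn{k} then receives the symmetric local score
#' \deqn{H^k(i,j) = \tfrac12\left(H_{\langle i,j\rangle} +
#'   H_{\langle j,i\rangle}\right),}
#' where the directed terms are computed by [directed_local_ere()].
#'
#' Genes with zero variance in the reference cohort or in any case cohort in
#' scope cannot be profiled; they are dropped together with their incident
#' edges, with a warning. Probabilities are floored at `1e-300` before logs;
#' the number of floored entries is recorded in the fit.
#'
#' @param expression A data frame whose first column holds gene identifiers
#'   and whose remaining columns are numeric per-sample expression values
#'   (as returned by [read_expression()] or [simulate_cohorts()]), or a
#'   numeric matrix with gene rownames and sample colnames. A simulation
#'   object from [simulate_cohorts()] may also be passed directly, in which
#'   case `metadata` and `network` are taken from it.
#' @param metadata Data frame with columns `sample_id`, `cohort`
#'   (`"reference"`/`"case"`) and `stage` (case samples only; `NA` allowed
#'   for reference rows).
#' @param network Data frame whose first two columns name the genes of each
#'   undirected edge (optional third column is ignored here; see
#'   [read_network()] for score filtering).
#' @param top_fraction Default fraction of edges forming each sample's
#'   high-entropy set \eqn{S}; stored in the fit and used by downstream
#'   helpers unless overridden.
#' @param case_scope `"all"` (default): one case cohort pooling every case
#'   sample, so that a sample whose expression is rare *across the whole
#'   case population* gets a low case probability and hence a high entropy
#'   score. `"per_stage"`: the case probability vector for a sample at
#'   stage \eqn{t} is fitted on that stage's case samples only. The pooled
#'   scope is the default because normalized KDE probability vectors
#'   evaluated at a cohort's own points are invariant under location-scale
#'   changes of that cohort: a stage whose module genes merely fluctuate
#'   more is invisible to a per-stage fit, while the pooled fit sees its
#'   samples in the tails of the case-wide density. Per-stage remains
#'   available for sensitivity analysis; stage signals \eqn{H(t)} are
#'   stage-specific under either scope because each stage contributes its
#'   own samples.
#' @param stage_order Character vector giving the progression order of
#'   stages. Defaults to order of first appearance in `metadata`.
#' @param sigma_denominator Passed to [kde_probability_vector()].
#' @return An object of class `ere_fit`; see [tidy.ere_fit()],
#'   [sample_ere()], [stage_series()], [detect_critical()],
#'   [classify_edges()].
#' @export
ere_fit <- function(expression, metadata = NULL, network = NULL,
                    top_fraction = 0.05,
                    case_scope = c("all", "per_stage"),
                    stage_order = NULL,
                    sigma_denominator = c("n-1", "n")) {
  case_scope <- match.arg(case_scope)
  sigma_denominator <- match.arg(sigma_denominator)
  if (inherits(expression, "ere_simulation")) {
    sim <- expression
    expression <- sim$expression
    if (is.null(metadata)) metadata <- sim$metadata
    if (is.null(network)) network <- sim$network
  }
  if (is.null(metadata) || is.null(network)) {
    stop("`metadata` and `network` are required.", call. = FALSE)
  }
  if (!(is.numeric(top_fraction) && length(top_fraction) == 1L &&
        top_fraction > 0 && top_fraction <= 1)) {
    stop("`top_fraction` must lie in (0, 1].", call. = FALSE)
  }

  mat <- as_expression_matrix(expression)
  meta <- check_metadata(metadata, colnames(mat))
  edges <- canonical_edges(network)

  ref_ids <- meta$sample_id[meta$cohort == "reference"]
  case_meta <- meta[meta$cohort == "case", , drop = FALSE]
  if (length(ref_ids) < 2L) {
    stop("Need at least 2 reference samples.", call. = FALSE)
  }
  if (nrow(case_meta) == 0L) stop("No case samples in metadata.", call. = FALSE)

  if (is.null(stage_order)) stage_order <- unique(case_meta$stage)
  if (!setequal(stage_order, unique(case_meta$stage))) {
    stop("`stage_order` must cover exactly the stages present in the case ",
         "metadata.", call. = FALSE)
  }
  case_meta$stage <- as.character(case_meta$stage)
  # case samples kept grouped by declared stage order
  case_meta <- case_meta[order(match(case_meta$stage, stage_order)), ,
                         drop = FALSE]

  # restrict network to genes present in the matrix
  keep <- edges$gene_a %in% rownames(mat) & edges$gene_b %in% rownames(mat)
  if (any(!keep)) {
    message(sum(!keep), " edge(s) dropped: gene absent from expression matrix.")
    edges <- edges[keep, , drop = FALSE]
  }

  scope_groups <- if (case_scope == "per_stage") {
    split(case_meta$sample_id, factor(case_meta$stage, levels = stage_order))
  } else {
    list(all = case_meta$sample_id)
  }
  for (nm in names(scope_groups)) {
    if (length(scope_groups[[nm]]) < 2L) {
      stop("Case cohort '", nm, "' has fewer than 2 samples; ",
           "KDE profiles need at least 2.", call. = FALSE)
    }
  }

  # drop genes that are degenerate in the reference or in any scope cohort
  net_genes <- union(edges$gene_a, edges$gene_b)
  bad <- degenerate_genes(mat[net_genes, ref_ids, drop = FALSE])
  for (ids in scope_groups) {
    bad <- union(bad, degenerate_genes(mat[net_genes, ids, drop = FALSE]))
  }
  if (length(bad)) {
    warning("Dropping ", length(bad), " zero-variance gene(s) and incident ",
            "edges: ", paste(bad, collapse = ", "), call. = FALSE)
    edges <- edges[!(edges$gene_a %in% bad | edges$gene_b %in% bad), ,
                   drop = FALSE]
  }
  if (nrow(edges) == 0L) {
    stop("No usable network edges after gene filtering.", call. = FALSE)
  }
  genes <- union(edges$gene_a, edges$gene_b)

  ref_stats <- profile_stats(mat[genes, ref_ids, drop = FALSE],
                             sigma_denominator)
  ref_c <- stats::setNames(ref_stats$neg_entropy, genes)

  n_clipped <- ref_stats$n_clipped
  logp_case <- matrix(NA_real_, nrow = length(genes), ncol = nrow(case_meta),
                      dimnames = list(genes, case_meta$sample_id))
  for (ids in scope_groups) {
    st <- profile_stats(mat[genes, ids, drop = FALSE], sigma_denominator)
    logp_case[, ids] <- st$logp
    n_clipped <- n_clipped + st$n_clipped
  }
  if (n_clipped > 0) {
    message(n_clipped, " KDE probabilit(ies) floored at 1e-300 before log.")
  }

  # H^k(i,j) = (C_i + C_j)/2 - (log p_c(y_ik) + log p_c(y_jk))/2,
  # with C_g = sum p_r log p_r of gene g's reference probability vector.
  values <- (ref_c[edges$gene_a] + ref_c[edges$gene_b]) / 2 -
    (logp_case[edges$gene_a, , drop = FALSE] +
       logp_case[edges$gene_b, , drop = FALSE]) / 2
  dimnames(values) <- list(edge_label(edges), case_meta$sample_id)

  new_ere_fit(values = values, edges = edges, samples = case_meta,
              stage_order = stage_order, top_fraction = top_fraction,
              case_scope = case_scope, ref_neg_entropy = ref_c,
              n_clipped = n_clipped)
}

new_ere_fit <- function(values, edges, samples, stage_order, top_fraction,
                        case_scope = NA_character_, ref_neg_entropy = NULL,
                        n_clipped = NA_integer_) {
  stopifnot(nrow(values) == nrow(edges), ncol(values) == nrow(samples),
            all(is.finite(values)))
  structure(
    list(values = values, edges = tibble::as_tibble(edges),
         samples = tibble::as_tibble(samples), stage_order = stage_order,
         top_fraction = top_fraction, case_scope = case_scope,
         ref_neg_entropy = ref_neg_entropy, n_clipped = n_clipped),
    class = "ere_fit"
  )
}

#' Rebuild a fit object from a long score table
#'
#' Reassembles the edges-by-samples score matrix from a long-format table
#' (as written by [tidy.ere_fit()] or the command-line `run` step), so that
#' downstream stage detection and biomarker calling can start from files.
#'
#' @param scores Data frame with columns `gene_a`, `gene_b`, `sample_id`,
#'   `ere`, and optionally `stage`.
#' @param metadata Optional metadata table supplying `stage` (and survival
#'   fields) per `sample_id`; required if `scores` lacks a `stage` column.
#' @param stage_order,top_fraction See [ere_fit()].
#' @return An `ere_fit` object (without reference profiles).
#' @export
ere_fit_from_scores <- function(scores, metadata = NULL, stage_order = NULL,
                                top_fraction = 0.05) {
  need <- c("gene_a", "gene_b", "sample_id", "ere")
  if (!all(need %in% names(scores))) {
    stop("`scores` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scores <- tibble::as_tibble(scores)
  if (!"stage" %in% names(scores)) {
    if (is.null(metadata) || !all(c("sample_id", "stage") %in% names(metadata))) {
      stop("Supply `metadata` with sample_id and stage, or a stage column.",
           call. = FALSE)
    }
    scores$stage <- metadata$stage[match(scores$sample_id, metadata$sample_id)]
  }
  edges <- canonical_edges(unique(scores[, c("gene_a", "gene_b")]))
  sample_ids <- unique(scores$sample_id)
  samples <- tibble::tibble(
    sample_id = sample_ids,
    cohort = "case",
    stage = scores$stage[match(sample_ids, scores$sample_id)]
  )
  if (is.null(stage_order)) stage_order <- unique(samples$stage)
  values <- matrix(NA_real_, nrow(edges), length(sample_ids),
                   dimnames = list(edge_label(edges), sample_ids))
  idx <- cbind(match(edge_label(scores[, c("gene_a", "gene_b")]),
                     rownames(values)),
               match(scores$sample_id, colnames(values)))
  values[idx] <- scores$ere
  if (anyNA(values)) {
    stop("`scores` does not cover every edge x sample combination.",
         call. = FALSE)
  }
  new_ere_fit(values, edges, samples, stage_order, top_fraction)
}

#' Per-sample aggregate entropy over the high-scoring edge set
#'
#' For each case sample the \eqn{M} edges with the largest local scores form
#' the signaling set \eqn{S} (\eqn{M = \max(1, \lfloor f \cdot E\rfloor)} for
#' `top_fraction` \eqn{f} and \eqn{E} edges; ties at the cutoff are broken by
#' canonical edge order so results are deterministic), and the sample score
#' is \eqn{H^k = \frac1M \sum_{\langle i,j\rangle \in S} H^k(i,j)}.
#'
#' @param fit An [ere_fit()] object.
#' @param top_fraction Fraction of edges in \eqn{S}; defaults to the fit's.
#' @return A tibble with one row per case sample: `sample_id`, `stage`, `m`,
#'   `h_k`, and a list-column `selected_edges` of edge labels.
#' @export
sample_ere <- function(fit, top_fraction = NULL) {
  stopifnot(inherits(fit, "ere_fit"))
  f <- top_fraction %||% fit$top_fraction
  if (!(is.numeric(f) && length(f) == 1L && f > 0 && f <= 1)) {
    stop("`top_fraction` must lie in (0, 1].", call. = FALSE)
  }
  m <- top_set_size(f, nrow(fit$values))
  rank_key <- canonical_rank(fit$edges)
  sel <- lapply(seq_len(ncol(fit$values)), function(k) {
    top_edge_indices(fit$values[, k], m, rank_key)
  })
  tibble::tibble(
    sample_id = fit$samples$sample_id,
    stage = fit$samples$stage,
    m = m,
    h_k = vapply(seq_along(sel), function(k) mean(fit$values[sel[[k]], k]),
                 numeric(1)),
    selected_edges = lapply(sel, function(i) rownames(fit$values)[i])
  )
}

#' High-entropy set membership per edge and sample
#'
#' Boolean membership of every edge in every sample's top-`top_fraction` set
#' \eqn{S}, using exactly the selection rule of [sample_ere()]; each sample's
#' membership count equals \eqn{M}.
#'
#' @inheritParams sample_ere
#' @return A tibble with columns `gene_a`, `gene_b`, `edge`, `sample_id`,
#'   `in_top`.
#' @export
high_ere_membership <- function(fit, top_fraction = NULL) {
  stopifnot(inherits(fit, "ere_fit"))
  f <- top_fraction %||% fit$top_fraction
  m <- top_set_size(f, nrow(fit$values))
  rank_key <- canonical_rank(fit$edges)
  memb <- matrix(FALSE, nrow(fit$values), ncol(fit$values),
                 dimnames = dimnames(fit$values))
  for (k in seq_len(ncol(memb))) {
    memb[top_edge_indices(fit$values[, k], m, rank_key), k] <- TRUE
  }
  tibble::tibble(
    gene_a = rep(fit$edges$gene_a, times = ncol(memb)),
    gene_b = rep(fit$edges$gene_b, times = ncol(memb)),
    edge = rep(rownames(memb), times = ncol(memb)),
    sample_id = rep(colnames(memb), each = nrow(memb)),
    in_top = as.vector(memb)
  )
}

# M = max(1, floor(f * E))
top_set_size <- function(top_fraction, n_edges) {
  max(1L, as.integer(floor(top_fraction * n_edges)))
}

# indices of the m largest values; ties broken by canonical edge rank
top_edge_indices <- function(v, m, rank_key) {
  order(-v, rank_key)[seq_len(m)]
}

canonical_rank <- function(edges) {
  order(order(edges$gene_a, edges$gene_b))
}

edge_label <- function(edges) paste(edges$gene_a, edges$gene_b, sep = "--")

#' @export
print.ere_fit <- function(x, ...) {
  cat("<ere_fit> ", nrow(x$values), " edges x ", ncol(x$values),
      " case samples\n", sep = "")
  cat("  stages: ", paste(x$stage_order, collapse = " < "), "\n", sep = "")
  cat("  case scope: ", x$case_scope, "; top fraction: ", x$top_fraction,
      "\n", sep = "")
  invisible(x)
}
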