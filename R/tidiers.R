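#' Tidy a fitted entropy object into a long score table
#'
#' One row per edge and case sample, suitable for heatmaps and for feeding
#' the file-based pipeline back through [ere_fit_from_scores()].
#'
#' @param x An [ere_fit()] object.
#' @param ... Unused.
#' @return A tibble `gene_a`, `gene_b`, `edge`, `sample_id`, `stage`, `ere`.
#' @export
tidy.ere_fit <- function(x, ...) {
  tibble::tibble(
    gene_a = rep(x$edges$gene_a, times = ncol(x$values)),
    gene_b = rep(x$edges$gene_b, times = ncol(x$values)),
    edge = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    stage = rep(x$samples$stage, each = nrow(x$values)),
    ere = as.vector(x$values)
  )
}

#' One-row summary of a fitted entropy object
#'
#' @inheritParams tidy.ere_fit
#' @return A tibble with `n_edges`, `n_samples`, `n_stages`, `case_scope`,
#'   `top_fraction`, `n_clipped`.
#' @export
glance.ere_fit <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$values), n_samples = ncol(x$values),
    n_stages = length(x$stage_order), case_scope = x$case_scope,
    top_fraction = x$top_fraction, n_clipped = x$n_clipped
  )
}

#' Heatmap of local entropy scores
#'
#' Edges by samples, samples grouped by stage — the standard view for
#' spotting the collective entropy rise at a critical stage.
#'
#' @param object An [ere_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ere_fit <- function(object, ...) {
  tbl <- tidy(object)
  tbl$sample_id <- factor(tbl$sample_id, levels = object$samples$sample_id)
  tbl$stage <- factor(tbl$stage, levels = object$stage_order)
  ggplot2::ggplot(tbl, ggplot2::aes(.data$sample_id, .data$edge,
                                    fill = .data$ere)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~stage, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "local ERE") +
    ggplot2::labs(x = "case sample", y = "network edge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Tidy a stage report
#'
#' @param x An [detect_critical()] report.
#' @param ... Unused.
#' @return The per-stage tibble: `stage`, `n_t`, `h_t`, `reference_mean`,
#'   `statistic`, `df`, `p_value`, `critical`.
#' @export
tidy.ere_stage_report <- function(x, ...) x$stages

#' One-row summary of a stage report
#'
#' @inheritParams tidy.ere_stage_report
#' @return A tibble with `critical_stage`, `alpha`, `reference`,
#'   `n_stages`, `n_tested`, `n_flagged`.
#' @export
glance.ere_stage_report <- function(x, ...) {
  tibble::tibble(
    critical_stage = x$critical_stage, alpha = x$alpha,
    reference = x$reference, n_stages = nrow(x$stages),
    n_tested = sum(!is.na(x$stages$p_value)),
    n_flagged = sum(x$stages$critical)
  )
}

#' Stage-series plot with the flagged critical stage highlighted
#'
#' @param object An [detect_critical()] report.
#' @param ... Unused.
#' @return A ggplot object showing \eqn{H(t)} across stages; the flagged
#'   critical stage (if any) is marked.
#' @export
autoplot.ere_stage_report <- function(object, ...) {
  tbl <- object$stages
  tbl$stage <- factor(tbl$stage, levels = tbl$stage)
  p <- ggplot2::ggplot(tbl, ggplot2::aes(.data$stage, .data$h_t, group = 1)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$critical), size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(x = "stage", y = "mean sample ERE  H(t)") +
    ggplot2::theme_minimal()
  if (!is.na(object$critical_stage)) {
    p <- p + ggplot2::geom_vline(xintercept = object$critical_stage,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
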