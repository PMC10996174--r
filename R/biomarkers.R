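#' Split patients into long- and short-survival groups
#'
#' Patients surviving past `cut_years` (strictly) form the long-survival
#' group regardless of censoring; patients with an observed death at or
#' before the cut form the short-survival group. Patients censored at or
#' before the cut are excluded: their group is unknowable.
#'
#' @param records Data frame with columns `sample_id`, `survival_time`
#'   (years) and `event` (logical or 0/1; `TRUE` = death observed).
#' @param cut_years Survival cut in years, default 5.
#' @return A tibble `sample_id`, `survival_time`, `event`, `group` with
#'   `group` one of `"long"`, `"short"`, `"excluded"`.
#' @export
survival_groups <- function(records, cut_years = 5) {
  need <- c("sample_id", "survival_time", "event")
  if (!all(need %in% names(records)) || nrow(records) == 0L) {
    stop("`records` must be non-empty with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rec <- tibble::as_tibble(records)[need]
  if (anyDuplicated(rec$sample_id)) {
    stop("Duplicate sample_id in survival records.", call. = FALSE)
  }
  if (!all(is.finite(rec$survival_time)) || any(rec$survival_time < 0)) {
    stop("`survival_time` must be finite and non-negative.", call. = FALSE)
  }
  rec$event <- as.logical(rec$event)
  rec$group <- dplyr::case_when(
    rec$survival_time > cut_years ~ "long",
    rec$event ~ "short",
    .default = "excluded"
  )
  rec
}

#' Call positive and negative prognostic edge biomarkers
#'
#' An edge is a *positive* biomarker when it sits in the per-sample
#' high-entropy set of strictly more than `prevalence_threshold` of the
#' long-survival group's samples, and a *negative* biomarker for the
#' short-survival group; the threshold is strict ("over 80%" at the
#' default). An edge exceeding the threshold in both groups has no
#' unambiguous prognostic direction and is called `"none"` with both
#' prevalences reported.
#'
#' For prognostic calling the fit should normally pool all case samples into
#' one case cohort (`ere_fit(..., case_scope = "all")`).
#'
#' @inheritParams sample_ere
#' @param records Survival records as in [survival_groups()], or the output
#'   of [survival_groups()] itself (a `group` column is recognised).
#' @param prevalence_threshold Strict prevalence threshold, default 0.8.
#' @param cut_years Passed to [survival_groups()] when `records` has no
#'   `group` column.
#' @return A tibble `gene_a`, `gene_b`, `edge`, `call`, `prevalence_long`,
#'   `prevalence_short`, `n_long`, `n_short`. Zero rows (with a warning)
#'   when either survival group is empty among the fitted samples.
#' @export
classify_edges <- function(fit, records, prevalence_threshold = 0.8,
                           top_fraction = NULL, cut_years = 5) {
  stopifnot(inherits(fit, "ere_fit"))
  groups <- if ("group" %in% names(records)) {
    tibble::as_tibble(records)
  } else {
    survival_groups(records, cut_years)
  }
  long_ids <- intersect(groups$sample_id[groups$group == "long"],
                        fit$samples$sample_id)
  short_ids <- intersect(groups$sample_id[groups$group == "short"],
                         fit$samples$sample_id)
  empty_calls <- tibble::tibble(
    gene_a = character(), gene_b = character(), edge = character(),
    call = character(), prevalence_long = numeric(),
    prevalence_short = numeric(), n_long = integer(), n_short = integer()
  )
  if (length(long_ids) == 0L || length(short_ids) == 0L) {
    warning("Empty long- or short-survival group; no biomarker calls made.",
            call. = FALSE)
    return(empty_calls)
  }
  memb <- high_ere_membership(fit, top_fraction)
  wide <- matrix(memb$in_top, nrow = nrow(fit$edges),
                 dimnames = list(edge_label(fit$edges),
                                 fit$samples$sample_id))
  prev_long <- rowMeans(wide[, long_ids, drop = FALSE])
  prev_short <- rowMeans(wide[, short_ids, drop = FALSE])
  pos <- prev_long > prevalence_threshold
  neg <- prev_short > prevalence_threshold
  call <- dplyr::case_when(
    pos & neg ~ "none", # ambiguous prognostic direction
    pos ~ "positive",
    neg ~ "negative",
    .default = "none"
  )
  tibble::tibble(
    gene_a = fit$edges$gene_a, gene_b = fit$edges$gene_b,
    edge = edge_label(fit$edges), call = call,
    prevalence_long = unname(prev_long), prevalence_short = unname(prev_short),
    n_long = length(long_ids), n_short = length(short_ids)
  )
}

#' Stratify patients by one edge's entropy scores
#'
#' Splits the fitted case samples at the median of the edge's local scores:
#' strictly above the median is the high-entropy group, the rest (including
#' median ties) the low-entropy group. The output joins directly with
#' survival records for Kaplan--Meier / log-rank analysis (e.g.
#' `survival::survdiff(Surv(survival_time, event) ~ group, data = .)`).
#'
#' @inheritParams sample_ere
#' @param gene_a,gene_b The two genes of the edge (order irrelevant).
#' @return A tibble `sample_id`, `stage`, `ere`, `group` (`"high"`/`"low"`).
#' @export
stratify_by_edge <- function(fit, gene_a, gene_b) {
  stopifnot(inherits(fit, "ere_fit"))
  lab <- edge_label(canonical_edges(tibble::tibble(gene_a = gene_a,
                                                   gene_b = gene_b)))
  i <- match(lab, rownames(fit$values))
  if (is.na(i)) stop("Edge ", lab, " not present in the fit.", call. = FALSE)
  v <- fit$values[i, ]
  med <- stats::median(v)
  grp <- ifelse(v > med, "high", "low")
  if (!any(grp == "high")) {
    warning("All samples tie at the median for edge ", lab,
            "; high-entropy group is empty.", call. = FALSE)
  }
  tibble::tibble(sample_id = fit$samples$sample_id,
                 stage = fit$samples$stage, ere = unname(v),
                 group = unname(grp))
}
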