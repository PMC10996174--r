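#' Per-stage network entropy series
#'
#' Groups the per-sample scores \eqn{H^k} of [sample_ere()] by stage and
#' returns the stage means \eqn{H(t) = \frac{1}{N(t)} \sum_k H^k(t)} together
#' with the stage sizes \eqn{N(t)}.
#'
#' @inheritParams sample_ere
#' @return A tibble with columns `stage` (in progression order), `n_t`, `h_t`.
#' @export
stage_series <- function(fit, top_fraction = NULL) {
  per_sample <- sample_ere(fit, top_fraction)
  per_sample$stage <- factor(per_sample$stage, levels = fit$stage_order)
  out <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$stage),
    n_t = dplyr::n(), h_t = mean(.data$h_k), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$stage)
  if (any(out$n_t < 2L)) {
    stop("Every stage needs at least 2 case samples.", call. = FALSE)
  }
  dplyr::mutate(out, stage = as.character(.data$stage))
}

#' Flag the critical (pre-transition) stage
#'
#' For every interior stage \eqn{t}, the stage's individual sample scores
#' \eqn{H^k(t)} are tested with a two-sided one-sample t-test against a
#' reference value: by default the mean of the two neighbouring stage means
#' \eqn{(H(t-1) + H(t+1))/2} (with `reference = "all_others"`, the mean of
#' all other stage means). A stage is flagged critical when its p-value falls
#' below `alpha` *and* its mean exceeds the reference value (the signal of
#' interest is a significant increase). The earliest flagged stage is
#' reported as the critical stage; boundary stages are never tested.
#'
#' A tested stage whose scores have zero variance gets p-value 0 if its mean
#' differs from the reference (1 otherwise), with a warning.
#'
#' @inheritParams sample_ere
#' @param alpha Significance level, default 0.05. No multiplicity correction
#'   is applied across stages; all per-stage p-values are reported.
#' @param reference `"neighbors"` (default) or `"all_others"`.
#' @return An object of class `ere_stage_report`; see
#'   [tidy.ere_stage_report()], [glance.ere_stage_report()],
#'   [autoplot.ere_stage_report()].
#' @export
detect_critical <- function(fit, alpha = 0.05,
                            reference = c("neighbors", "all_others"),
                            top_fraction = NULL) {
  stopifnot(inherits(fit, "ere_fit"))
  reference <- match.arg(reference)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie in (0, 1).", call. = FALSE)
  }
  per_sample <- sample_ere(fit, top_fraction)
  series <- stage_series(fit, top_fraction)
  stages <- series$stage
  n_stage <- length(stages)
  if (n_stage < 3L) {
    stop("Critical-stage detection needs at least 3 stages.", call. = FALSE)
  }
  h_t <- stats::setNames(series$h_t, stages)

  res <- tibble::tibble(
    stage = stages, n_t = series$n_t, h_t = series$h_t,
    reference_mean = NA_real_, statistic = NA_real_, df = NA_real_,
    p_value = NA_real_, critical = FALSE
  )
  for (i in seq_len(n_stage)) {
    if (i == 1L || i == n_stage) next # boundary stages are untested
    mu <- if (reference == "neighbors") {
      mean(c(h_t[i - 1L], h_t[i + 1L]))
    } else {
      mean(h_t[-i])
    }
    x <- per_sample$h_k[per_sample$stage == stages[i]]
    tt <- one_sample_t(x, mu, stage = stages[i])
    res$reference_mean[i] <- mu
    res$statistic[i] <- tt$statistic
    res$df[i] <- tt$df
    res$p_value[i] <- tt$p_value
    res$critical[i] <- is.finite(tt$p_value) && tt$p_value < alpha &&
      h_t[i] > mu
  }
  flagged <- res$stage[res$critical]
  structure(
    list(stages = res,
         critical_stage = if (length(flagged)) flagged[1L] else NA_character_,
         alpha = alpha, reference = reference,
         top_fraction = top_fraction %||% fit$top_fraction),
    class = "ere_stage_report"
  )
}

# Two-sided one-sample t-test from its closed form. Degenerate (zero
# variance) inputs get p = 0 when the mean differs from mu, else p = 1.
one_sample_t <- function(x, mu, stage = NULL) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  df <- n - 1
  if (s == 0) {
    warning("Degenerate variance in stage ",
            if (is.null(stage)) "" else paste0("'", stage, "'"),
            ": all sample scores identical.", call. = FALSE)
    return(list(statistic = if (m == mu) NaN else sign(m - mu) * Inf,
                df = df, p_value = if (m == mu) 1 else 0))
  }
  t_stat <- (m - mu) / (s / sqrt(n))
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' @export
print.ere_stage_report <- function(x, ...) {
  cat("<ere_stage_report>\n")
  cat("  critical stage: ",
      if (is.na(x$critical_stage)) "none flagged" else x$critical_stage,
      " (alpha = ", x$alpha, ", reference = ", x$reference, ")\n", sep = "")
  print(x$stages)
  invisible(x)
}
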