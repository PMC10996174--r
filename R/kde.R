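#' Plug-in bandwidth for a univariate Gaussian kernel density estimate
#'
#' Silverman-type plug-in rule \eqn{h = (4\sigma^5 / (3N))^{1/5}}, where
#' \eqn{\sigma} is the sample standard deviation of the cohort and \eqn{N}
#' its size. The bandwidth is homogeneous of degree one in \eqn{\sigma}.
#'
#' @param sigma Sample standard deviation of the cohort (computed with the
#'   \eqn{N-1} denominator by the callers in this package; see
#'   [kde_probability_vector()]). Must be strictly positive.
#' @param n Cohort size, an integer \eqn{\ge 2}.
#' @param gene_id Optional gene label used in the error message when the
#'   cohort is degenerate (\code{sigma == 0}).
#' @return A positive scalar bandwidth.
#' @export
#' @examples
#' plugin_bandwidth(1, 3) # (4/9)^(1/5)
plugin_bandwidth <- function(sigma, n, gene_id = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a single finite non-negative number.", call. = FALSE)
  }
  if (sigma == 0) {
    who <- if (is.null(gene_id)) "cohort" else paste0("gene '", gene_id, "'")
    stop("Degenerate cohort for ", who,
         ": all expression values identical (sigma = 0), bandwidth undefined.",
         call. = FALSE)
  }
  (4 * sigma^5 / (3 * n))^(1 / 5)
}

#' Kernel-density probability vector over a cohort's own sample points
#'
#' Fits a univariate Gaussian KDE with the plug-in bandwidth of
#' [plugin_bandwidth()] to a cohort of expression values, evaluates the
#' density only at the cohort's own observed points (the kernel centred at a
#' point contributes to the density at that same point), and normalizes the
#' densities to a probability vector summing to one. These vectors are the
#' \eqn{P_r} / \eqn{P_c} building blocks of every edge entropy score.
#'
#' @param values Numeric vector of expression values for one gene in one
#'   cohort; length \eqn{\ge 2}, all finite, not all identical.
#' @param sigma_denominator Denominator convention for the standard deviation
#'   entering the bandwidth: `"n-1"` (default, the sample standard deviation)
#'   or `"n"` (the population form).
#' @param gene_id Optional gene label for error messages.
#' @return A numeric probability vector aligned with `values`, summing to 1,
#'   all entries strictly positive, with attribute `bandwidth`.
#' @export
#' @examples
#' p <- kde_probability_vector(c(0, 1, 2))
#' sum(p) # 1
kde_probability_vector <- function(values, sigma_denominator = c("n-1", "n"),
                                   gene_id = NULL) {
  sigma_denominator <- match.arg(sigma_denominator)
  if (!is.numeric(values) || length(values) < 2L) {
    stop("A cohort needs at least 2 expression values.", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("Cohort expression values must all be finite.", call. = FALSE)
  }
  n <- length(values)
  sigma <- stats::sd(values)
  if (sigma_denominator == "n") sigma <- sigma * sqrt((n - 1) / n)
  h <- plugin_bandwidth(sigma, n, gene_id = gene_id)
  # f_h(x_k) = (1/(n h)) sum_j K((x_k - x_j)/h); the 1/(n h) factor cancels
  # in the normalization, so unnormalized kernel sums suffice.
  ksum <- colSums(stats::dnorm(outer(values, values, "-") / h))
  p <- ksum / sum(ksum)
  attr(p, "bandwidth") <- h
  p
}

#' Directed local edge relative entropy
#'
#' For an edge between genes \eqn{g_i} and \eqn{g_j} and one case sample
#' \eqn{k}, the directed score contrasts gene \eqn{g_j}'s reference
#' probability vector \eqn{P_r} with the case-cohort probability of gene
#' \eqn{g_i}'s observed value in that sample:
#' \deqn{H_{\langle j,i\rangle} = \sum_m p_r(x_{jm})
#'   \log\left(p_r(x_{jm}) / p_c(y_{ik})\right)
#'   = \sum_m p_r \log p_r \; - \; \log p_c(y_{ik}),}
#' using the natural logarithm. The value may be negative. It is strictly
#' decreasing in \code{p_case}: the rarer the case observation under the
#' case-cohort density, the larger the score.
#'
#' @param p_ref Reference probability vector (sums to 1, all positive).
#' @param p_case Case-cohort probability (or vector of probabilities, one per
#'   case sample) of the partner gene's observed value; each in \eqn{(0, 1]}.
#' @return Numeric, same length as `p_case`.
#' @export
directed_local_ere <- function(p_ref, p_case) {
  if (any(!is.finite(p_case)) || any(p_case <= 0) || any(p_case > 1)) {
    stop("`p_case` must lie in (0, 1].", call. = FALSE)
  }
  sum(p_ref * log(p_ref)) - log(p_case)
}

#' Symmetric local edge relative entropy
#'
#' The directed score is not symmetric in the two genes of an edge; the
#' per-edge, per-sample statistic is the arithmetic mean of the two
#' directions.
#'
#' @param h_ij,h_ji The two directed scores (finite numerics, vectorized).
#' @return `(h_ij + h_ji) / 2`.
#' @export
symmetric_local_ere <- function(h_ij, h_ji) {
  (h_ij + h_ji) / 2
}

# Per-gene profile summaries for a cohort matrix (genes x samples):
# negative entropy of the reference probability vector and/or log
# probabilities at the cohort's own points. Probabilities are floored at
# 1e-300 before taking logs; the number of floored entries is returned.
profile_stats <- function(mat, sigma_denominator = "n-1") {
  genes <- rownames(mat)
  n_clipped <- 0L
  logp <- matrix(NA_real_, nrow = nrow(mat), ncol = ncol(mat),
                 dimnames = dimnames(mat))
  neg_entropy <- numeric(nrow(mat))
  bandwidth <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    p <- kde_probability_vector(mat[g, ], sigma_denominator = sigma_denominator,
                                gene_id = genes[g])
    bandwidth[g] <- attr(p, "bandwidth")
    clipped <- p < 1e-300
    n_clipped <- n_clipped + sum(clipped)
    p <- pmax(p, 1e-300)
    logp[g, ] <- log(p)
    neg_entropy[g] <- sum(p * log(p))
  }
  list(genes = genes, neg_entropy = neg_entropy, logp = logp,
       bandwidth = bandwidth, n_clipped = n_clipped)
}

# Genes with zero variance within a sample subset of `mat`; these cannot be
# given a KDE profile and their incident edges must be dropped.
degenerate_genes <- function(mat) {
  v <- apply(mat, 1L, function(x) max(x) - min(x))
  rownames(mat)[v == 0]
}
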