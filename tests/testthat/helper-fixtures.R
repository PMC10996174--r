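# Shared fixtures: tiny hand-checkable datasets and a fit built directly
# from a designed score matrix (via the long-table constructor).

# deterministic 2-gene / 1-edge dataset small enough to verify by hand
tiny_dataset <- function() {
  mat <- rbind(
    gA = c(1.0, 2.0, 3.5, 1.2, 2.8, 0.7, 1.9),
    gB = c(0.5, 1.5, 2.5, 3.1, 0.9, 2.2, 1.4)
  )
  colnames(mat) <- c(paste0("r", 1:3), paste0("c", 1:4))
  metadata <- tibble::tibble(
    sample_id = colnames(mat),
    cohort = c(rep("reference", 3), rep("case", 4)),
    stage = c(rep(NA, 3), "s1", "s1", "s2", "s2")
  )
  network <- tibble::tibble(gene_a = "gA", gene_b = "gB")
  list(mat = mat, metadata = metadata, network = network)
}

# fit whose edges x samples score matrix is exactly `values`
fit_from_matrix <- function(values, edges, stages = NULL) {
  samples <- sprintf("k%02d", seq_len(ncol(values)))
  if (is.null(stages)) stages <- rep("s1", ncol(values))
  scores <- tibble::tibble(
    gene_a = rep(edges$gene_a, times = ncol(values)),
    gene_b = rep(edges$gene_b, times = ncol(values)),
    sample_id = rep(samples, each = nrow(values)),
    stage = rep(stages, each = nrow(values)),
    ere = as.vector(values)
  )
  ere_fit_from_scores(scores)
}

# independent O(N^2) Gaussian-kernel oracle for the probability vector
kde_oracle <- function(values, sigma_denominator = "n-1") {
  n <- length(values)
  s <- stats::sd(values)
  if (sigma_denominator == "n") s <- s * sqrt((n - 1) / n)
  h <- (4 * s^5 / (3 * n))^(1 / 5)
  f <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + exp(-((values[k] - values[j]) / h)^2 / 2) / sqrt(2 * pi)
    }
    f[k] <- acc / (n * h)
  }
  f / sum(f)
}

run_cli <- function(args) {
  script <- system.file("cli", "ere.R", package = "edgentropy")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(script, args),
                 env = paste0("R_LIBS=", paste(.libPaths(),
                                               collapse = .Platform$path.sep)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0) stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
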