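test_that("directed score vanishes for uniform profiles and matches hand sums", {
  # uniform reference, case probability 1/m: all log ratios vanish
  expect_equal(directed_local_ere(rep(0.25, 4), 0.25), 0)
  # two-term hand evaluation: 0.5 log(0.5/0.25) + 0.5 log(0.5/0.25) = log 2
  expect_equal(directed_local_ere(c(0.5, 0.5), 0.25), log(2),
               tolerance = 1e-12)
})

test_that("directed score decomposes into neg-entropy minus log case probability", {
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- runif(10)
      p <- p / sum(p)
      pc <- runif(1, 1e-6, 1)
      expect_equal(directed_local_ere(p, pc),
                   -(-sum(p * log(p))) - log(pc), tolerance = 1e-10)
    }
  })
})

test_that("directed score is strictly decreasing in the case probability", {
  p <- c(0.2, 0.3, 0.5)
  pc <- sort(runif(20, 1e-4, 1))
  vals <- directed_local_ere(p, pc)
  expect_true(all(diff(vals) < 0))
  expect_error(directed_local_ere(p, 0), "\\(0, 1\\]")
  expect_error(directed_local_ere(p, -0.1), "\\(0, 1\\]")
})

test_that("symmetric score is the arithmetic mean of the two directions", {
  expect_equal(symmetric_local_ere(0.2, 0.4), 0.3)
  expect_equal(symmetric_local_ere(1.7, 1.7), 1.7)
  expect_equal(symmetric_local_ere(0.9, -0.3), symmetric_local_ere(-0.3, 0.9))
})

test_that("edge scores reproduce a fully manual evaluation on a tiny dataset", {
  d <- tiny_dataset()
  fit <- ere_fit(d$mat, d$metadata, d$network, case_scope = "per_stage")
  # manual per-stage evaluation for stage s1 (case samples c1, c2)
  ref_a <- as.numeric(kde_probability_vector(d$mat["gA", 1:3]))
  ref_b <- as.numeric(kde_probability_vector(d$mat["gB", 1:3]))
  pc_a <- as.numeric(kde_probability_vector(d$mat["gA", 4:5]))
  pc_b <- as.numeric(kde_probability_vector(d$mat["gB", 4:5]))
  for (k in 1:2) {
    h_ab <- directed_local_ere(ref_a, pc_b[k]) # profile of gA vs case of gB
    h_ba <- directed_local_ere(ref_b, pc_a[k])
    expect_equal(unname(fit$values["gA--gB", k]),
                 symmetric_local_ere(h_ab, h_ba), tolerance = 1e-12)
  }
})

test_that("edge scores are invariant to gene order within an edge", {
  sim <- simulate_cohorts(sim_config(seed = 21, n_reference = 20,
                                     samples_per_stage = 10))
  fit1 <- suppressMessages(ere_fit(sim))
  swapped <- sim$network[, c("gene_b", "gene_a")]
  names(swapped) <- c("gene_a", "gene_b")
  fit2 <- suppressMessages(ere_fit(sim$expression, sim$metadata, swapped))
  expect_equal(fit1$values, fit2$values)
})

test_that("pooled and per-stage case scopes agree for a single-stage cohort", {
  d <- tiny_dataset()
  meta1 <- d$metadata
  meta1$stage[meta1$cohort == "case"] <- "only"
  f_all <- ere_fit(d$mat, meta1, d$network, case_scope = "all")
  f_stage <- ere_fit(d$mat, meta1, d$network, case_scope = "per_stage")
  expect_equal(f_all$values, f_stage$values)
})

test_that("zero-variance genes are dropped with their incident edges", {
  d <- tiny_dataset()
  mat <- rbind(d$mat, gC = rep(1, 7)) # constant gene
  net <- tibble::tibble(gene_a = c("gA", "gB"), gene_b = c("gB", "gC"))
  expect_warning(fit <- ere_fit(mat, d$metadata, net, case_scope = "all"),
                 "zero-variance")
  expect_equal(rownames(fit$values), "gA--gB")
})

test_that("per-sample aggregation equals a sort-based oracle", {
  withr::with_seed(99, {
    edges <- canonical_edges(tibble::tibble(
      gene_a = sprintf("x%03d", 1:100), gene_b = sprintf("y%03d", 1:100)))
    vals <- matrix(rnorm(100 * 8), 100, 8)
    fit <- fit_from_matrix(vals, edges)
    ps <- sample_ere(fit, top_fraction = 0.05)
    expect_equal(ps$m, rep(5L, 8))
    for (k in 1:8) {
      expect_equal(ps$h_k[k], mean(sort(vals[, k], decreasing = TRUE)[1:5]))
    }
  })
})

test_that("aggregation handles the top-1 and whole-set limits", {
  withr::with_seed(4, {
    edges <- canonical_edges(tibble::tibble(
      gene_a = sprintf("x%02d", 1:20), gene_b = sprintf("y%02d", 1:20)))
    vals <- matrix(rnorm(20 * 3), 20, 3)
    fit <- fit_from_matrix(vals, edges)
    top1 <- sample_ere(fit, top_fraction = 0.05) # floor(0.05*20) = 1
    expect_equal(top1$m, rep(1L, 3))
    expect_equal(top1$h_k, apply(vals, 2, max))
    full <- sample_ere(fit, top_fraction = 1)
    expect_equal(full$h_k, colMeans(vals))
  })
})

test_that("aggregate decreases as the top fraction grows", {
  withr::with_seed(5, {
    edges <- canonical_edges(tibble::tibble(
      gene_a = sprintf("x%02d", 1:60), gene_b = sprintf("y%02d", 1:60)))
    vals <- matrix(rnorm(60 * 5), 60, 5)
    fit <- fit_from_matrix(vals, edges)
    fracs <- c(0.02, 0.05, 0.2, 0.5, 1)
    hk <- sapply(fracs, function(f) sample_ere(fit, f)$h_k)
    for (k in 1:5) expect_true(all(diff(hk[k, ]) <= 1e-12))
    # and the top-set mean always dominates the overall mean
    expect_true(all(hk[, 2] >= colMeans(vals) - 1e-12))
  })
})

test_that("top-set membership is consistent with aggregation and sums to M", {
  withr::with_seed(6, {
    edges <- canonical_edges(tibble::tibble(
      gene_a = sprintf("x%02d", 1:50), gene_b = sprintf("y%02d", 1:50)))
    vals <- matrix(rnorm(50 * 8), 50, 8)
    fit <- fit_from_matrix(vals, edges)
    memb <- high_ere_membership(fit, top_fraction = 0.1) # M = 5
    counts <- tapply(memb$in_top, memb$sample_id, sum)
    expect_true(all(counts == 5L))
    ps <- sample_ere(fit, top_fraction = 0.1)
    for (k in seq_len(nrow(ps))) {
      in_top <- memb$edge[memb$sample_id == ps$sample_id[k] & memb$in_top]
      expect_setequal(in_top, ps$selected_edges[[k]])
    }
    expect_true(all(high_ere_membership(fit, top_fraction = 1)$in_top))
  })
})

test_that("ties at the cutoff resolve deterministically by canonical edge order", {
  edges <- canonical_edges(tibble::tibble(gene_a = c("a", "b", "c", "d"),
                                          gene_b = c("z", "z", "z", "z")))
  vals <- matrix(c(1, 1, 1, 0), 4, 1) # three-way tie for the top
  fit <- fit_from_matrix(vals, edges)
  ps <- sample_ere(fit, top_fraction = 0.5) # M = 2
  expect_equal(sort(ps$selected_edges[[1]]), c("a--z", "b--z"))
})

test_that("long-table round trip reconstructs the fit exactly", {
  sim <- simulate_cohorts(sim_config(seed = 31, n_reference = 20,
                                     samples_per_stage = 10))
  fit <- suppressMessages(ere_fit(sim))
  fit2 <- ere_fit_from_scores(tidy(fit))
  expect_equal(fit2$values, fit$values)
  expect_equal(fit2$stage_order, fit$stage_order)
})
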