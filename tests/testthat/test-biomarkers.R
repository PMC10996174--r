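test_that("survival grouping follows the five-year rule with censoring", {
  rec <- tibble::tibble(
    sample_id = c("p1", "p2", "p3", "p4", "p5"),
    survival_time = c(6.0, 3.0, 3.0, 5.0, 5.01),
    event = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  g <- survival_groups(rec)
  expect_equal(g$group, c("long",     # survived past the cut, censoring moot
                          "short",    # observed death before the cut
                          "excluded", # censored before the cut: unknowable
                          "short",    # death at exactly the cut
                          "long"))    # strictly past the cut
  expect_error(survival_groups(rec[0, ]), "non-empty")
  expect_error(survival_groups(dplyr::mutate(rec, survival_time = -1)))
})

test_that("prevalence calls are strict at the threshold", {
  edges <- canonical_edges(tibble::tibble(gene_a = c("a", "c", "e"),
                                          gene_b = c("b", "d", "f")))
  # 20 samples: 10 long (k01..k10), 10 short (k11..k20); M = 1 of 3 edges
  # edge 1 top in 9/10 long, 2/10 short -> positive
  # edge 2 top in exactly 8/10 long    -> NOT positive (0.8 is not > 0.8)
  top <- c("a--b", "a--b", "a--b", "a--b", "a--b", "a--b", "a--b", "a--b",
           "a--b", "c--d", # long: 9x edge1, 1x edge2
           "a--b", "a--b", "c--d", "c--d", "c--d", "c--d", "c--d", "c--d",
           "c--d", "c--d") # short: 2x edge1, 8x edge2
  vals <- matrix(0, 3, 20, dimnames = list(c("a--b", "c--d", "e--f"), NULL))
  for (k in 1:20) vals[top[k], k] <- 1
  fit <- fit_from_matrix(vals, edges)
  rec <- tibble::tibble(
    sample_id = sprintf("k%02d", 1:20),
    survival_time = c(rep(7, 10), rep(2, 10)),
    event = TRUE
  )
  calls <- classify_edges(fit, rec, top_fraction = 1 / 3)
  expect_equal(calls$call[calls$edge == "a--b"], "positive")
  expect_equal(calls$prevalence_long[calls$edge == "a--b"], 0.9)
  expect_equal(calls$prevalence_short[calls$edge == "a--b"], 0.2)
  # short-group prevalence of c--d is exactly 0.8: strict, so no call
  expect_equal(calls$prevalence_short[calls$edge == "c--d"], 0.8)
  expect_equal(calls$call[calls$edge == "c--d"], "none")
  expect_equal(calls$call[calls$edge == "e--f"], "none")
})

test_that("an edge prevalent in both groups has no prognostic direction", {
  edges <- canonical_edges(tibble::tibble(gene_a = c("a", "c"),
                                          gene_b = c("b", "d")))
  vals <- matrix(c(1, 0), 2, 10) # edge a--b is everyone's top edge
  fit <- fit_from_matrix(vals, edges)
  rec <- tibble::tibble(sample_id = sprintf("k%02d", 1:10),
                        survival_time = c(rep(8, 5), rep(2, 5)), event = TRUE)
  calls <- classify_edges(fit, rec, top_fraction = 0.5)
  expect_equal(calls$prevalence_long[calls$edge == "a--b"], 1)
  expect_equal(calls$prevalence_short[calls$edge == "a--b"], 1)
  expect_equal(calls$call[calls$edge == "a--b"], "none")
})

test_that("empty survival groups yield a warning and no calls", {
  edges <- canonical_edges(tibble::tibble(gene_a = "a", gene_b = "b"))
  fit <- fit_from_matrix(matrix(rnorm(6), 1), edges)
  rec <- tibble::tibble(sample_id = sprintf("k%02d", 1:6),
                        survival_time = 8, event = FALSE) # long only
  expect_warning(calls <- classify_edges(fit, rec), "Empty")
  expect_equal(nrow(calls), 0)
})

test_that("calls are invariant to sample order", {
  withr::with_seed(23, {
    edges <- canonical_edges(tibble::tibble(
      gene_a = sprintf("x%02d", 1:10), gene_b = sprintf("y%02d", 1:10)))
    vals <- matrix(rnorm(10 * 12), 10, 12)
    rec <- tibble::tibble(sample_id = sprintf("k%02d", 1:12),
                          survival_time = runif(12, 0.5, 10), event = TRUE)
    c1 <- classify_edges(fit_from_matrix(vals, edges), rec)
    perm <- sample(12)
    fitp <- fit_from_matrix(vals[, perm], edges)
    fitp$samples$sample_id <- sprintf("k%02d", perm)
    c2 <- classify_edges(fitp, rec)
    expect_equal(c1, c2)
  })
})

test_that("median stratification splits samples as the order statistics say", {
  edges <- canonical_edges(tibble::tibble(gene_a = "a", gene_b = "b"))
  fit <- fit_from_matrix(matrix(c(1, 2, 3, 4), 1), edges)
  s <- stratify_by_edge(fit, "b", "a") # gene order must not matter
  expect_equal(s$group, c("low", "low", "high", "high"))
  withr::with_seed(24, {
    v <- rnorm(31)
    fit2 <- fit_from_matrix(matrix(v, 1), edges)
    s2 <- stratify_by_edge(fit2, "a", "b")
    expect_equal(s2$group, ifelse(v > median(v), "high", "low"))
  })
  fit3 <- fit_from_matrix(matrix(rep(2, 5), 1), edges)
  expect_warning(s3 <- stratify_by_edge(fit3, "a", "b"), "tie")
  expect_true(all(s3$group == "low"))
  expect_error(stratify_by_edge(fit, "a", "zz"), "not present")
})

test_that("stratified groups drive a standard log-rank analysis", {
  skip_if_not_installed("survival")
  sim <- simulate_cohorts(sim_config(seed = 61, dispersion_factor = 1))
  sv <- simulate_survival(sim, seed = 62)
  fit <- suppressMessages(ere_fit(sv$expression, sv$metadata, sv$network,
                                  case_scope = "all"))
  strata <- stratify_by_edge(fit, "g05", "g06")
  tbl <- dplyr::inner_join(strata, sv$records, by = "sample_id")
  sd_ <- survival::survdiff(survival::Surv(survival_time, event) ~ group,
                            data = tbl)
  # the planted positive edge separates survival strongly
  expect_lt(1 - pchisq(sd_$chisq, 1), 0.01)
})

test_that("planted prognostic edges are recovered with correct signs", {
  sim <- simulate_cohorts(sim_config(seed = 71, dispersion_factor = 1))
  sv <- simulate_survival(sim, seed = 72)
  fit <- suppressMessages(ere_fit(sv$expression, sv$metadata, sv$network,
                                  case_scope = "all"))
  calls <- classify_edges(fit, sv$records)
  expect_setequal(calls$edge[calls$call == "positive"], "g05--g06")
  expect_setequal(calls$edge[calls$call == "negative"], "g09--g10")
  expect_true(all(calls$prevalence_long >= 0 & calls$prevalence_long <= 1))
  expect_true(all(calls$prevalence_short >= 0 & calls$prevalence_short <= 1))
})
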