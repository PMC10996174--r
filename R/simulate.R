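#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of [simulate_cohorts()]. The
#' defaults describe the study conditions used throughout the package's
#' tests: a 16-gene network (ring plus 8 random chords), 5 case stages of 30
#' samples, 50 reference samples, and a planted critical stage (the third)
#' on a 4-gene dispersion-inflated module.
#'
#' @param n_genes Number of genes, >= 3. Default 16.
#' @param network_spec `"ring_with_chords"` (default), `"random_gnm"`, or
#'   `"custom"` (then supply `custom_edges`).
#' @param n_chords Number of extra chords for `"ring_with_chords"`, or extra
#'   edges beyond `n_genes` for `"random_gnm"`. Default 8.
#' @param custom_edges Two-column data frame of edges for
#'   `network_spec = "custom"`.
#' @param n_stages Number of case stages, >= 3. Default 5.
#' @param samples_per_stage Case samples per stage, >= 10. Default 30.
#' @param n_reference Reference cohort size, >= 20. Default 50.
#' @param critical_stage_index Planted critical stage; must be interior
#'   (neither first nor last). Default 3.
#' @param dnb_genes Genes forming the fluctuating module at the critical
#'   stage; must induce at least one network edge. Default the first four
#'   genes (ring neighbours, so 3 induced edges at least).
#' @param dispersion_factor Multiplier `kappa >=  1` on `noise_sd` for excited
#'   samples' `dnb_genes` at the critical stage; `kappa = 1` is a pure null.
#'   Default 4.
#' @param excitation_prob Probability that a critical-stage sample is
#'   "excited" (draws its `dnb_genes` with sd `kappa * noise_sd`). The
#'   sample-level mixture is what creates low-density tails in the case
#'   KDE; inflating every sample of the stage equally would be an exact
#'   location-scale change of the stage cohort, which normalized density
#'   vectors cannot see under per-stage fitting. Default 0.7.
#' @param mean_shift_after Mean shift added to `dnb_genes` in stages after
#'   the critical one (after-transition expression change). Default 3.
#' @param noise_sd Per-gene noise standard deviation. Default 1.
#' @param baseline_mean Baseline expression mean (log2-intensity-like
#'   scale). Default 8.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration. Default 1.
#' @return A validated list of class `ere_sim_config`.
#' @export
sim_config <- function(n_genes = 16,
                       network_spec = c("ring_with_chords", "random_gnm",
                                        "custom"),
                       n_chords = 8, custom_edges = NULL,
                       n_stages = 5, samples_per_stage = 30,
                       n_reference = 50, critical_stage_index = 3,
                       dnb_genes = NULL, dispersion_factor = 4,
                       excitation_prob = 0.7, mean_shift_after = 3,
                       noise_sd = 1, baseline_mean = 8, seed = 1) {
  network_spec <- match.arg(network_spec)
  stopifnot(n_genes >= 3, n_stages >= 3, samples_per_stage >= 10,
            n_reference >= 20, noise_sd > 0, dispersion_factor >= 1,
            excitation_prob > 0, excitation_prob <= 1)
  if (critical_stage_index <= 1 || critical_stage_index >= n_stages) {
    stop("`critical_stage_index` must be interior (not first, not last).",
         call. = FALSE)
  }
  genes <- sim_gene_names(n_genes)
  if (is.null(dnb_genes)) dnb_genes <- genes[1:min(4, n_genes - 1)]
  if (!all(dnb_genes %in% genes)) {
    stop("`dnb_genes` must be a subset of the simulated genes.",
         call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, network_spec = network_spec, n_chords = n_chords,
         custom_edges = custom_edges, n_stages = n_stages,
         samples_per_stage = samples_per_stage, n_reference = n_reference,
         critical_stage_index = critical_stage_index, dnb_genes = dnb_genes,
         dispersion_factor = dispersion_factor,
         excitation_prob = excitation_prob,
         mean_shift_after = mean_shift_after, noise_sd = noise_sd,
         baseline_mean = baseline_mean, seed = seed),
    class = "ere_sim_config"
  )
}

sim_gene_names <- function(n) sprintf("g%02d", seq_len(n))

#' Toy interaction network for simulations
#'
#' A connected ring over `n_genes` genes plus `n_chords` distinct random
#' chords (seeded), returned as a canonical deduplicated edge list without
#' self-loops.
#'
#' @param n_genes Number of genes, >= 3.
#' @param n_chords Number of chords to add, capped at the number of
#'   available non-ring pairs.
#' @param seed Integer seed for the chord draw.
#' @return A tibble `gene_a`, `gene_b` in canonical (lexicographic) order.
#' @export
toy_network <- function(n_genes = 16, n_chords = 8, seed = 1) {
  if (n_genes < 3) stop("`n_genes` must be >= 3.", call. = FALSE)
  genes <- sim_gene_names(n_genes)
  ring <- tibble::tibble(gene_a = genes,
                         gene_b = genes[c(seq_len(n_genes)[-1], 1L)])
  all_pairs <- utils::combn(genes, 2)
  pair_tbl <- tibble::tibble(gene_a = all_pairs[1, ], gene_b = all_pairs[2, ])
  ring_lab <- edge_label(canonical_edges(ring))
  candidates <- pair_tbl[!(edge_label(pair_tbl) %in% ring_lab), , drop = FALSE]
  n_chords <- min(n_chords, nrow(candidates))
  chords <- withr::with_seed(seed, {
    candidates[sample.int(nrow(candidates), n_chords), , drop = FALSE]
  })
  canonical_edges(rbind(canonical_edges(ring), chords))
}

#' Simulate a reference cohort and staged case cohorts with a planted
#' critical stage
#'
#' Reference samples and non-critical pre-transition stages draw every gene
#' i.i.d. Gaussian with mean `baseline_mean` and sd `noise_sd`. At the
#' critical stage, each sample is independently excited with probability
#' `excitation_prob`; excited samples draw the `dnb_genes` with sd
#' `dispersion_factor * noise_sd`, planting heavy-tailed collective
#' fluctuation on the module. Stages after the critical one add
#' `mean_shift_after` to the `dnb_genes` (an after-transition mean change,
#' which per-stage KDE probability vectors are invariant to). With
#' `dispersion_factor = 1` the dataset is an exact null.
#'
#' @param config An [sim_config()] object (or arguments for one via `...`).
#' @param ... Passed to [sim_config()] when `config` is missing.
#' @return An object of class `ere_simulation`: a list with `expression`
#'   (tibble, first column `gene`), `metadata`, `network`, and `truth`
#'   (critical stage label, dnb genes, induced dnb edges, excited sample
#'   ids, the config).
#' @export
simulate_cohorts <- function(config = sim_config(...), ...) {
  stopifnot(inherits(config, "ere_sim_config"))
  genes <- sim_gene_names(config$n_genes)
  network <- switch(
    config$network_spec,
    ring_with_chords = toy_network(config$n_genes, config$n_chords,
                                   seed = config$seed),
    random_gnm = random_gnm_network(config$n_genes, config$n_chords,
                                    seed = config$seed),
    custom = canonical_edges(config$custom_edges)
  )
  dnb_edges <- network[network$gene_a %in% config$dnb_genes &
                         network$gene_b %in% config$dnb_genes, , drop = FALSE]
  if (nrow(dnb_edges) == 0L) {
    stop("`dnb_genes` induce no network edge; the planted signal would be ",
         "invisible to an edge statistic.", call. = FALSE)
  }

  stages <- sprintf("stage%d", seq_len(config$n_stages))
  ref_ids <- sprintf("r%03d", seq_len(config$n_reference))
  case_ids <- unlist(lapply(seq_len(config$n_stages), function(t) {
    sprintf("s%d_%02d", t, seq_len(config$samples_per_stage))
  }))

  dnb_idx <- match(config$dnb_genes, genes)
  out <- withr::with_seed(config$seed, {
    ref <- matrix(stats::rnorm(config$n_genes * config$n_reference,
                               config$baseline_mean, config$noise_sd),
                  nrow = config$n_genes,
                  dimnames = list(genes, ref_ids))
    excited <- character(0)
    case_cols <- vector("list", config$n_stages)
    for (t in seq_len(config$n_stages)) {
      m <- matrix(stats::rnorm(config$n_genes * config$samples_per_stage,
                               config$baseline_mean, config$noise_sd),
                  nrow = config$n_genes)
      ids <- sprintf("s%d_%02d", t, seq_len(config$samples_per_stage))
      if (t == config$critical_stage_index && config$dispersion_factor > 1) {
        exc <- stats::runif(config$samples_per_stage) < config$excitation_prob
        n_exc <- sum(exc)
        if (n_exc > 0) {
          m[dnb_idx, exc] <- stats::rnorm(
            length(dnb_idx) * n_exc, config$baseline_mean,
            config$dispersion_factor * config$noise_sd
          )
        }
        excited <- ids[exc]
      }
      if (t > config$critical_stage_index) {
        m[dnb_idx, ] <- m[dnb_idx, ] + config$mean_shift_after
      }
      dimnames(m) <- list(genes, ids)
      case_cols[[t]] <- m
    }
    list(mat = cbind(ref, do.call(cbind, case_cols)), excited = excited)
  })

  metadata <- tibble::tibble(
    sample_id = c(ref_ids, case_ids),
    cohort = c(rep("reference", length(ref_ids)),
               rep("case", length(case_ids))),
    stage = c(rep(NA_character_, length(ref_ids)),
              rep(stages, each = config$samples_per_stage))
  )
  structure(
    list(
      expression = expression_to_tibble(out$mat),
      metadata = metadata,
      network = network,
      truth = list(critical_stage = stages[config$critical_stage_index],
                   dnb_genes = config$dnb_genes, dnb_edges = dnb_edges,
                   excited_samples = out$excited, config = config)
    ),
    class = "ere_simulation"
  )
}

random_gnm_network <- function(n_genes, n_extra, seed) {
  genes <- sim_gene_names(n_genes)
  # spanning path guarantees connectivity; extra edges drawn uniformly
  path <- tibble::tibble(gene_a = genes[-n_genes], gene_b = genes[-1])
  all_pairs <- utils::combn(genes, 2)
  pair_tbl <- tibble::tibble(gene_a = all_pairs[1, ], gene_b = all_pairs[2, ])
  path_lab <- edge_label(canonical_edges(path))
  candidates <- pair_tbl[!(edge_label(pair_tbl) %in% path_lab), , drop = FALSE]
  extra <- withr::with_seed(seed, {
    candidates[sample.int(nrow(candidates), min(n_extra, nrow(candidates))), ,
               drop = FALSE]
  })
  canonical_edges(rbind(canonical_edges(path), extra))
}

#' Plant prognostic edges and simulate survival records
#'
#' Builds a prognostic-cohort fixture from a simulated dataset: the case
#' samples are split at random into a long-survival and a short-survival
#' cohort, their expression is redrawn with compact-support uniform noise
#' (`baseline_mean` plus `Uniform(-w, w)` with `w = case_noise_half_width *
#' noise_sd`), and each planted positive edge is given an extreme entropy
#' score in (by default) 95% of long-survival samples only — each negative
#' edge in short-survival samples only — by setting both endpoint genes of
#' the edge to an isolated outlier: magnitude drawn uniformly from
#' `outlier_range` (in `noise_sd` units) with random sign, so perturbed
#' values scatter over a wide band instead of forming a secondary density
#' mode.
#'
#' The compact-support noise matters: under a plug-in-bandwidth KDE, a
#' Gaussian cohort's own extreme samples are nearly as rare under the case
#' density as planted outliers are, which would make high-entropy membership
#' reflect ordinary sampling noise as much as the planted prognostic signal.
#' Uniform noise has no deep self-tails, so the planted edges are the only
#' systematic low-density structure. Long-survival times are drawn above
#' `cut_years`, short-survival times below it with the death observed.
#'
#' @param dataset An [simulate_cohorts()] object.
#' @param positive_edges,negative_edges Lists of length-2 character vectors
#'   (or 2-column data frames) naming planted edges; all must exist in the
#'   dataset's network. Defaults plant one of each on ring edges disjoint
#'   from the dataset's dnb module.
#' @param seed Integer seed.
#' @param boost_prob Per-sample probability that a group sample receives its
#'   group's perturbation. Default 0.95.
#' @param outlier_range Magnitude range of the outlier, in `noise_sd` units.
#'   Default `c(8, 40)`.
#' @param case_noise_half_width Half-width of the uniform case noise, in
#'   `noise_sd` units. Default 2 (matching the Gaussian noise variance
#'   roughly: a `Uniform(-2, 2)` has sd 1.15).
#' @param cut_years Survival cut, default 5.
#' @return An object of class `ere_survival_sim`: list with `expression`
#'   (perturbed tibble), `metadata` (with `survival_time` and `event`
#'   columns added), `network`, `records`, and `truth` (planted edges and
#'   boosted sample ids per edge sign).
#' @export
simulate_survival <- function(dataset,
                              positive_edges = list(c("g05", "g06")),
                              negative_edges = list(c("g09", "g10")),
                              seed = 1, boost_prob = 0.95,
                              outlier_range = c(8, 40),
                              case_noise_half_width = 2, cut_years = 5) {
  stopifnot(inherits(dataset, "ere_simulation"))
  cfg <- dataset$truth$config
  pos <- canonical_edges(edge_list_to_tbl(positive_edges))
  neg <- canonical_edges(edge_list_to_tbl(negative_edges))
  net_lab <- edge_label(dataset$network)
  missing <- setdiff(c(edge_label(pos), edge_label(neg)), net_lab)
  if (length(missing)) {
    stop("Planted edge(s) not in the network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  mat <- as_expression_matrix(dataset$expression)
  case_ids <- dataset$metadata$sample_id[dataset$metadata$cohort == "case"]
  n_case <- length(case_ids)
  w <- case_noise_half_width * cfg$noise_sd

  res <- withr::with_seed(seed, {
    mat[, case_ids] <- cfg$baseline_mean +
      matrix(stats::runif(nrow(mat) * n_case, -w, w), nrow(mat))
    long_ids <- sort(sample(case_ids, floor(n_case / 2)))
    short_ids <- setdiff(case_ids, long_ids)
    boost <- function(ids, edges) {
      boosted <- character(0)
      for (id in ids) {
        if (stats::runif(1) >= boost_prob) next
        boosted <- c(boosted, id)
        for (r in seq_len(nrow(edges))) {
          for (g in c(edges$gene_a[r], edges$gene_b[r])) {
            mag <- stats::runif(1, outlier_range[1], outlier_range[2])
            sgn <- sample(c(-1, 1), 1)
            mat[g, id] <<- cfg$baseline_mean + sgn * mag * cfg$noise_sd
          }
        }
      }
      boosted
    }
    boosted_pos <- boost(long_ids, pos)
    boosted_neg <- boost(short_ids, neg)
    records <- tibble::tibble(
      sample_id = case_ids,
      survival_time = ifelse(
        case_ids %in% long_ids,
        stats::runif(n_case, cut_years + 1, cut_years + 5),
        stats::runif(n_case, 0.5, cut_years - 0.5)
      ),
      event = ifelse(case_ids %in% long_ids,
                     stats::runif(n_case) < 0.5, TRUE)
    )
    list(records = records, long_ids = long_ids, short_ids = short_ids,
         boosted_pos = boosted_pos, boosted_neg = boosted_neg, mat = mat)
  })

  metadata <- dplyr::left_join(dataset$metadata, res$records, by = "sample_id")
  structure(
    list(expression = expression_to_tibble(res$mat), metadata = metadata,
         network = dataset$network, records = res$records,
         truth = list(positive_edges = pos, negative_edges = neg,
                      long_ids = res$long_ids, short_ids = res$short_ids,
                      boosted_positive = res$boosted_pos,
                      boosted_negative = res$boosted_neg)),
    class = "ere_survival_sim"
  )
}

edge_list_to_tbl <- function(x) {
  if (is.data.frame(x)) {
    tibble::tibble(gene_a = as.character(x[[1]]), gene_b = as.character(x[[2]]))
  } else {
    tibble::tibble(gene_a = vapply(x, `[`, "", 1),
                   gene_b = vapply(x, `[`, "", 2))
  }
}
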