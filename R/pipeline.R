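#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with its default.  The
#' master `seed` drives all stochastic stages through [derive_seed()], so
#' each stage can be reproduced in isolation.
#'
#' @param input path to a survey CSV, or a `survey_dataset` object.
#' @param output_dir directory for the report bundle (created if missing).
#' @param alpha edge-pruning significance level.
#' @param min_age,max_age closed age interval retained.
#' @param goldbricker_r,goldbricker_unique_frac overlap screening thresholds.
#' @param correlation_method `"pearson"`, `"spearman"` or `"polychoric"`.
#' @param n_boot,drop_fraction case-drop bootstrap controls.
#' @param n_permutations,n_ppc_draws comparison test controls.
#' @param min_group_n minimum per-group sample size; smaller groups are
#'   dropped with a warning (default `10 * n_items`, pruning is unstable
#'   below that). `NULL` computes the default at run time.
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir = NULL, alpha = 0.05,
                            min_age = 20, max_age = 29,
                            goldbricker_r = 0.7,
                            goldbricker_unique_frac = 0.2,
                            correlation_method = "pearson",
                            n_boot = 1000, drop_fraction = 0.25,
                            n_permutations = 5000, n_ppc_draws = 1000,
                            min_group_n = NULL, seed = 1) {
  stopifnot(alpha > 0, alpha <= 1, drop_fraction >= 0, drop_fraction < 1,
            n_boot >= 1, n_permutations >= 1, n_ppc_draws >= 1)
  structure(list(input = input, output_dir = output_dir, alpha = alpha,
                 min_age = min_age, max_age = max_age,
                 goldbricker_r = goldbricker_r,
                 goldbricker_unique_frac = goldbricker_unique_frac,
                 correlation_method = correlation_method, n_boot = n_boot,
                 drop_fraction = drop_fraction,
                 n_permutations = n_permutations,
                 n_ppc_draws = n_ppc_draws, min_group_n = min_group_n,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full multi-group network analysis pipeline
#'
#' Stage order: clean (straight-liners, age) -> overlap screening ->
#' per-group network estimation with fit indices -> centrality ->
#' all pairwise comparisons (skipped with fewer than 2 groups) -> case-drop
#' bootstrap per group -> cross-group variability network.  When
#' `config$output_dir` is set, the bundle (JSON report, edge lists,
#' centrality and bootstrap CSVs, GraphML files) is written there.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle`: list with `cleaning`, `networks`,
#'   `centrality`, `globals`, `comparisons`, `bootstrap`, `variability`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  data <- if (inherits(config$input, "survey_dataset")) {
    config$input
  } else {
    read_survey_csv(config$input)
  }

  cleaned <- clean_survey(data, config$min_age, config$max_age,
                          config$goldbricker_r,
                          config$goldbricker_unique_frac)
  ds <- cleaned$data
  community <- ds$community
  p <- ncol(ds$responses)
  min_n <- if (is.null(config$min_group_n)) 10 * p else config$min_group_n

  groups <- sort(unique(ds$group))
  sizes <- table(ds$group)[groups]
  too_small <- groups[sizes < min_n]
  if (length(too_small)) {
    warning(sprintf("dropping group(s) below the n >= %d guard: %s", min_n,
                    paste(too_small, collapse = ", ")))
    groups <- setdiff(groups, too_small)
  }
  if (!length(groups)) stop("no group passes the sample-size guard",
                            call. = FALSE)

  group_data <- lapply(groups, function(g) {
    ds$responses[ds$group == g, , drop = FALSE]
  })
  names(group_data) <- groups

  networks <- lapply(group_data, function(X) {
    corr <- estimate_correlations(X, config$correlation_method)
    prune_network(corr, config$alpha, communities = community)
  })
  centr <- lapply(networks, centrality_table, community = community)
  globals <- lapply(networks, global_indices, community = community)

  comparisons <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (t in seq_len(ncol(pairs))) {
      a <- pairs[1, t]; b <- pairs[2, t]
      comparisons[[paste(a, b, sep = "_vs_")]] <- compare_networks(
        group_data[[a]], group_data[[b]], community,
        label_a = a, label_b = b,
        n_permutations = config$n_permutations,
        n_ppc_draws = config$n_ppc_draws, alpha = config$alpha,
        seed = derive_seed(config$seed, 100L + t))
    }
  }

  boots <- lapply(seq_along(groups), function(k) {
    casedrop_bootstrap(group_data[[k]], config$n_boot,
                       config$drop_fraction, config$alpha,
                       seed = derive_seed(config$seed, 200L + k))
  })
  names(boots) <- groups

  variability <- if (length(groups) >= 2) {
    variability_network(networks, groups = groups)
  } else {
    NULL
  }

  manifest <- list(config = config[setdiff(names(config), "input")],
                   groups = as.list(setNames(as.integer(sizes[groups]),
                                             groups)),
                   n_items = p,
                   package_version = as.character(
                     utils::packageVersion("resilnet")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  bundle <- structure(list(cleaning = cleaned$report, networks = networks,
                           centrality = centr, globals = globals,
                           comparisons = comparisons, bootstrap = boots,
                           variability = variability, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(config$output_dir)) {
    write_report_bundle(bundle, config$output_dir, community)
  }
  bundle
}

#' Write a report bundle to disk
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @param community item-to-community map for edge labels.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, community = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- function(f) file.path(dir, f)

  report <- list(
    cleaning = unclass(bundle$cleaning),
    fit = lapply(bundle$networks, function(nt) {
      unclass(nt$fit)[c("chi_square", "df", "bic", "rmsea", "cfi", "tli",
                        "log_likelihood")]
    }),
    globals = bundle$globals,
    comparisons = lapply(bundle$comparisons, function(cmp) {
      unclass(cmp)[c("group_a", "group_b", "kl_observed", "kl_p",
                     "global_ei_diff", "global_ei_p",
                     "global_bridge_ei_diff", "global_bridge_ei_p",
                     "edge_diff_count", "bridge_edge_diff_count",
                     "nonbridge_edge_diff_count", "node_ei_diff_count",
                     "node_bridge_ei_diff_count", "n_permutations",
                     "n_ppc_draws", "seed")]
    }),
    bootstrap = lapply(bundle$bootstrap, function(bt) {
      list(overall_recovery = bt$overall_recovery, n_boot = bt$n_boot,
           n_failed = bt$n_failed, drop_fraction = bt$drop_fraction)
    }),
    manifest = bundle$manifest)
  jsonlite::write_json(report, jpath("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)

  for (g in names(bundle$networks)) {
    network_edgelist(bundle$networks[[g]],
                     jpath(sprintf("edges_%s.csv", g)),
                     communities = community)
    write_graphml(bundle$networks[[g]],
                  jpath(sprintf("network_%s.graphml", g)),
                  communities = community)
    write_centrality_csv(bundle$centrality[[g]],
                         jpath(sprintf("centrality_%s.csv", g)))
    write_bootstrap_csv(bundle$bootstrap[[g]],
                        jpath(sprintf("bootstrap_%s.csv", g)))
  }
  if (!is.null(bundle$variability)) {
    write_variability(bundle$variability, jpath("variability_edges.csv"),
                      jpath("variability.graphml"), community = community)
  }
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  print(x$cleaning)
  for (g in names(x$networks)) {
    cat(sprintf("[%s] ", g)); print(x$networks[[g]])
  }
  cat(sprintf("  %d pairwise comparison(s)\n", length(x$comparisons)))
  invisible(x)
}
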