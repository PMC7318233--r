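#' Analysis configuration
#'
#' One configuration object fully determines a run of [network_analysis()]:
#' EBIC-glasso settings, the spin-glass parameters (defaults are the
#' published call: resolution 0.5, 17 spins, start temperature 1, stop
#' temperature 0.01, cooling factor 0.99), bootstrap sizes, the
#' drop-proportion grid, the minimum subgroup size, and the master seed.
#'
#' @param gamma_ebic EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio,edge_tol Penalty path settings; see
#'   [ebic_glasso()].
#' @param spinglass List of spin-glass parameters; see
#'   [spinglass_communities()].
#' @param run_stability,run_difference Whether to run the bootstrap stages
#'   (they dominate run time).
#' @param stability List: `drop_proportions`, `n_boot`, `cor_method`.
#' @param difference List: `n_boot`.
#' @param min_subgroup_n Subgroups smaller than this are skipped with a
#'   logged reason (default 150; small-subgroup networks are too unstable
#'   to interpret).
#' @param layout_iterations Fruchterman-Reingold iterations.
#' @param seed Master seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(gamma_ebic = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01, edge_tol = 1e-10,
                            spinglass = list(), run_stability = TRUE,
                            run_difference = TRUE, stability = list(),
                            difference = list(), min_subgroup_n = 150,
                            layout_iterations = 500, seed = 1) {
  sg <- utils::modifyList(
    list(gamma = 0.5, spins = 17, start_temp = 1, stop_temp = 0.01,
         cooling = 0.99, sweeps = 5, restarts = 1), spinglass)
  st <- utils::modifyList(
    list(drop_proportions = seq(0.05, 0.75, by = 0.05), n_boot = 1000,
         cor_method = "pearson"), stability)
  df <- utils::modifyList(list(n_boot = 1000), difference)
  structure(list(gamma_ebic = gamma_ebic, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, edge_tol = edge_tol,
                 spinglass = sg, run_stability = run_stability,
                 run_difference = run_difference, stability = st,
                 difference = df, min_subgroup_n = min_subgroup_n,
                 layout_iterations = layout_iterations, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}

analyze_cohort <- function(x, label, config, seed) {
  items <- attr(x, "items")
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) inform(paste0("[", label, "] ", msg))

  stage(paste0("estimating network (n = ", nrow(x), ")"))
  net <- suppressWarnings(symptom_network(
    x, items = items, gamma = config$gamma_ebic, n_lambda = config$n_lambda,
    lambda_min_ratio = config$lambda_min_ratio, edge_tol = config$edge_tol))
  if (net$correlations$psd_repaired) {
    stage("tetrachoric matrix repaired to positive definite")
  }
  edges <- count_edges(net)
  top_edges <- suppressWarnings(top_associations(net, 3))

  stage("detecting communities")
  part <- spinglass_communities(
    net, gamma = config$spinglass$gamma, spins = config$spinglass$spins,
    start_temp = config$spinglass$start_temp,
    stop_temp = config$spinglass$stop_temp,
    cooling = config$spinglass$cooling, sweeps = config$spinglass$sweeps,
    restarts = config$spinglass$restarts, seed = seed)
  part <- isolate_outliers(net, part)

  cent <- centrality(net)
  top_central <- suppressMessages(summarize_top3(cent))
  layout <- fruchterman_reingold(net, seed = seed,
                                 iterations = config$layout_iterations)

  stability <- NULL
  if (isTRUE(config$run_stability)) {
    stage(paste0("case-dropping bootstrap (n_boot = ",
                 config$stability$n_boot, ")"))
    stability <- case_drop_bootstrap(
      x, items = items,
      drop_proportions = config$stability$drop_proportions,
      n_boot = config$stability$n_boot, seed = seed,
      gamma = config$gamma_ebic, cor_method = config$stability$cor_method)
  }
  difference <- NULL
  if (isTRUE(config$run_difference)) {
    stage(paste0("difference bootstrap (n_boot = ",
                 config$difference$n_boot, ")"))
    difference <- difference_bootstrap(
      x, items = items, n_boot = config$difference$n_boot, seed = seed,
      gamma = config$gamma_ebic)
  }
  stage(paste0("done in ", round(proc.time()[["elapsed"]] - t0, 1), " s"))
  list(label = label, n = nrow(x), prevalence = prevalence(x),
       network = net, edges = edges, top_edges = top_edges,
       communities = part, centrality = cent, top_central = top_central,
       layout = layout, stability = stability, difference = difference,
       seed = seed)
}

#' Run the full symptom-network analysis
#'
#' Orchestrates the complete pipeline — prevalence table, tetrachoric
#' correlations, EBIC-glasso network, edge summary, spin-glass communities
#' with isolate flags, centralities with top-3 summary, layout, and (when
#' enabled) the stability and difference bootstraps — on the overall cohort
#' and separately on every level of each requested subgroup column.
#' Subgroups below `config$min_subgroup_n` are skipped with a logged
#' reason. Deterministic given the data, configuration and seed.
#'
#' @param data Binary symptom data (`symptom_matrix` or data frame).
#' @param items Symptom columns.
#' @param subgroups Character vector of subgroup column names to analyze
#'   (default: the validated `subgroups` attribute, if any).
#' @param config An [analysis_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `analysis_report`: `cohorts` (named list of
#'   per-cohort results), `skipped` (tibble of skipped subgroups),
#'   `config`, `provenance` (config hash, seed, package version,
#'   timestamp).
#' @export
#' @examples
#' x <- simulate_cohort(reap_cohort_spec(), seed = 1)
#' cfg <- analysis_config(run_stability = FALSE, run_difference = FALSE)
#' rep <- network_analysis(x, subgroups = "region", config = cfg,
#'                         quiet = TRUE)
#' rep$cohorts$overall$edges
network_analysis <- function(data, items = NULL, subgroups = NULL,
                             config = analysis_config(), quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  subgroups <- subgroups %||% attr(x, "subgroups")
  run <- function(expr) {
    if (quiet) suppressMessages(expr) else expr
  }

  cohorts <- list(list(label = "overall", rows = seq_len(nrow(x))))
  for (sg in subgroups) {
    if (!sg %in% names(x)) abort(paste0("unknown subgroup column: ", sg))
    for (lev in sort(unique(as.character(x[[sg]])))) {
      cohorts <- c(cohorts, list(list(label = paste0(sg, ":", lev),
                                      rows = which(x[[sg]] == lev))))
    }
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, length(cohorts))

  results <- list()
  skipped <- list()
  for (i in seq_along(cohorts)) {
    ch <- cohorts[[i]]
    if (ch$label != "overall" && length(ch$rows) < config$min_subgroup_n) {
      if (!quiet) {
        inform(paste0("[", ch$label, "] skipped: n = ", length(ch$rows),
                      " below minimum subgroup size ", config$min_subgroup_n))
      }
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        label = ch$label, n = length(ch$rows),
        reason = paste0("n below minimum subgroup size ",
                        config$min_subgroup_n))
      next
    }
    sub <- x[ch$rows, , drop = FALSE]
    attr(sub, "items") <- attr(x, "items")
    results[[ch$label]] <- run(analyze_cohort(sub, ch$label, config,
                                              seed = seeds[i]))
  }
  structure(list(
    cohorts = results,
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(label = character(), n = integer(),
                     reason = character()),
    config = config,
    provenance = list(config_hash = rlang::hash(config), seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("symptomnet")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "analysis_report")
}

report_list <- function(report, include_timestamp = TRUE) {
  prov <- report$provenance
  if (!include_timestamp) prov$timestamp <- NULL
  list(
    provenance = prov,
    skipped = report$skipped,
    cohorts = purrr::map(report$cohorts, function(ch) {
      list(
        label = ch$label, n = ch$n, seed = ch$seed,
        prevalence = ch$prevalence,
        network = list(lambda = ch$network$lambda, ebic = ch$network$ebic,
                       gamma = ch$network$gamma,
                       nonzero = ch$edges$nonzero,
                       possible = ch$edges$possible,
                       percent = ch$edges$percent,
                       psd_repaired = ch$network$correlations$psd_repaired),
        top_edges = ch$top_edges,
        communities = list(membership = as.list(ch$communities$membership),
                           n_communities = ch$communities$n_communities,
                           hamiltonian = ch$communities$hamiltonian,
                           isolated = as.list(ch$communities$isolated),
                           largest_cluster = ch$communities$largest_cluster),
        centrality = ch$centrality,
        top_central = ch$top_central,
        stability = if (!is.null(ch$stability)) {
          list(cs = ch$stability$cs, n_boot = ch$stability$n_boot,
               n_skipped = ch$stability$n_skipped)
        },
        difference = if (!is.null(ch$difference)) {
          list(n_significant = sum(ch$difference$differences$significant),
               n_pairs = nrow(ch$difference$differences),
               n_boot = ch$difference$n_boot)
        })
    }))
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report` from [network_analysis()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @param include_timestamp Keep the timestamp provenance field (set to
#'   `FALSE` for byte-identical reproducibility checks).
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL, include_timestamp = TRUE) {
  stopifnot(inherits(report, "analysis_report"))
  js <- jsonlite::toJSON(report_list(report, include_timestamp),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Symptom network analysis report (", length(x$cohorts),
      " cohort(s))\n", sep = "")
  for (ch in x$cohorts) {
    cat("\n== ", ch$label, " (n = ", ch$n, ") ==\n", sep = "")
    cat("  edges: ", ch$edges$nonzero, "/", ch$edges$possible, " (",
        format(ch$edges$percent, nsmall = 1), "%), communities: ",
        ch$communities$n_communities, "\n", sep = "")
    top <- ch$top_central[ch$top_central$index == "strength", ]
    cat("  top strength: ", paste(top$item, collapse = ", "), "\n", sep = "")
    if (!is.null(ch$stability)) {
      cs <- ch$stability$cs
      cat("  CS: ", paste0(cs$index, " = ", format(cs$cs, nsmall = 2),
                           collapse = ", "), "\n", sep = "")
    }
  }
  if (nrow(x$skipped) > 0) {
    cat("\nSkipped: ", paste(x$skipped$label, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
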