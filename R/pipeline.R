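# Pipeline orchestration: simulate (or load) -> preprocess -> estimate
# (multilayer + synaptic-only) -> topology -> communities -> balance ->
# group comparison -> network-informed models, with a run manifest.

#' Default pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed.
#' @param n_perm permutations for the group comparison (0 disables it).
#' @param ... overrides (any entry of the returned list).
#' @return configuration list.
#' @export
pipeline_config <- function(out_dir = tempfile("synaptnet_run_"), seed = 1,
                            n_perm = 100, ...) {
  cfg <- list(out_dir = out_dir, seed = seed, gamma = 0.5, n_lambda = 100,
              lambda_min_ratio = 0.01, n_perm = n_perm, alpha = 0.05,
              spinglass_restarts = 10, powerlaw_boot = 200,
              simulate = list(n_per_group = 220),
              input = NULL)  # or list(high = csv, low = csv, meta = tsv)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file.
#' @return configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or loaded data and writes all
#' declared artifacts (GraphML + CSV edge lists, centrality CSV,
#' partition CSV, balance JSON, comparison JSON/CSV, regression CSVs)
#' plus a run manifest with configuration, seeds, warnings and file
#' hashes. Deterministic given the seed.
#'
#' @param config from [pipeline_config()] or [read_pipeline_config()].
#' @return invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    message("[synaptnet] ", msg)
    invisible(msg)
  }
  t0 <- Sys.time()
  # --- stage: data ---
  if (is.null(config$input)) {
    note("simulate: n = %d per group, seed = %d",
         config$simulate$n_per_group, config$seed)
    study <- generate_study(synthetic_config(
      n_per_group = config$simulate$n_per_group, seed = config$seed))
  } else {
    for (f in unlist(config$input))
      if (!file.exists(f)) stop("input file not found: ", f)
    note("load: %s", paste(unlist(config$input), collapse = ", "))
    meta <- read_node_meta(config$input$meta)
    load_grp <- function(path) {
      tb <- read_subject_table(path)
      cov_cols <- setdiff(colnames(tb$X), meta$node_id)
      list(X = tb$X[, meta$node_id, drop = FALSE],
           covariates = as.data.frame(tb$X[, cov_cols, drop = FALSE]))
    }
    study <- list(high = load_grp(config$input$high),
                  low = load_grp(config$input$low),
                  node_meta = meta, truth = NULL)
  }
  meta <- study$node_meta
  X_all <- rbind(study$high$X, study$low$X)
  # --- stage: preprocess ---
  npn <- nonparanormal_transform(X_all)
  # --- stage: estimate (multilayer, all subjects) ---
  note("estimate: multilayer network, p = %d", ncol(npn))
  est <- estimate_multilayer(npn, meta, gamma = config$gamma,
                             n_lambda = config$n_lambda,
                             lambda_min_ratio = config$lambda_min_ratio)
  net <- est$network
  write_network(net, file.path(config$out_dir, "multilayer.graphml"),
                file.path(config$out_dir, "multilayer_edges.csv"))
  # --- stage: topology ---
  cent <- centrality_table(net)
  topo <- topology_summary(net, n_boot = config$powerlaw_boot,
                           seed = config$seed)
  write.csv(cent, file.path(config$out_dir, "centrality.csv"),
            row.names = FALSE)
  jsonlite::write_json(topo, file.path(config$out_dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA)
  # --- stage: synaptic-only re-estimation + communities ---
  syn_ids <- meta$node_id[meta$layer == "synaptic_peptide"]
  note("estimate: synaptic-only network, p = %d", length(syn_ids))
  syn_est <- estimate_multilayer(npn[, syn_ids, drop = FALSE], meta,
                                 gamma = config$gamma,
                                 n_lambda = config$n_lambda,
                                 lambda_min_ratio = config$lambda_min_ratio)
  syn_net <- syn_est$network
  part <- spinglass_partition(syn_net, seed = config$seed,
                              n_restarts = config$spinglass_restarts)
  write.csv(data.frame(node_id = names(part$assignment),
                       module_id = as.integer(part$assignment)),
            file.path(config$out_dir, "partition.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(K = part$K, modularity_signed = part$modularity,
         modularity_positive = part$modularity_positive,
         transitivity = part$transitivity, hamiltonian = part$hamiltonian,
         seed = part$seed, n_restarts = part$n_restarts),
    file.path(config$out_dir, "partition.json"), auto_unbox = TRUE,
    digits = NA)
  write_network(syn_net, file.path(config$out_dir, "synaptic.graphml"),
                file.path(config$out_dir, "synaptic_edges.csv"))
  # --- stage: balance ---
  bal <- suppressWarnings(global_balance(net))
  jsonlite::write_json(
    list(n_triangles = bal$n_triangles, n_balanced = bal$n_balanced,
         balance_fraction = bal$balance_fraction),
    file.path(config$out_dir, "balance.json"), auto_unbox = TRUE,
    digits = NA)
  write.csv(bal$unbalanced, file.path(config$out_dir,
                                      "unbalanced_triangles.csv"),
            row.names = FALSE)
  # --- stage: group comparison ---
  comp <- NULL
  if (config$n_perm > 0) {
    note("compare: %d permutations", config$n_perm)
    comp <- nct(study$high$X, study$low$X, meta, n_perm = config$n_perm,
                alpha = config$alpha, gamma = config$gamma,
                n_lambda = config$n_lambda,
                lambda_min_ratio = config$lambda_min_ratio,
                seed = config$seed)
    write.csv(comp$edges, file.path(config$out_dir, "comparison_edges.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(global_diff = comp$global$diff, global_p = comp$global$p,
           n_perm = comp$n_perm, n_failed = comp$n_failed,
           interlayer = comp$interlayer),
      file.path(config$out_dir, "comparison.json"), auto_unbox = TRUE,
      digits = NA)
  }
  # --- stage: network-informed models ---
  models <- NULL
  covs <- rbind(study$high$covariates, study$low$covariates)
  if (!is.null(covs$cognition_z)) {
    scores <- vapply(sort(unique(part$assignment)), function(m)
      module_score(npn, part$assignment, m),
      numeric(nrow(npn)))
    colnames(scores) <- paste0("module", sort(unique(part$assignment)))
    assoc <- module_cognition_association(
      scores, covs$cognition_z,
      data.frame(age = covs$age, sex = covs$sex,
                 education = covs$education))
    write.csv(assoc, file.path(config$out_dir, "module_cognition.csv"),
              row.names = FALSE)
    mod2 <- if ("module2" %in% colnames(scores)) scores[, "module2"]
            else scores[, 1]
    ptau <- intersect(c("tau_AT100_t217", "tau_AT8_s202"), colnames(npn))
    mfit <- NULL
    if (length(ptau) == 2 && !is.null(covs$tangle_density)) {
      mfit <- threeway_moderation(covs$tangle_density, npn[, ptau[1]],
                                  npn[, ptau[2]], mod2, covs$activity)
      write.csv(mfit$coefficients,
                file.path(config$out_dir, "moderation.csv"),
                row.names = FALSE)
    }
    models <- list(module_cognition = assoc, moderation = mfit)
  }
  # --- manifest ---
  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("synaptnet")),
    config = config[setdiff(names(config), "input")],
    seed = config$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    file_hashes = as.list(tools::md5sum(files)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(network = net, fit = est$fit, centrality = cent,
                 topology = topo, synaptic_network = syn_net,
                 partition = part, balance = bal, comparison = comp,
                 models = models, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Render a plain-text/markdown report from an artifact directory
#'
#' Produces `report.md` plus network figures (seeded Fruchterman-Reingold
#' layout, blue positive / red negative edges) from the artifacts written
#' by [run_pipeline()].
#'
#' @param artifact_dir directory produced by [run_pipeline()].
#' @return path of the report file.
#' @export
render_report <- function(artifact_dir) {
  need <- c("multilayer.graphml", "centrality.csv", "topology.json",
            "partition.json", "balance.json")
  for (f in need)
    if (!file.exists(file.path(artifact_dir, f)))
      stop("missing artifact: ", f)
  topo <- jsonlite::read_json(file.path(artifact_dir, "topology.json"))
  part <- jsonlite::read_json(file.path(artifact_dir, "partition.json"))
  bal <- jsonlite::read_json(file.path(artifact_dir, "balance.json"))
  cent <- read.csv(file.path(artifact_dir, "centrality.csv"))
  plot_net <- function(graphml, png_out) {
    g <- igraph::read_graph(file.path(artifact_dir, graphml),
                            format = "graphml")
    grDevices::png(file.path(artifact_dir, png_out), 1200, 1200, res = 150)
    set.seed(42)
    igraph::plot.igraph(
      g, layout = igraph::layout_with_fr(g,
        weights = abs(igraph::E(g)$weight)),
      vertex.size = 4, vertex.label.cex = 0.4,
      edge.color = ifelse(igraph::E(g)$weight > 0, "steelblue", "firebrick"),
      edge.width = 3 * abs(igraph::E(g)$weight) /
        max(abs(igraph::E(g)$weight)))
    grDevices::dev.off()
    png_out
  }
  figs <- c(plot_net("multilayer.graphml", "multilayer.png"),
            if (file.exists(file.path(artifact_dir, "synaptic.graphml")))
              plot_net("synaptic.graphml", "synaptic.png"))
  lines <- c(
    "# Multilayer network analysis report", "",
    sprintf("- Global connectivity: %.4f", topo$global_connectivity),
    sprintf("- Diameter (1/|w| lengths): %.4f", topo$diameter),
    sprintf("- Power-law KS = %s, p = %s", format(topo$ks_statistic),
            format(topo$ks_pvalue)),
    sprintf("- Synaptic modules: K = %d, Q(signed) = %.3f, T = %.3f",
            part$K, part$modularity_signed, part$transitivity),
    sprintf("- Structural balance: %d triangles, fraction balanced = %s",
            bal$n_triangles, format(bal$balance_fraction)),
    sprintf("- Hub nodes: %s",
            paste(cent$node_id[cent$hub_flag], collapse = ", ")),
    "", paste(sprintf("![network](%s)", figs), collapse = "\n"))
  if (file.exists(file.path(artifact_dir, "comparison.json"))) {
    cmp <- jsonlite::read_json(file.path(artifact_dir, "comparison.json"))
    lines <- c(lines, "",
               sprintf("- Group comparison: global connectivity diff = %.4f (p = %.4f, %d permutations)",
                       cmp$global_diff, cmp$global_p, cmp$n_perm))
  } else {
    lines <- c(lines, "", "- Group comparison: not run")
  }
  out <- file.path(artifact_dir, "report.md")
  writeLines(lines, out)
  out
}
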