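#' Pipeline configuration
#'
#' Thresholds and settings of the HCIP scoring pipeline. Defaults follow the
#' published filtering scheme: control enrichment strictly greater than 10,
#' WD^N at least 1 against the 95% quantile of the simulated (permuted) WD
#' matrix, top-10 control averaging, three major modules.
#'
#' @param enrichment_min strict control-enrichment threshold (> pass).
#' @param wdn_min inclusive WD^N threshold (>= pass).
#' @param control_top_n control NSAF values averaged per protein.
#' @param sim_quantile quantile of the simulated WD distribution.
#' @param n_permutations permutation rounds for the threshold.
#' @param top_n_intensities precursor ions averaged by TOP3.
#' @param n_major_clusters modules cut from the dendrogram.
#' @param alpha_levels significance levels for `*` and `**`.
#' @param rescue_similarity_min strict r_u bound for rescue.
#' @param rng_seed integer seed for the permutation null.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(enrichment_min = 10,
                            wdn_min = 1,
                            control_top_n = 10L,
                            sim_quantile = 0.95,
                            n_permutations = 100L,
                            top_n_intensities = 3L,
                            n_major_clusters = 3L,
                            alpha_levels = c(0.05, 0.01),
                            rescue_similarity_min = 0,
                            rng_seed = 1L) {
  cfg <- list(enrichment_min = enrichment_min, wdn_min = wdn_min,
              control_top_n = as.integer(control_top_n),
              sim_quantile = sim_quantile,
              n_permutations = as.integer(n_permutations),
              top_n_intensities = as.integer(top_n_intensities),
              n_major_clusters = as.integer(n_major_clusters),
              alpha_levels = alpha_levels,
              rescue_similarity_min = rescue_similarity_min,
              rng_seed = as.integer(rng_seed))
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a list or a YAML file path; checks every threshold against its
#' invariant and rejects unknown keys.
#'
#' @param config list of settings or path to a YAML file.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("enrichment_min", "wdn_min", "control_top_n", "sim_quantile",
             "n_permutations", "top_n_intensities", "n_major_clusters",
             "alpha_levels", "rescue_similarity_min", "rng_seed")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key: ", unknown))
  }
  chk <- function(key, ok, msg) {
    if (!is.null(config[[key]]) && !ok(config[[key]])) {
      paste0(key, ": ", msg)
    } else character(0)
  }
  pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x > 0
  errs <- c(errs,
            chk("enrichment_min", pos, "must be strictly positive"),
            chk("wdn_min", pos, "must be strictly positive"),
            chk("control_top_n", function(x) pos(x) && x >= 1,
                "must be a positive integer"),
            chk("sim_quantile", function(x) pos(x) && x < 1,
                "must lie in the open unit interval"),
            chk("n_permutations", function(x) pos(x) && x >= 1,
                "must be a positive integer"),
            chk("top_n_intensities", function(x) pos(x) && x >= 1,
                "must be a positive integer"),
            chk("n_major_clusters", function(x) pos(x) && x >= 1,
                "must be a positive integer"),
            chk("alpha_levels", function(x) is.numeric(x) &&
                  length(x) == 2L && all(x > 0 & x < 1) && x[1] > x[2],
                "must be two decreasing levels in (0, 1)"),
            chk("rescue_similarity_min", function(x) is.numeric(x) &&
                  length(x) == 1L && x >= 0 && x < 1,
                "must lie in [0, 1)"),
            chk("rng_seed", function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), "must be an integer"))
  errs
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with [pipeline_config()] keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  errs <- validate_config(vals)
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  do.call(pipeline_config, vals)
}

#' Score high-confidence interacting proteins
#'
#' Runs the full HCIP scoring cascade on a dataset: NSAF, mock-control
#' profile, control-enrichment filter, WD scoring with the simulated-matrix
#' threshold, WD^N filter, bait-relative profiles, gene distance matrix,
#' profile-based rescue, module discovery, and network assembly.
#'
#' @param dataset an [apms_dataset()] with bait and control runs.
#' @param config a [pipeline_config()].
#' @param rescue apply the distance-based rescue stage (needs bait-relative
#'   profiles; requires every bait to be detected in its own runs).
#' @param cluster cut modules on the final network proteins.
#' @return list with elements `nsaf`, `control_profile`, `enrichment`,
#'   `stats`, `threshold`, `wd`, `rescued`, `modules`, `network`.
#' @export
score_hcip <- function(dataset, config = pipeline_config(), rescue = TRUE,
                       cluster = TRUE) {
  stopifnot(inherits(dataset, "apms_dataset"),
            inherits(config, "pipeline_config"))
  info <- run_info(dataset)
  if (!any(info$is_control)) {
    stop("enrichment stage requires mock-control runs ",
         "(bait token CONTROL:<name>); none found")
  }
  nsaf_bait <- compute_nsaf(dataset, "bait")
  nsaf_ctrl <- compute_nsaf(dataset, "control")
  profile <- build_control_profile(nsaf_ctrl, config$control_top_n)
  enr <- enrichment_filter(nsaf_bait, dataset, profile,
                           config$enrichment_min)
  stats_tab <- build_stats_table(nsaf_bait, dataset)
  threshold <- simulate_threshold(stats_tab, config$n_permutations,
                                  config$sim_quantile, config$rng_seed)
  wd <- wdn_filter(stats_tab, threshold, config$wdn_min)
  hcip <- wd[wd$passed, c("bait", "prey")]
  key_e <- paste(enr$bait, enr$prey)
  hcip <- hcip[enr$passed[match(paste(hcip$bait, hcip$prey), key_e)], ,
               drop = FALSE]
  gdm <- NULL
  rescued <- NULL
  if (rescue || cluster) {
    rel <- relative_abundance(nsaf_bait, dataset)
    gdm <- suppressWarnings(gene_distance_matrix(rel))
  }
  if (rescue) {
    rescued <- rescue_subthreshold(enr, wd, gdm, hcip,
                                   config$rescue_similarity_min)
  }
  network <- assemble_network(enr, wd, rescued)
  modules <- NULL
  if (cluster && nrow(network$edges)) {
    nodes <- intersect(network_nodes(network), rownames(gdm))
    if (length(nodes) >= config$n_major_clusters && length(nodes) >= 2L) {
      modules <- hierarchical_modules(gdm[nodes, nodes, drop = FALSE],
                                      config$n_major_clusters)
      network <- assemble_network(enr, wd, rescued, modules)
    }
  }
  list(nsaf = nsaf_bait, control_profile = profile, enrichment = enr,
       stats = stats_tab, threshold = threshold, wd = wd,
       rescued = rescued, modules = modules, network = network)
}

#' Precision and recall of a network against a planted truth
#'
#' @param network an [interaction_network()].
#' @param truth an [generate_truth()] result.
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`.
#' @export
hcip_performance <- function(network, truth) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(truth, "apms_truth"))
  pred <- unique(edge_key(network$edges$bait, network$edges$prey))
  true <- unique(edge_key(truth$true_edges$bait_id,
                          truth$true_edges$prey_id))
  tp <- sum(pred %in% true)
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(true)) tp / length(true) else NA_real_,
       n_predicted = length(pred), n_true = length(true))
}

#' Run the full analysis pipeline and write its outputs
#'
#' Executes scoring, clustering and (optionally) quantification in
#' dependency order and writes `nsaf.tsv`, `scores.tsv`, `modules.tsv`,
#' `network.tsv` / `network.sif` / `network.graphml`, optional `quant.tsv`,
#' and a machine-readable `run_record.json` with the config snapshot, seed,
#' stage timings and output checksums. Re-running with identical inputs and
#' config reproduces identical outputs.
#'
#' @param dataset an [apms_dataset()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quant `NULL`, or a list `(bait, condition_a, condition_b)`
#'   requesting a differential TOP3 comparison.
#' @return invisibly, the [score_hcip()] result list plus `quant` and
#'   `run_record`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), out_dir,
                         quant = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[pipeline] stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  scored <- stage("score", score_hcip(dataset, config))

  nsaf_long <- data.frame(
    run_id = rep(rownames(scored$nsaf), ncol(scored$nsaf)),
    protein_id = rep(colnames(scored$nsaf), each = nrow(scored$nsaf)),
    nsaf = as.vector(scored$nsaf)
  )
  nsaf_long <- nsaf_long[nsaf_long$nsaf > 0, ]
  stage("write_nsaf", write_tsv(nsaf_long, file.path(out_dir, "nsaf.tsv")))

  scores <- merge(scored$wd,
                  scored$enrichment[, c("bait", "prey", "control_value",
                                        "enrichment")],
                  by = c("bait", "prey"), all.x = TRUE, sort = TRUE)
  stage("write_scores",
        write_tsv(scores, file.path(out_dir, "scores.tsv")))

  if (!is.null(scored$modules)) {
    mod <- data.frame(protein_id = names(scored$modules$labels),
                      module = unname(scored$modules$labels))
    stage("write_modules",
          write_tsv(mod, file.path(out_dir, "modules.tsv")))
  }
  stage("write_network", {
    write_network(scored$network, file.path(out_dir, "network.tsv"),
                  "edge-table")
    write_network(scored$network, file.path(out_dir, "network.sif"), "sif")
    write_network(scored$network, file.path(out_dir, "network.graphml"),
                  "graphml")
  })

  quant_tab <- NULL
  if (!is.null(quant)) {
    quant_tab <- stage("quant", {
      rel_a <- relative_top3(dataset, quant$bait, quant$condition_a,
                             config$top_n_intensities)
      rel_b <- relative_top3(dataset, quant$bait, quant$condition_b,
                             config$top_n_intensities)
      compare_conditions(rel_a, rel_b, config$alpha_levels)
    })
    write_tsv(quant_tab, file.path(out_dir, "quant.tsv"))
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "run_record.json"]
  record <- list(
    config = unclass(config),
    seed = config$rng_seed,
    n_runs = nrow(run_info(dataset)),
    n_proteins = nrow(dataset$proteins),
    stage_seconds = timings,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(scored, list(quant = quant_tab, run_record = record)))
}
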