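#' Configuration for the synthetic AP-MS generator
#'
#' Defaults describe the simulated study conditions used throughout the test
#' suite: 12 baits in 3 modules with 2 biological replicates each, 300 true
#' preys, a 150-protein Zipf-structured contaminant background, 20 mock
#' control runs, and an expected sequencing depth of 10^4 spectral counts per
#' run. Counts are Poisson; precursor-ion intensities are lognormal with a
#' configurable coefficient of variation.
#'
#' @param n_baits,n_true_preys,n_contaminants,n_modules,replicates_per_bait,n_control_runs
#'   positive integers; `n_modules <= n_baits`, `replicates_per_bait >= 2`.
#' @param sequencing_depth expected total spectral counts per run.
#' @param contaminant_zipf_exponent exponent of the rank-abundance power law
#'   of the contaminant background.
#' @param contaminant_scale abundance of the top contaminant relative to the
#'   bait (bait = 1).
#' @param count_noise count noise model token; only `"poisson"` is defined.
#' @param intensity_cv coefficient of variation of the lognormal
#'   precursor-intensity model.
#' @param intensity_scale arbitrary intensity unit scale.
#' @param conditions character vector of condition labels to simulate per
#'   bait.
#' @param condition_effects `NULL` or a data.frame with columns `condition`,
#'   `bait_id`, `prey_id`, `factor`: multiplicative abundance effects on
#'   specific interactions in specific conditions.
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_baits = 12L,
                             n_true_preys = 300L,
                             n_contaminants = 150L,
                             n_modules = 3L,
                             replicates_per_bait = 2L,
                             n_control_runs = 20L,
                             sequencing_depth = 1e4,
                             contaminant_zipf_exponent = 2,
                             contaminant_scale = 0.5,
                             count_noise = "poisson",
                             intensity_cv = 0.3,
                             intensity_scale = 1e6,
                             conditions = "untreated",
                             condition_effects = NULL,
                             rng_seed = 1L) {
  cfg <- list(n_baits = as.integer(n_baits),
              n_true_preys = as.integer(n_true_preys),
              n_contaminants = as.integer(n_contaminants),
              n_modules = as.integer(n_modules),
              replicates_per_bait = as.integer(replicates_per_bait),
              n_control_runs = as.integer(n_control_runs),
              sequencing_depth = sequencing_depth,
              contaminant_zipf_exponent = contaminant_zipf_exponent,
              contaminant_scale = contaminant_scale,
              count_noise = count_noise,
              intensity_cv = intensity_cv,
              intensity_scale = intensity_scale,
              conditions = conditions,
              condition_effects = condition_effects,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_baits < 1 || n_contaminants < 0 || n_true_preys < 0 ||
        n_control_runs < 0) {
      stop("generator sizes must be non-negative (n_baits >= 1)")
    }
    if (n_modules > n_baits) stop("n_modules must not exceed n_baits")
    if (n_modules < 1) stop("n_modules must be >= 1")
    if (replicates_per_bait < 2) {
      stop("replicates_per_bait must be >= 2 (biological replicates)")
    }
    if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
    if (contaminant_zipf_exponent <= 0 || contaminant_scale <= 0) {
      stop("contaminant parameters must be positive")
    }
    if (!identical(count_noise, "poisson")) {
      stop("unsupported count_noise model: ", count_noise)
    }
    if (intensity_cv < 0 || intensity_scale <= 0) {
      stop("intensity model parameters invalid")
    }
  })
  if (!is.null(cfg$condition_effects)) {
    ce <- as.data.frame(cfg$condition_effects)
    req <- c("condition", "bait_id", "prey_id", "factor")
    if (!all(req %in% names(ce))) {
      stop("condition_effects needs columns ", paste(req, collapse = ", "))
    }
    if (any(ce$factor < 0)) stop("condition effect factors must be >= 0")
    cfg$condition_effects <- ce
  }
  structure(cfg, class = "generator_config")
}

#' Generate a planted interactome truth
#'
#' Baits are partitioned evenly across modules; each true prey belongs to one
#' module and attaches to 1--3 of that module's baits with a bait-relative
#' abundance drawn log-uniformly in \[0.01, 1\]. Contaminant background
#' abundances follow a Zipf power law. Protein lengths are drawn uniformly in
#' 100--1000 amino acids. Deterministic given `rng_seed`.
#'
#' @param config a [generator_config()].
#' @return object of class `apms_truth`: `proteins` (metadata table),
#'   `true_edges` (bait_id, prey_id, relative_abundance, module),
#'   `bait_modules` (named integer), `contaminant_profile` (named numeric),
#'   `condition_effects` (data.frame, possibly empty).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$rng_seed)
  baits <- sprintf("BAIT%02d", seq_len(config$n_baits))
  preys <- if (config$n_true_preys > 0)
    sprintf("PREY%03d", seq_len(config$n_true_preys)) else character(0)
  conts <- if (config$n_contaminants > 0)
    sprintf("CONT%03d", seq_len(config$n_contaminants)) else character(0)
  ids <- c(baits, preys, conts)
  proteins <- data.frame(
    protein_id = ids,
    length = sample(100:1000, length(ids), replace = TRUE),
    is_bait = ids %in% baits
  )
  bait_modules <- stats::setNames(
    sort(rep_len(seq_len(config$n_modules), config$n_baits)), baits)
  if (length(preys)) {
    prey_modules <- sort(rep_len(seq_len(config$n_modules), length(preys)))
    edge_list <- vector("list", length(preys))
    for (i in seq_along(preys)) {
      members <- baits[bait_modules == prey_modules[i]]
      deg <- sample.int(min(3L, length(members)), 1L)
      to <- sample(members, deg)
      edge_list[[i]] <- data.frame(
        bait_id = to,
        prey_id = preys[i],
        relative_abundance = exp(stats::runif(deg, log(0.01), log(1))),
        module = prey_modules[i]
      )
    }
    true_edges <- do.call(rbind, edge_list)
  } else {
    true_edges <- data.frame(bait_id = character(0), prey_id = character(0),
                             relative_abundance = numeric(0),
                             module = integer(0))
  }
  rownames(true_edges) <- NULL
  profile <- if (length(conts)) {
    stats::setNames(
      config$contaminant_scale *
        seq_len(config$n_contaminants) ^ (-config$contaminant_zipf_exponent),
      conts)
  } else stats::setNames(numeric(0), character(0))
  ce <- config$condition_effects
  if (is.null(ce)) {
    ce <- data.frame(condition = character(0), bait_id = character(0),
                     prey_id = character(0), factor = numeric(0))
  }
  structure(list(proteins = proteins, true_edges = true_edges,
                 bait_modules = bait_modules, contaminant_profile = profile,
                 condition_effects = ce),
            class = "apms_truth")
}

# expected-abundance vector for one run of `bait` under `condition`
.run_abundance <- function(truth, bait, condition) {
  a <- stats::setNames(numeric(nrow(truth$proteins)),
                       truth$proteins$protein_id)
  a[bait] <- 1
  te <- truth$true_edges
  sel <- te$bait_id == bait
  if (any(sel)) {
    rel <- te$relative_abundance[sel]
    ce <- truth$condition_effects
    if (nrow(ce)) {
      m <- match(paste(condition, bait, te$prey_id[sel]),
                 paste(ce$condition, ce$bait_id, ce$prey_id))
      rel <- rel * ifelse(is.na(m), 1, ce$factor[m])
    }
    a[te$prey_id[sel]] <- rel
  }
  a[names(truth$contaminant_profile)] <- truth$contaminant_profile
  a
}

# draw one run: Poisson counts under E[SpC_j] = depth * a_j L_j / sum(a L),
# lognormal precursor intensities with median proportional to a_j
.draw_run <- function(a, run_id, bait, replicate, condition, proteins,
                      config) {
  L <- proteins$length
  w <- a * L
  lambda <- config$sequencing_depth * w / sum(w)
  spc <- stats::rpois(length(lambda), lambda)
  # a bait run in which the bait itself is not identified would fail QC and
  # be re-acquired; condition on bait detection instead of dropping the run
  if (!is_control_bait(bait)) {
    b <- match(bait, proteins$protein_id)
    if (spc[b] == 0L) spc[b] <- 1L
  }
  keep <- spc > 0
  if (!any(keep)) return(NULL)
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  ints <- lapply(which(keep), function(j) {
    n_int <- max(3L, as.integer(round(L[j] / 50)))
    stats::rlnorm(n_int, meanlog = log(config$intensity_scale * a[j]),
                  sdlog = sdlog)
  })
  data.frame(run_id = run_id, bait_id = bait, replicate = replicate,
             condition = condition,
             protein_id = proteins$protein_id[keep],
             spc = spc[keep],
             intensities = I(ints))
}

#' Simulate bait purification runs from a planted truth
#'
#' For each bait, condition and biological replicate, the expected spectral
#' count of protein j is `depth * a_j L_j / sum_k a_k L_k`, where `a_j` is 1
#' for the bait itself, the planted bait-relative abundance times the
#' condition factor for true preys, and the background abundance for
#' contaminants; realized counts are Poisson. Deterministic given the config
#' seed.
#'
#' @param truth an [generate_truth()] result.
#' @param config the matching [generator_config()].
#' @return an [apms_dataset()] holding the bait runs (no controls).
#' @export
simulate_runs <- function(truth, config) {
  stopifnot(inherits(truth, "apms_truth"),
            inherits(config, "generator_config"))
  baits <- names(truth$bait_modules)
  if (!all(truth$true_edges$bait_id %in% baits)) {
    stop("truth references unknown bait: ",
         setdiff(truth$true_edges$bait_id, baits)[1L])
  }
  set.seed(config$rng_seed + 1L)
  rows <- list()
  for (bait in baits) {
    for (cond in config$conditions) {
      a <- .run_abundance(truth, bait, cond)
      for (rep_i in seq_len(config$replicates_per_bait)) {
        run_id <- paste(bait, cond, rep_i, sep = ".")
        rows[[run_id]] <- .draw_run(a, run_id, bait, rep_i, cond,
                                    truth$proteins, config)
      }
    }
  }
  apms_dataset(truth$proteins, do.call(rbind, rows))
}

#' Simulate mock-control purification runs
#'
#' Controls contain only the contaminant background (no bait, no true preys)
#' under the same count and intensity model as bait runs, mirroring mock
#' GFP/RFP affinity purifications.
#'
#' @inheritParams simulate_runs
#' @param control_tag reserved control bait token.
#' @return long run data.frame of `n_control_runs` control runs.
#' @export
simulate_controls <- function(truth, config, control_tag = "CONTROL:GFP") {
  stopifnot(inherits(truth, "apms_truth"),
            inherits(config, "generator_config"))
  set.seed(config$rng_seed + 2L)
  a <- stats::setNames(numeric(nrow(truth$proteins)),
                       truth$proteins$protein_id)
  a[names(truth$contaminant_profile)] <- truth$contaminant_profile
  rows <- list()
  for (i in seq_len(config$n_control_runs)) {
    run_id <- sprintf("%s.%03d", sub("^CONTROL:", "CTRL_", control_tag), i)
    rows[[run_id]] <- .draw_run(a, run_id, control_tag, i, "control",
                                truth$proteins, config)
  }
  do.call(rbind, rows)
}

#' Simulate a complete AP-MS dataset with known ground truth
#'
#' Convenience wrapper: [generate_truth()], [simulate_runs()] and
#' [simulate_controls()] combined into one dataset.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (an `apms_dataset` containing bait
#'   and control runs) and `truth` (the planted `apms_truth`).
#' @export
simulate_apms <- function(config = generator_config()) {
  truth <- generate_truth(config)
  ds <- simulate_runs(truth, config)
  ctrl <- simulate_controls(truth, config)
  runs <- rbind(ds$runs, ctrl)
  rownames(runs) <- NULL
  list(dataset = apms_dataset(truth$proteins, runs), truth = truth)
}
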