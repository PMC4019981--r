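#' Normalized spectral abundance factors (NSAF)
#'
#' For every run r and protein j,
#' `NSAF[r, j] = (SpC[r, j] / L_j) / sum_k (SpC[r, k] / L_k)`,
#' where `L_j` is the protein length in amino acids. Each row sums to 1 over
#' the proteins detected in that run; undetected proteins have NSAF 0.
#'
#' @param dataset an [apms_dataset()].
#' @param which which runs to include: `"all"` (default), `"bait"` or
#'   `"control"`.
#' @return numeric matrix, runs x proteins, with run ids as row names and
#'   protein ids as column names.
#' @export
compute_nsaf <- function(dataset, which = c("all", "bait", "control")) {
  stopifnot(inherits(dataset, "apms_dataset"))
  which <- match.arg(which)
  runs <- dataset$runs
  if (which != "all") {
    ctrl <- is_control_bait(runs$bait_id)
    runs <- runs[if (which == "control") ctrl else !ctrl, , drop = FALSE]
  }
  if (nrow(runs) == 0L) stop("no ", which, " runs in dataset")
  run_ids <- unique(runs$run_id)
  prot_ids <- dataset$proteins$protein_id
  spc <- matrix(0, length(run_ids), length(prot_ids),
                dimnames = list(run_ids, prot_ids))
  spc[cbind(match(runs$run_id, run_ids),
            match(runs$protein_id, prot_ids))] <- runs$spc
  sal <- sweep(spc, 2L, dataset$proteins$length, "/")
  tot <- rowSums(sal)
  if (any(tot == 0)) {
    stop("run has all-zero spectral counts: ", run_ids[tot == 0][1L])
  }
  sal / tot
}

#' Redistribute shared peptide-group counts to proteins
#'
#' Optional pre-step emulating shared-peptide count adjustment: the counts of
#' each shared group are distributed over its member proteins proportionally
#' to their unique-count evidence in the same run (equal split when no member
#' has unique evidence).
#'
#' @param dataset an [apms_dataset()] whose `runs$spc` hold unique counts.
#' @param shared_map `NULL` (identity) or a data.frame with columns `run_id`,
#'   `spc` (group count) and `proteins` (list column of member protein ids).
#' @return the adjusted `apms_dataset`; `spc` may become fractional.
#' @export
redistribute_shared_counts <- function(dataset, shared_map = NULL) {
  stopifnot(inherits(dataset, "apms_dataset"))
  if (is.null(shared_map) || nrow(shared_map) == 0L) return(dataset)
  runs <- dataset$runs
  for (g in seq_len(nrow(shared_map))) {
    members <- shared_map$proteins[[g]]
    unknown <- setdiff(members, dataset$proteins$protein_id)
    if (length(unknown)) {
      stop("shared group references unknown protein: ", unknown[1L])
    }
    rid <- shared_map$run_id[g]
    idx <- match(paste(rid, members), paste(runs$run_id, runs$protein_id))
    uniq <- ifelse(is.na(idx), 0, runs$spc[idx])
    share <- if (sum(uniq) > 0) uniq / sum(uniq)
             else rep(1 / length(members), length(members))
    add <- shared_map$spc[g] * share
    for (m in seq_along(members)) {
      if (add[m] == 0) next
      if (is.na(idx[m])) {
        tmpl <- runs[runs$run_id == rid, ][1L, ]
        if (is.na(tmpl$run_id)) stop("shared group references unknown run: ", rid)
        tmpl$protein_id <- members[m]
        tmpl$spc <- add[m]
        tmpl$intensities <- list(numeric(0))
        runs <- rbind(runs, tmpl)
      } else {
        runs$spc[idx[m]] <- runs$spc[idx[m]] + add[m]
      }
    }
  }
  rownames(runs) <- NULL
  dataset$runs <- runs
  dataset
}

#' Contaminant abundance profile from mock-control runs
#'
#' Per protein, its NSAF values across all control runs are sorted in
#' decreasing order, padded with zeros up to `control_top_n`, and the first
#' `control_top_n` values are averaged. The floor — applied downstream to
#' proteins absent from every control — is the smallest non-zero profile
#' value (1e-9 when the controls are empty of signal).
#'
#' @param control_nsaf NSAF matrix of the control runs
#'   (`compute_nsaf(dataset, "control")`).
#' @param control_top_n number of top values averaged (default 10).
#' @return list of class `control_profile` with `values` (named numeric, one
#'   per protein) and `floor`.
#' @export
build_control_profile <- function(control_nsaf, control_top_n = 10L) {
  if (control_top_n < 1) stop("control_top_n must be >= 1")
  if (nrow(control_nsaf) < 1L) stop("need at least one control run")
  values <- apply(control_nsaf, 2L, function(v) {
    v <- sort(v, decreasing = TRUE)
    sum(v[seq_len(min(control_top_n, length(v)))]) / control_top_n
  })
  nz <- values[values > 0]
  structure(list(values = values,
                 floor = if (length(nz)) min(nz) else 1e-9),
            class = "control_profile")
}

#' Control-enrichment filter for candidate interactions
#'
#' For each bait i and prey j detected in at least one of the bait's runs,
#' `xbar` is the mean NSAF across all of the bait's replicates (zeros
#' included for replicates where the prey is undetected), the control value
#' is `max(profile value, floor)`, and the enrichment ratio is
#' `E = xbar / control value`. A candidate passes when `E > enrichment_min`
#' (strict, default 10). The bait itself is not a candidate in its own runs.
#'
#' @param bait_nsaf NSAF matrix of the bait runs.
#' @param dataset the [apms_dataset()] (for run-to-bait grouping).
#' @param profile a [build_control_profile()] result.
#' @param enrichment_min strict pass threshold on E.
#' @return data.frame with columns `bait`, `prey`, `xbar`, `control_value`,
#'   `enrichment`, `passed`.
#' @export
enrichment_filter <- function(bait_nsaf, dataset, profile,
                              enrichment_min = 10) {
  stopifnot(inherits(profile, "control_profile"))
  if (enrichment_min <= 0) stop("enrichment_min must be positive")
  xbar <- bait_prey_means(bait_nsaf, dataset)
  ctrl <- pmax(profile$values[xbar$prey], profile$floor)
  out <- data.frame(bait = xbar$bait, prey = xbar$prey, xbar = xbar$xbar,
                    control_value = unname(ctrl),
                    enrichment = xbar$xbar / unname(ctrl))
  out$passed <- out$enrichment > enrichment_min
  out
}

# mean NSAF per (bait, prey) over all replicates of the bait (zeros
# included); candidates are preys detected in >= 1 replicate, self excluded
bait_prey_means <- function(bait_nsaf, dataset) {
  info <- run_info(dataset)
  info <- info[!info$is_control & info$run_id %in% rownames(bait_nsaf), ]
  if (nrow(info) == 0L) stop("dataset contains no bait runs")
  out <- list()
  for (bait in unique(info$bait_id)) {
    rows <- info$run_id[info$bait_id == bait]
    sub <- bait_nsaf[rows, , drop = FALSE]
    xbar <- colMeans(sub)
    ndet <- colSums(sub > 0)
    keep <- xbar > 0 & colnames(bait_nsaf) != bait
    out[[bait]] <- data.frame(bait = bait, prey = colnames(bait_nsaf)[keep],
                              xbar = unname(xbar[keep]),
                              n_detected = unname(ndet[keep]),
                              n_replicates = length(rows))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
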