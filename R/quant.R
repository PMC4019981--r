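#' TOP3 protein abundance from precursor-ion intensities
#'
#' Mean of the `top_n` (default 3) most intense precursor ions. When fewer
#' than `top_n` intensities are available, the mean of all available values
#' is returned and the result is flagged low-evidence (attribute
#' `low_evidence`).
#'
#' @param intensities numeric vector of positive precursor intensities.
#' @param top_n number of top intensities averaged.
#' @return positive scalar with logical attribute `low_evidence`.
#' @export
top3 <- function(intensities, top_n = 3L) {
  if (length(intensities) == 0L) {
    stop("undefined abundance: no precursor intensities")
  }
  if (any(intensities <= 0)) stop("intensities must be positive")
  v <- sort(intensities, decreasing = TRUE)
  n_used <- min(top_n, length(v))
  structure(mean(v[seq_len(n_used)]),
            low_evidence = length(v) < top_n)
}

#' Per-run TOP3 abundances
#'
#' @param dataset an [apms_dataset()].
#' @param run_id a run identifier.
#' @param top_n passed to [top3()].
#' @return data.frame `protein_id`, `top3`, `low_evidence` over the proteins
#'   of the run that carry intensities.
#' @export
run_top3 <- function(dataset, run_id, top_n = 3L) {
  rows <- dataset$runs[dataset$runs$run_id == run_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown run: ", run_id)
  has <- lengths(rows$intensities) > 0
  rows <- rows[has, , drop = FALSE]
  vals <- lapply(rows$intensities, top3, top_n = top_n)
  data.frame(protein_id = rows$protein_id,
             top3 = vapply(vals, as.numeric, numeric(1)),
             low_evidence = vapply(vals, attr, logical(1), "low_evidence"))
}

#' Bait-normalized relative abundances
#'
#' Divides every TOP3 abundance in a run by the bait's TOP3 abundance, as in
#' label-free normalization of pull-down intensities to the bait.
#'
#' @param top3_values a [run_top3()]-style data.frame for one run.
#' @param bait_id the bait of the run.
#' @return the input with an added `relative` column.
#' @export
bait_normalize <- function(top3_values, bait_id) {
  b <- top3_values$top3[top3_values$protein_id == bait_id]
  if (length(b) == 0L || !is.finite(b) || b <= 0) {
    stop("bait ", bait_id, " has no defined TOP3 abundance; run excluded")
  }
  top3_values$relative <- top3_values$top3 / b
  top3_values
}

#' Bait-relative TOP3 matrix for one bait and condition
#'
#' @param dataset an [apms_dataset()].
#' @param bait bait identifier.
#' @param condition condition label.
#' @param top_n passed to [top3()].
#' @return matrix preys x replicates of bait-relative abundances (0 where a
#'   prey is undetected in a replicate); the bait row equals 1.
#' @export
relative_top3 <- function(dataset, bait, condition, top_n = 3L) {
  info <- run_info(dataset)
  runs <- info$run_id[info$bait_id == bait & info$condition == condition]
  if (length(runs) == 0L) {
    stop("no runs for bait ", bait, " in condition ", condition)
  }
  per_run <- lapply(runs, function(r) {
    bait_normalize(run_top3(dataset, r, top_n = top_n), bait)
  })
  prots <- sort(unique(unlist(lapply(per_run, `[[`, "protein_id"))))
  mat <- matrix(0, length(prots), length(runs),
                dimnames = list(prots, runs))
  for (j in seq_along(per_run)) {
    mat[per_run[[j]]$protein_id, j] <- per_run[[j]]$relative
  }
  mat
}

#' Differential interaction analysis between two conditions
#'
#' Per prey, given replicate bait-relative abundances under conditions A and
#' B: `log2fc = log2((mean_B + eps) / (mean_A + eps))` with `eps` = half the
#' smallest non-zero relative abundance in the comparison, and a two-sided
#' two-sample t-test on `log(value + eps)` (equal-variance by default).
#' Stars: `**` for p < 0.01, `*` for 0.01 <= p < 0.05, `ns` otherwise. No
#' multiple-testing correction by default, matching per-protein asterisk
#' reporting; set `p_adjust = "BH"` for Benjamini-Hochberg on the stars.
#'
#' @param rel_a,rel_b matrices preys x replicates (see [relative_top3()]);
#'   rows are aligned by name, preys absent from one condition count as 0.
#' @param alpha_levels significance levels for `*` and `**`.
#' @param var_equal Student (TRUE, default) or Welch t-test.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return data.frame `prey`, `mean_rel_A`, `mean_rel_B`, `log2fc`,
#'   `p_value`, `stars`, `degenerate`.
#' @export
compare_conditions <- function(rel_a, rel_b, alpha_levels = c(0.05, 0.01),
                               var_equal = TRUE, p_adjust = "none") {
  if (ncol(rel_a) < 2L || ncol(rel_b) < 2L) {
    stop("need >= 2 replicates per condition")
  }
  preys <- sort(union(rownames(rel_a), rownames(rel_b)))
  get <- function(mat, p) if (p %in% rownames(mat)) mat[p, ] else
    rep(0, ncol(mat))
  nz <- c(rel_a[rel_a > 0], rel_b[rel_b > 0])
  if (length(nz) == 0L) stop("no non-zero abundances to compare")
  eps <- min(nz) / 2
  out <- lapply(preys, function(p) {
    va <- get(rel_a, p)
    vb <- get(rel_b, p)
    mA <- mean(va)
    mB <- mean(vb)
    degenerate <- FALSE
    la <- log(va + eps)
    lb <- log(vb + eps)
    if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      degenerate <- TRUE
      p_val <- if (isTRUE(all.equal(mA, mB))) 1 else 0
    } else {
      p_val <- stats::t.test(la, lb, var.equal = var_equal)$p.value
    }
    data.frame(prey = p, mean_rel_A = mA, mean_rel_B = mB,
               log2fc = log2((mB + eps) / (mA + eps)),
               p_value = p_val, degenerate = degenerate)
  })
  out <- do.call(rbind, out)
  p_star <- stats::p.adjust(out$p_value, method = p_adjust)
  out$stars <- ifelse(p_star < alpha_levels[2L], "**",
                      ifelse(p_star < alpha_levels[1L], "*", "ns"))
  rownames(out) <- NULL
  out
}

#' Time-course summary of bait-relative abundances
#'
#' Per prey and time point, the mean and standard deviation of the replicate
#' bait-relative abundances, ordered by time. A time point with a single
#' replicate reports `sd = NA`; a prey absent from a time point has no row
#' for it.
#'
#' @param rel_by_time named list, one preys x replicates matrix per time
#'   label (names like `"0"`, `"10"`, `"30"`, `"60"` are ordered
#'   numerically when possible, otherwise as given).
#' @return data.frame `prey`, `time`, `mean_rel`, `sd_rel`.
#' @export
time_course <- function(rel_by_time) {
  if (length(rel_by_time) < 2L) stop("need >= 2 time points")
  labels <- names(rel_by_time)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", labels)))
  if (!anyNA(num)) labels <- labels[order(num)]
  out <- list()
  for (lab in labels) {
    mat <- rel_by_time[[lab]]
    out[[lab]] <- data.frame(
      prey = rownames(mat),
      time = lab,
      mean_rel = rowMeans(mat),
      sd_rel = if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) else
        NA_real_
    )
  }
  res <- do.call(rbind, out)
  res$time <- factor(res$time, levels = labels)
  rownames(res) <- NULL
  res
}
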