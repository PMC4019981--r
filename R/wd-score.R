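#' Bait x prey statistics table for WD scoring
#'
#' Collects, from the bait-run NSAF matrix, the ingredients of the
#' CompPASS-family WD score: per (bait i, prey j) the mean NSAF `xbar[i, j]`
#' across bait i's replicates (zeros included) and the number `n[i, j]` of
#' replicates detecting j; per prey j the number of baits `f_j` detecting it
#' and a reproducibility weight `omega_j = max(1, s_j / m_j)` where `m_j` and
#' `s_j` are the mean and standard deviation of the non-zero `xbar` values of
#' prey j across baits (`omega_j = 1` when `f_j = 1`). `k` is the number of
#' bait groups; control runs are excluded.
#'
#' @param bait_nsaf NSAF matrix of the bait runs.
#' @param dataset the [apms_dataset()].
#' @return list of class `wd_stats` with `k` and `entries` (data.frame
#'   `bait`, `prey`, `xbar`, `n`, `f`, `omega`).
#' @export
build_stats_table <- function(bait_nsaf, dataset) {
  entries <- bait_prey_means(bait_nsaf, dataset)
  k <- length(unique(entries$bait))
  names(entries)[names(entries) == "n_detected"] <- "n"
  f_tab <- table(entries$prey)
  entries$f <- as.integer(f_tab[entries$prey])
  omega <- vapply(split(entries$xbar, entries$prey), function(x) {
    if (length(x) < 2L) return(1)
    m <- mean(x)
    s <- stats::sd(x)
    max(1, s / m)
  }, numeric(1))
  entries$omega <- unname(omega[entries$prey])
  entries$n_replicates <- NULL
  rownames(entries) <- NULL
  structure(list(k = k, entries = entries), class = "wd_stats")
}

# vectorized WD over an entries data.frame
.wd_values <- function(entries, k) {
  sqrt(entries$xbar * ((k / entries$f) * entries$omega) ^ entries$n)
}

#' WD score of one bait--prey entry
#'
#' `WD[i, j] = sqrt( xbar[i, j] * ((k / f_j) * omega_j) ^ n[i, j] )`:
#' abundance weighted by cross-bait frequency and replicate reproducibility.
#' Returns 0 when `xbar = 0`.
#'
#' @param table a [build_stats_table()] result.
#' @param bait,prey identifiers of the entry.
#' @return non-negative scalar.
#' @export
wd_score <- function(table, bait, prey) {
  stopifnot(inherits(table, "wd_stats"))
  i <- which(table$entries$bait == bait & table$entries$prey == prey)
  if (length(i) == 0L) return(0)
  e <- table$entries[i, , drop = FALSE]
  if (e$xbar == 0) return(0)
  if (e$f == 0) stop("inconsistent stats table: f = 0 with non-zero xbar")
  .wd_values(e, table$k)
}

# one permuted-table round: each prey's non-zero (xbar, n) pairs are
# reassigned uniformly at random (without replacement) to bait columns,
# preserving f_j and the value multiset; omega and WD are recomputed
.permuted_wd <- function(table) {
  ent <- table$entries
  perm <- ent
  for (idx in split(seq_len(nrow(ent)), ent$prey)) {
    f <- length(idx)
    baits <- sample.int(table$k, f)         # new bait columns
    ord <- sample.int(f)                    # shuffle value pairs
    perm$bait[idx] <- baits
    perm$xbar[idx] <- ent$xbar[idx][ord]
    perm$n[idx] <- ent$n[idx][ord]
  }
  omega <- vapply(split(perm$xbar, perm$prey), function(x) {
    if (length(x) < 2L) return(1)
    max(1, stats::sd(x) / mean(x))
  }, numeric(1))
  perm$omega <- unname(omega[perm$prey])
  .wd_values(perm, table$k)
}

#' WD-score threshold from a simulated (permuted) data matrix
#'
#' Builds `n_permutations` permuted tables in which each prey's non-zero
#' entries are randomly reassigned to bait columns (preserving its
#' cross-bait frequency and value multiset, i.e. its contaminant signature,
#' while destroying bait specificity), recomputes all WD scores, pools them,
#' and returns the `sim_quantile` empirical quantile — the value below which
#' that fraction of the simulated data falls. Raw WD scores are normalized
#' to this threshold to give WD^N.
#'
#' @param table a [build_stats_table()] result.
#' @param n_permutations number of permutation rounds (default 100).
#' @param sim_quantile quantile of the pooled simulated scores (default
#'   0.95).
#' @param rng_seed integer seed.
#' @param return_scores also return the pooled simulated WD scores.
#' @return the threshold (positive scalar), or a list `threshold`, `scores`
#'   when `return_scores = TRUE`.
#' @export
simulate_threshold <- function(table, n_permutations = 100L,
                               sim_quantile = 0.95, rng_seed = 1L,
                               return_scores = FALSE) {
  stopifnot(inherits(table, "wd_stats"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (sim_quantile <= 0 || sim_quantile >= 1) {
    stop("sim_quantile must lie in (0, 1)")
  }
  if (nrow(table$entries) == 0L || all(table$entries$xbar == 0)) {
    stop("stats table has no non-zero entries")
  }
  set.seed(rng_seed)
  pooled <- unlist(lapply(seq_len(n_permutations),
                          function(i) .permuted_wd(table)))
  pooled <- pooled[pooled > 0]
  thr <- unname(stats::quantile(pooled, sim_quantile))
  if (return_scores) list(threshold = thr, scores = pooled) else thr
}

#' Normalize WD scores and apply the WD^N filter
#'
#' `WDN = WD / threshold`; an interaction passes when `WDN >= wdn_min`
#' (inclusive, default 1).
#'
#' @param table a [build_stats_table()] result.
#' @param threshold positive threshold from [simulate_threshold()].
#' @param wdn_min inclusive pass threshold on WD^N.
#' @return data.frame `bait`, `prey`, `xbar`, `f`, `omega`, `n`, `wd`,
#'   `wdn`, `passed`.
#' @export
wdn_filter <- function(table, threshold, wdn_min = 1) {
  stopifnot(inherits(table, "wd_stats"))
  if (threshold <= 0) stop("threshold must be positive")
  ent <- table$entries
  out <- data.frame(bait = ent$bait, prey = ent$prey, xbar = ent$xbar,
                    f = ent$f, omega = ent$omega, n = ent$n,
                    wd = .wd_values(ent, table$k))
  out$wdn <- out$wd / threshold
  out$passed <- out$wdn >= wdn_min
  out
}
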