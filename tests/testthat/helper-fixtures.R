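# Shared fixtures: tiny hand-built datasets plus a lazily cached default
# synthetic simulation (reused across test files within one session).

.fixture_cache <- new.env(parent = emptyenv())

# default study-condition simulation + scoring, computed once per session
default_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_apms(generator_config(rng_seed = seed))
  }
  .fixture_cache[[key]]
}

default_scored <- function(seed = 1L) {
  key <- paste0("scored", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- default_sim(seed)
    .fixture_cache[[key]] <-
      score_hcip(sim$dataset, pipeline_config(rng_seed = seed))
  }
  .fixture_cache[[key]]
}

# two bait runs + one control over three proteins, hand-sized counts
toy_dataset <- function() {
  proteins <- data.frame(protein_id = c("BAITX", "PREYA", "CONTZ"),
                         length = c(100L, 200L, 400L))
  runs <- data.frame(
    run_id = c("r1", "r1", "r1", "r2", "r2", "c1"),
    bait_id = c("BAITX", "BAITX", "BAITX", "BAITX", "BAITX", "CONTROL:GFP"),
    replicate = c(1L, 1L, 1L, 2L, 2L, 1L),
    condition = "untreated",
    protein_id = c("BAITX", "PREYA", "CONTZ", "BAITX", "PREYA", "CONTZ"),
    spc = c(20L, 10L, 4L, 18L, 12L, 40L)
  )
  runs$intensities <- list(c(300, 200, 100), c(50, 40, 30), c(20, 10),
                           c(280, 210, 90), c(55, 42, 33), c(25, 12))
  apms_dataset(proteins, runs)
}

# stats table built directly (bypassing NSAF) for WD formula tests
manual_stats <- function(entries, k) {
  structure(list(k = k, entries = entries), class = "wd_stats")
}

# independent brute-force NSAF recomputation (loops, no matrix algebra)
oracle_nsaf <- function(dataset) {
  L <- stats::setNames(dataset$proteins$length, dataset$proteins$protein_id)
  ids <- dataset$proteins$protein_id
  out <- list()
  for (r in unique(dataset$runs$run_id)) {
    rows <- dataset$runs[dataset$runs$run_id == r, ]
    sal <- stats::setNames(numeric(length(ids)), ids)
    for (i in seq_len(nrow(rows))) {
      sal[rows$protein_id[i]] <- rows$spc[i] / L[rows$protein_id[i]]
    }
    out[[r]] <- sal / sum(sal)
  }
  do.call(rbind, out)
}

# independent brute-force top-n control averaging
oracle_control_profile <- function(control_nsaf, top_n) {
  vapply(colnames(control_nsaf), function(p) {
    v <- sort(control_nsaf[, p], decreasing = TRUE)
    v <- c(v, numeric(top_n))[seq_len(top_n)]   # zero padding
    mean(v)
  }, numeric(1))
}

# independent WD evaluation used by the exhaustive permutation oracle
oracle_wd <- function(xbar, n, f, omega, k) {
  sqrt(xbar * ((k / f) * omega)^n)
}

# exhaustive permutation null: for each prey enumerate every equally likely
# assignment of its value pairs to bait columns and pool the resulting WD
# scores. Each assignment round contributes one value list per prey, so the
# per-prey pools are reweighted to a common number of assignments before
# pooling (preys differ in how many assignments exist).
oracle_permutation_scores <- function(table) {
  ent <- table$entries
  k <- table$k
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  lcm2 <- function(a, b) a / gcd(a, b) * b
  per_prey <- lapply(split(seq_len(nrow(ent)), ent$prey), function(idx) {
    f <- length(idx)
    xb <- ent$xbar[idx]
    nn <- ent$n[idx]
    omega <- if (f < 2) 1 else max(1, stats::sd(xb) / mean(xb))
    cols <- utils::combn(k, f, simplify = FALSE)
    ords <- perms(f)
    pool <- numeric(0)
    for (co in cols) {
      for (o in seq_len(nrow(ords))) {
        pool <- c(pool, oracle_wd(xb[ords[o, ]], nn[ords[o, ]], f, omega, k))
      }
    }
    list(pool = pool, n_assign = length(cols) * nrow(ords))
  })
  total <- Reduce(lcm2, vapply(per_prey, `[[`, 0, "n_assign"))
  pooled <- unlist(lapply(per_prey, function(p) {
    rep(p$pool, times = total / p$n_assign)
  }))
  unname(pooled[pooled > 0])
}

perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# planted module label per protein of a truth object
planted_modules <- function(truth) {
  prey_mod <- tapply(truth$true_edges$module, truth$true_edges$prey_id,
                     function(m) m[1L])
  c(truth$bait_modules, unlist(prey_mod))
}
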