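test_that("stats table computes frequency and reproducibility weights", {
  # 3 baits, preys with different cross-bait patterns
  proteins <- data.frame(protein_id = c("B1", "B2", "B3", "P1", "P2", "P3"),
                         length = rep(100L, 6L))
  runs <- expand.grid(run_id = NA, bait_id = c("B1", "B2", "B3"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(runs))) {
    b <- runs$bait_id[i]
    r <- paste0(b, ".", runs$replicate[i])
    prots <- c(b, "P1"[b == "B1"], "P2", "P3"[b != "B3"])
    spc <- c(50L, 10L[b == "B1"], 5L, c(B1 = 2L, B2 = 6L)[b][b != "B3"])
    rows[[r]] <- data.frame(run_id = r, bait_id = b,
                            replicate = runs$replicate[i], condition = "u",
                            protein_id = prots, spc = unname(spc))
  }
  ds <- apms_dataset(proteins, do.call(rbind, rows))
  tab <- build_stats_table(compute_nsaf(ds, "bait"), ds)
  expect_equal(tab$k, 3L)
  ent <- tab$entries
  # P1 seen only with B1: f = 1, omega = 1
  expect_equal(ent$f[ent$prey == "P1"], 1L)
  expect_equal(ent$omega[ent$prey == "P1"], 1)
  # P2 is seen with every bait at similar abundance: cv < 1, omega floored
  expect_equal(unique(ent$f[ent$prey == "P2"]), 3L)
  expect_equal(unique(ent$omega[ent$prey == "P2"]), 1)
  # n counts detecting replicates
  expect_equal(ent$n[ent$prey == "P1"], 2L)
})

test_that("omega floors the coefficient of variation at one", {
  # xbar {0.1, 0.3}: cv = 0.1414/0.2 < 1 -> omega = 1
  ent <- data.frame(bait = c("B1", "B2"), prey = "P",
                    xbar = c(0.1, 0.3), n = c(1L, 1L), f = 2L, omega = NA)
  cv <- stats::sd(ent$xbar) / mean(ent$xbar)
  expect_lt(cv, 1)
  # rebuilt through the table constructor: manual two-bait dataset
  proteins <- data.frame(protein_id = c("B1", "B2", "P"),
                         length = rep(100L, 3L))
  runs <- data.frame(run_id = c("a1", "a1", "a2", "a2",
                                "b1", "b1", "b2", "b2"),
                     bait_id = rep(c("B1", "B2"), each = 4L),
                     replicate = rep(c(1L, 1L, 2L, 2L), 2L),
                     condition = "u",
                     protein_id = rep(c("B1", "P", "B1", "P"), 2L),
                     spc = c(90L, 10L, 90L, 10L, 70L, 30L, 70L, 30L))
  runs$protein_id[5:8] <- c("B2", "P", "B2", "P")
  ds <- apms_dataset(proteins, runs)
  tab <- build_stats_table(compute_nsaf(ds, "bait"), ds)
  expect_equal(unique(tab$entries$omega[tab$entries$prey == "P"]),
               max(1, stats::sd(c(0.1, 0.3)) / mean(c(0.1, 0.3))))
})

test_that("WD evaluates its closed form and zero abundance scores zero", {
  tab <- manual_stats(
    data.frame(bait = c("B1", "B2", "B3"), prey = c("P1", "P2", "P2"),
               xbar = c(0.04, 0.09, 0.09), n = c(2L, 1L, 1L),
               f = c(1L, 2L, 2L), omega = 1), k = 3L)
  # sqrt(0.04 * (3/1 * 1)^2) = 0.6
  expect_equal(wd_score(tab, "B1", "P1"), 0.6)
  # prey in all k baits with omega 1, n = 1: WD = sqrt(xbar)
  tab_all <- manual_stats(
    data.frame(bait = c("B1", "B2"), prey = "P", xbar = 0.25, n = 1L,
               f = 2L, omega = 1), k = 2L)
  expect_equal(wd_score(tab_all, "B1", "P"), 0.5)
  tab0 <- manual_stats(
    data.frame(bait = "B1", prey = "P", xbar = 0, n = 0L, f = 1L,
               omega = 1), k = 2L)
  expect_equal(wd_score(tab0, "B1", "P"), 0)
  expect_equal(wd_score(tab0, "B9", "P"), 0)
})

test_that("WD is monotone in abundance and replicate support", {
  base <- data.frame(bait = "B1", prey = "P", xbar = 0.1, n = 1L, f = 1L,
                     omega = 1.5)
  k <- 4L
  wd0 <- wd_score(manual_stats(base, k), "B1", "P")
  up_x <- base; up_x$xbar <- 0.2
  expect_gt(wd_score(manual_stats(up_x, k), "B1", "P"), wd0)
  up_n <- base; up_n$n <- 2L
  expect_gt(wd_score(manual_stats(up_n, k), "B1", "P"), wd0)
})

test_that("degenerate tables give threshold equal to the common WD and all pass", {
  # every prey in exactly one bait with identical xbar and n everywhere:
  # the permutation null is invariant, so WDN = 1 for all entries
  tab <- manual_stats(
    data.frame(bait = c("B1", "B2", "B3"), prey = c("P1", "P2", "P3"),
               xbar = 0.04, n = 2L, f = 1L, omega = 1), k = 3L)
  thr <- simulate_threshold(tab, n_permutations = 20L, rng_seed = 9L)
  expect_equal(thr, 0.6)
  res <- wdn_filter(tab, thr)
  expect_equal(res$wdn, rep(1, 3L))
  expect_true(all(res$passed))
})

test_that("sampled permutation null matches exhaustive enumeration", {
  # 3-bait x 4-prey toy with one 10x-enriched specific entry
  ent <- data.frame(
    bait = c("B1", "B1", "B2", "B3", "B1", "B2", "B3", "B2"),
    prey = c("Pspec", "Pcom", "Pcom", "Pcom", "Pmid", "Pmid", "Pmid", "Plone"),
    xbar = c(0.10, 0.012, 0.010, 0.011, 0.02, 0.018, 0.02, 0.01),
    n = c(2L, 2L, 2L, 1L, 1L, 2L, 1L, 1L))
  f_tab <- table(ent$prey)
  ent$f <- as.integer(f_tab[ent$prey])
  ent$omega <- vapply(split(ent$xbar, ent$prey)[ent$prey], function(x)
    if (length(x) < 2) 1 else max(1, stats::sd(x) / mean(x)), numeric(1))
  tab <- manual_stats(ent, k = 3L)
  exact <- oracle_permutation_scores(tab)
  for (s in 1:10) {
    sampled <- simulate_threshold(tab, n_permutations = 200L, rng_seed = s,
                                  return_scores = TRUE)
    ks <- suppressWarnings(stats::ks.test(sampled$scores, exact))
    expect_gt(ks$p.value, 0.01)
    # the planted specific entry sits at or above the threshold. On a table
    # this small its WD is the pooled maximum and carries more than 5% of
    # the null mass, so the 95% quantile ties with it exactly (WDN = 1).
    res <- wdn_filter(tab, sampled$threshold)
    expect_gte(res$wdn[res$prey == "Pspec"], 1)
    expect_true(res$passed[res$prey == "Pspec"])
  }
})

test_that("a planted specific entry normalizes strictly above one on larger tables", {
  # 21 entries: the specific entry carries < 5% of the pooled null mass, so
  # the 95% quantile falls below it and WDN exceeds 1 strictly
  common <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(bait = c("B1", "B2"), prey = sprintf("C%02d", i),
               xbar = 0.01 * c(1, 1.1) * i / 5, n = c(2L, 2L))
  }))
  ent <- rbind(data.frame(bait = "B3", prey = "Pspec", xbar = 0.1, n = 2L),
               common)
  f_tab <- table(ent$prey)
  ent$f <- as.integer(f_tab[ent$prey])
  ent$omega <- vapply(split(ent$xbar, ent$prey)[ent$prey], function(x)
    if (length(x) < 2) 1 else max(1, stats::sd(x) / mean(x)), numeric(1))
  tab <- manual_stats(ent, k = 4L)
  thr <- simulate_threshold(tab, n_permutations = 100L, rng_seed = 2L)
  res <- wdn_filter(tab, thr)
  expect_gt(res$wdn[res$prey == "Pspec"], 1)
  expect_equal(res$prey[which.max(res$wdn)], "Pspec")
})

test_that("WDN is invariant under global rescaling of abundances", {
  scored <- default_scored()
  tab <- scored$stats
  tab2 <- tab
  tab2$entries$xbar <- tab2$entries$xbar * 1000
  thr1 <- simulate_threshold(tab, 50L, rng_seed = 12L)
  thr2 <- simulate_threshold(tab2, 50L, rng_seed = 12L)
  expect_equal(thr2 / thr1, sqrt(1000), tolerance = 1e-9)
  expect_equal(wdn_filter(tab2, thr2)$wdn, wdn_filter(tab, thr1)$wdn,
               tolerance = 1e-9)
})

test_that("the WDN boundary is inclusive", {
  tab <- manual_stats(
    data.frame(bait = c("B1", "B2"), prey = c("P1", "P2"),
               xbar = c(0.09, 0.36), n = 1L, f = 1L, omega = 1), k = 2L)
  wd1 <- wd_score(tab, "B1", "P1")
  res <- wdn_filter(tab, threshold = wd1)
  expect_equal(res$wdn[res$prey == "P1"], 1)
  expect_true(res$passed[res$prey == "P1"])
  expect_equal(res$wdn[res$prey == "P2"], 2)
  zero <- wdn_filter(manual_stats(
    data.frame(bait = "B1", prey = "P", xbar = 0, n = 0L, f = 1L,
               omega = 1), 2L), threshold = wd1)
  expect_false(zero$passed)
  expect_error(wdn_filter(tab, threshold = 0), "positive")
})

test_that("threshold simulation validates its inputs", {
  tab <- manual_stats(data.frame(bait = "B1", prey = "P", xbar = 0, n = 0L,
                                 f = 1L, omega = 1), 2L)
  expect_error(simulate_threshold(tab), "non-zero")
  tab2 <- manual_stats(data.frame(bait = "B1", prey = "P", xbar = 0.1,
                                  n = 1L, f = 1L, omega = 1), 2L)
  expect_error(simulate_threshold(tab2, n_permutations = 0L),
               "n_permutations")
  expect_error(simulate_threshold(tab2, sim_quantile = 1), "sim_quantile")
})
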