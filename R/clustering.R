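#' Bait-relative abundance matrix
#'
#' For each bait run the NSAF of every protein is divided by the NSAF of the
#' bait in that run; ratios are averaged across the bait's replicates (zeros
#' included for undetected proteins). Rows are proteins, columns baits; a
#' bait's own entry in its own column is 1.
#'
#' @param bait_nsaf NSAF matrix of the bait runs.
#' @param dataset the [apms_dataset()].
#' @param proteins optional character vector restricting the rows.
#' @return numeric matrix, proteins x baits.
#' @export
relative_abundance <- function(bait_nsaf, dataset, proteins = NULL) {
  info <- run_info(dataset)
  info <- info[!info$is_control & info$run_id %in% rownames(bait_nsaf), ]
  if (nrow(info) == 0L) stop("dataset contains no bait runs")
  baits <- sort(unique(info$bait_id))
  if (is.null(proteins)) proteins <- colnames(bait_nsaf)
  mat <- matrix(0, length(proteins), length(baits),
                dimnames = list(proteins, baits))
  for (bait in baits) {
    rows <- info$run_id[info$bait_id == bait]
    ratios <- sapply(rows, function(r) {
      b <- bait_nsaf[r, bait]
      if (b <= 0) {
        stop("bait ", bait, " undetected in its own run ", r)
      }
      bait_nsaf[r, proteins] / b
    })
    mat[, bait] <- rowMeans(matrix(ratios, nrow = length(proteins)))
  }
  mat
}

#' Gene distance matrix from uncentered Pearson correlation
#'
#' `d(x, y) = 1 - r_u(x, y)` with
#' `r_u(x, y) = sum(x*y) / sqrt(sum(x^2) * sum(y^2))` (cosine-like, no mean
#' centering). For non-negative profiles d lies in \[0, 1\]; the diagonal is
#' 0. All-zero profiles are dropped with a warning.
#'
#' @param matrix profile matrix (rows = proteins, columns = baits), e.g. from
#'   [relative_abundance()].
#' @return symmetric distance matrix with protein ids as dimnames.
#' @export
gene_distance_matrix <- function(matrix) {
  norms <- sqrt(rowSums(matrix ^ 2))
  zero <- norms == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero profile(s): ",
            paste(utils::head(rownames(matrix)[zero], 3L), collapse = ", "))
    matrix <- matrix[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  if (nrow(matrix) < 2L) stop("need at least two non-zero profiles")
  r_u <- tcrossprod(matrix / norms)
  d <- 1 - r_u
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

#' Hierarchical module discovery on a gene distance matrix
#'
#' Agglomerative clustering with average linkage on the uncentered-Pearson
#' distances, cut into `n_major_clusters` modules (default 3). Profiles are
#' ordered lexicographically before clustering and modules are renumbered by
#' their lexicographically smallest member, so the result is deterministic.
#'
#' @param gdm symmetric distance matrix from [gene_distance_matrix()].
#' @param n_major_clusters number of modules to cut.
#' @return list of class `module_assignment` with `labels` (named integer,
#'   module index per protein) and `tree` (the `hclust` object).
#' @export
hierarchical_modules <- function(gdm, n_major_clusters = 3L) {
  if (n_major_clusters < 1) stop("n_major_clusters must be >= 1")
  if (n_major_clusters > nrow(gdm)) {
    stop("n_major_clusters exceeds the number of profiles")
  }
  ord <- order(rownames(gdm))
  gdm <- gdm[ord, ord, drop = FALSE]
  tree <- stats::hclust(stats::as.dist(gdm), method = "average")
  raw <- stats::cutree(tree, k = n_major_clusters)
  # renumber modules by lexicographically smallest member
  first <- vapply(split(names(raw), raw), min, character(1))
  relabel <- stats::setNames(rank(first, ties.method = "first"),
                             names(first))
  labels <- stats::setNames(as.integer(relabel[as.character(raw)]),
                            names(raw))
  structure(list(labels = labels, tree = tree),
            class = "module_assignment")
}

#' Rescue sub-threshold interactions by profile similarity
#'
#' Candidates that pass the control-enrichment filter but fall below the
#' WD^N threshold are rescued when the prey's bait-relative profile has
#' positive uncentered-Pearson similarity (`r_u > similarity_min`, strict)
#' with the profile of at least one high-confidence interactor of the same
#' bait. Preys without a profile in the distance matrix are never rescued.
#'
#' @param enrichment [enrichment_filter()] result.
#' @param wd [wdn_filter()] result.
#' @param gdm distance matrix covering the candidate proteins (built from
#'   the bait-relative profiles of the unfiltered candidate set).
#' @param hcip_edges data.frame `bait`, `prey` of the strictly passing
#'   high-confidence interactions.
#' @param similarity_min strict lower bound on r_u (default 0).
#' @return data.frame `bait`, `prey`, `max_similarity`, `rescued` over the
#'   sub-threshold candidates.
#' @export
rescue_subthreshold <- function(enrichment, wd, gdm, hcip_edges,
                                similarity_min = 0) {
  key_e <- paste(enrichment$bait, enrichment$prey)
  key_w <- paste(wd$bait, wd$prey)
  m <- match(key_e, key_w)
  sub <- enrichment$passed & !is.na(m) & !wd$passed[m]
  cand <- enrichment[sub, c("bait", "prey")]
  if (nrow(cand) == 0L) {
    return(data.frame(bait = character(0), prey = character(0),
                      max_similarity = numeric(0), rescued = logical(0)))
  }
  cand$max_similarity <- NA_real_
  cand$rescued <- FALSE
  ids <- rownames(gdm)
  for (i in seq_len(nrow(cand))) {
    if (!cand$prey[i] %in% ids) next
    anchors <- hcip_edges$prey[hcip_edges$bait == cand$bait[i]]
    anchors <- setdiff(intersect(anchors, ids), cand$prey[i])
    if (length(anchors) == 0L) next
    r_u <- 1 - gdm[cand$prey[i], anchors]
    cand$max_similarity[i] <- max(r_u)
    cand$rescued[i] <- max(r_u) > similarity_min
  }
  rownames(cand) <- NULL
  cand
}

#' Assemble the final high-confidence interaction network
#'
#' Edge set = interactions passing both the enrichment and WD^N filters,
#' plus rescued sub-threshold interactions. Edges carry all scores, the
#' rescue flag and (when module labels are given) the prey's module.
#' Bait--bait pairs scored from both directions are deduplicated into one
#' canonical edge that retains the reverse direction's WD^N.
#'
#' @param enrichment [enrichment_filter()] result.
#' @param wd [wdn_filter()] result.
#' @param rescued optional [rescue_subthreshold()] result.
#' @param modules optional [hierarchical_modules()] result.
#' @return an [interaction_network()].
#' @export
assemble_network <- function(enrichment, wd, rescued = NULL,
                             modules = NULL) {
  key_e <- paste(enrichment$bait, enrichment$prey)
  key_w <- paste(wd$bait, wd$prey)
  m <- match(key_w, key_e)
  tab <- data.frame(bait = wd$bait, prey = wd$prey, xbar = wd$xbar,
                    enrichment = ifelse(is.na(m), NA_real_,
                                        enrichment$enrichment[m]),
                    wd = wd$wd, wdn = wd$wdn)
  both <- wd$passed & !is.na(m) & enrichment$passed[m]
  pass <- tab[both, , drop = FALSE]
  pass$rescued <- logical(nrow(pass))
  if (!is.null(rescued) && nrow(rescued)) {
    res <- rescued[rescued$rescued, c("bait", "prey"), drop = FALSE]
    if (nrow(res)) {
      key_r <- paste(res$bait, res$prey)
      add <- tab[match(key_r, paste(tab$bait, tab$prey)), , drop = FALSE]
      add$rescued <- TRUE
      pass <- rbind(pass, add)
    }
  }
  if (nrow(pass) == 0L) {
    return(interaction_network(
      data.frame(bait = character(0), prey = character(0))))
  }
  if (!is.null(modules)) {
    lab <- modules$labels
    pass$module <- ifelse(pass$prey %in% names(lab),
                          lab[pass$prey], NA_integer_)
  }
  # canonical dedup of pairs scored from both bait directions
  key <- edge_key(pass$bait, pass$prey)
  pass$wdn_reverse <- NA_real_
  drop <- logical(nrow(pass))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep <- idx[order(pass$bait[idx])][1L]   # canonical direction
    other <- setdiff(idx, keep)
    pass$wdn_reverse[keep] <- max(pass$wdn[other])
    pass$rescued[keep] <- all(pass$rescued[idx])
    drop[other] <- TRUE
  }
  pass <- pass[!drop, , drop = FALSE]
  rownames(pass) <- NULL
  interaction_network(pass)
}

#' Recall against a reference interaction set
#'
#' Fraction of reference interactions (restricted to those supported by at
#' least `min_publications` publications) recovered in the network; edges
#' are compared as unordered pairs.
#'
#' @param network an [interaction_network()].
#' @param reference a [read_reference_ppi()]-style data.frame.
#' @param min_publications stratum cutoff (>= , default 1).
#' @return recall fraction in \[0, 1\].
#' @export
recall_vs_reference <- function(network, reference, min_publications = 1L) {
  stopifnot(inherits(network, "interaction_network"))
  stratum <- reference[reference$n_publications >= min_publications, ,
                       drop = FALSE]
  if (nrow(stratum) == 0L) stop("reference stratum is empty")
  ref_keys <- edge_key(stratum$protein_a, stratum$protein_b)
  net_keys <- edge_key(network$edges$bait, network$edges$prey)
  mean(ref_keys %in% net_keys)
}

#' Count within-family dimeric sub-complexes
#'
#' Number of distinct unordered pairs of family members joined by an edge in
#' the network: the count of potentially concurrent pairwise sub-complexes
#' a family of homotypic dimerization domains (e.g. SARAH) can form.
#'
#' @param network an [interaction_network()].
#' @param family character vector of family member ids.
#' @return integer count.
#' @export
enumerate_family_dimers <- function(network, family) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  within <- e$bait %in% family & e$prey %in% family & e$bait != e$prey
  length(unique(edge_key(e$bait[within], e$prey[within])))
}

#' SARAH-domain family selectivity network
#'
#' The reported binding selectivity among the nine human SARAH-domain
#' proteins: the Hippo kinases MST1 and MST2 each bind SAV1 and all six
#' RASSF proteins, MST1 and MST2 form a heterodimer, and no RASSF--RASSF or
#' RASSF--SAV1 pairs are observed.
#'
#' @return an [interaction_network()] over the nine-member family.
#' @export
sarah_selectivity_network <- function() {
  partners <- c("SAV1", paste0("RASF", 1:6))
  edges <- rbind(
    data.frame(bait = "MST1", prey = partners),
    data.frame(bait = "MST2", prey = partners),
    data.frame(bait = "MST1", prey = "MST2")
  )
  interaction_network(edges)
}

#' Members of the SARAH-domain protein family
#'
#' @return character vector: MST1, MST2, SAV1, RASF1--RASF6.
#' @export
sarah_family <- function() {
  c("MST1", "MST2", "SAV1", paste0("RASF", 1:6))
}
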