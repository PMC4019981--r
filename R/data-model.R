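#' @title AP-MS dataset container
#'
#' @description An `apms_dataset` bundles the protein metadata and the long
#' table of purification runs (bait pull-downs plus mock controls) that every
#' downstream stage consumes. Runs are stored in long format (one row per
#' run x detected protein) because AP-MS count matrices are sparse.
#'
#' @param proteins data.frame with columns `protein_id` (unique character),
#'   `length` (amino acids, >= 1) and optionally `is_bait` (logical; inferred
#'   from the runs when absent).
#' @param runs data.frame with columns `run_id`, `bait_id`, `replicate`,
#'   `condition`, `protein_id`, `spc` (non-negative integer spectral count)
#'   and optionally `intensities` (list column of positive numeric vectors,
#'   one precursor-ion intensity list per protein).
#'
#' Mock-control runs carry the reserved bait token `CONTROL:<name>`
#' (e.g. `CONTROL:GFP`); every other run must contain its own bait.
#'
#' @return An object of class `apms_dataset` with elements `proteins` and
#'   `runs`.
#' @export
apms_dataset <- function(proteins, runs) {
  proteins <- as.data.frame(proteins)
  runs <- as.data.frame(runs)
  req_p <- c("protein_id", "length")
  req_r <- c("run_id", "bait_id", "replicate", "condition", "protein_id", "spc")
  if (!all(req_p %in% names(proteins))) {
    stop("protein table lacks required column(s): ",
         paste(setdiff(req_p, names(proteins)), collapse = ", "))
  }
  if (!all(req_r %in% names(runs))) {
    stop("run table lacks required column(s): ",
         paste(setdiff(req_r, names(runs)), collapse = ", "))
  }
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein_id in protein table: ",
         proteins$protein_id[duplicated(proteins$protein_id)][1L])
  }
  bad_len <- which(!is.finite(proteins$length) | proteins$length < 1)
  if (length(bad_len)) {
    stop("protein table row ", bad_len[1L], " (",
         proteins$protein_id[bad_len[1L]], "): length must be >= 1")
  }
  proteins$length <- as.integer(round(proteins$length))
  bad_spc <- which(!is.finite(runs$spc) | runs$spc < 0)
  if (length(bad_spc)) {
    stop("run table row ", bad_spc[1L], " (run ", runs$run_id[bad_spc[1L]],
         ", protein ", runs$protein_id[bad_spc[1L]],
         "): spectral count must be a non-negative integer")
  }
  unknown <- setdiff(runs$protein_id, proteins$protein_id)
  if (length(unknown)) {
    stop("run table references protein(s) absent from the protein table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (!"intensities" %in% names(runs)) {
    runs$intensities <- replicate(nrow(runs), numeric(0), simplify = FALSE)
  }
  if (!"is_bait" %in% names(proteins)) {
    proteins$is_bait <- proteins$protein_id %in%
      runs$bait_id[!is_control_bait(runs$bait_id)]
  }
  # a non-control run must contain its own bait
  info <- unique(runs[, c("run_id", "bait_id")])
  for (i in seq_len(nrow(info))) {
    if (is_control_bait(info$bait_id[i])) next
    sel <- runs$run_id == info$run_id[i] & runs$protein_id == info$bait_id[i]
    if (!any(sel)) {
      stop("run ", info$run_id[i], " does not contain its bait ",
           info$bait_id[i])
    }
  }
  structure(list(proteins = proteins, runs = runs), class = "apms_dataset")
}

#' Is a bait token a mock-control tag?
#'
#' Control purifications (GFP/RFP mock APs) are marked by the reserved bait
#' token `CONTROL:<name>`.
#'
#' @param bait_id character vector of bait tokens.
#' @return logical vector.
#' @export
is_control_bait <- function(bait_id) {
  startsWith(as.character(bait_id), "CONTROL:")
}

#' Run-level metadata of a dataset
#'
#' @param dataset an `apms_dataset`.
#' @return data.frame with one row per run: `run_id`, `bait_id`, `replicate`,
#'   `condition`, `is_control`.
#' @export
run_info <- function(dataset) {
  stopifnot(inherits(dataset, "apms_dataset"))
  info <- unique(dataset$runs[, c("run_id", "bait_id", "replicate",
                                  "condition")])
  info$is_control <- is_control_bait(info$bait_id)
  rownames(info) <- NULL
  info
}

#' @export
print.apms_dataset <- function(x, ...) {
  info <- run_info(x)
  cat("apms_dataset:", nrow(x$proteins), "proteins,",
      sum(!info$is_control), "bait runs (",
      length(unique(info$bait_id[!info$is_control])), "baits ),",
      sum(info$is_control), "control runs\n")
  invisible(x)
}

#' Read an AP-MS dataset from delimited text tables
#'
#' The run table is long format, one row per run x protein, with columns
#' `run_id`, `bait_id`, `replicate`, `condition`, `protein_id`, `spc`,
#' `intensities`; the intensity list is a single `;`-joined cell. The protein
#' table has columns `protein_id`, `length` and optionally `is_bait`.
#' Tab-delimited by default; comma autodetected from the header line.
#'
#' @param run_table,protein_table paths to delimited text files.
#' @return an [apms_dataset()].
#' @export
read_dataset <- function(run_table, protein_table) {
  runs <- read_delim_auto(run_table)
  proteins <- read_delim_auto(protein_table)
  if ("intensities" %in% names(runs)) {
    runs$intensities <- parse_intensity_cells(runs$intensities)
  }
  apms_dataset(proteins, runs)
}

#' Write an AP-MS dataset to delimited text tables
#'
#' Inverse of [read_dataset()]: intensity lists are serialized as `;`-joined
#' decimals, output is UTF-8 tab-delimited with LF line endings.
#'
#' @param dataset an `apms_dataset`.
#' @param run_table,protein_table output paths.
#' @return invisibly, the dataset.
#' @export
write_dataset <- function(dataset, run_table, protein_table) {
  stopifnot(inherits(dataset, "apms_dataset"))
  runs <- dataset$runs
  runs$intensities <- vapply(
    runs$intensities,
    function(v) paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                      collapse = ";"),
    character(1)
  )
  runs$intensities[runs$intensities == ""] <- NA_character_
  write_tsv(runs, run_table)
  cols <- intersect(c("protein_id", "length", "is_bait"),
                    names(dataset$proteins))
  write_tsv(dataset$proteins[, cols], protein_table)
  invisible(dataset)
}

parse_intensity_cells <- function(x) {
  lapply(as.character(x), function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(numeric(0))
    v <- as.numeric(strsplit(cell, ";", fixed = TRUE)[[1L]])
    if (anyNA(v) || any(v <= 0)) {
      stop("intensity cell is not a ;-joined list of positive numbers: ",
           cell)
    }
    v
  })
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a reference protein-protein interaction table
#'
#' Expects columns `protein_a`, `protein_b`, `n_publications`. Edges are
#' undirected and returned canonicalized (lexicographically ordered pair);
#' duplicate pairs are merged keeping the maximum publication count;
#' self-edges are kept with a warning.
#'
#' @param table path to a delimited text file.
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `n_publications`, canonical and deduplicated.
#' @export
read_reference_ppi <- function(table) {
  df <- read_delim_auto(table)
  req <- c("protein_a", "protein_b", "n_publications")
  if (!all(req %in% names(df))) {
    stop("reference PPI table lacks required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      n_publications = integer(0)))
  }
  if (any(df$n_publications < 1)) stop("n_publications must be >= 1")
  if (any(df$protein_a == df$protein_b)) {
    warning("reference contains self-edge(s); kept")
  }
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(df$n_publications, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[`, "", 1L),
                    protein_b = vapply(parts, `[`, "", 2L),
                    n_publications = as.integer(agg))
  rownames(out) <- NULL
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Canonical unordered edge keys
#'
#' @param a,b character vectors of node identifiers.
#' @return character vector of keys such that `edge_key(a, b)` equals
#'   `edge_key(b, a)`.
#' @export
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
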