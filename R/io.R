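#' Coerce a count table to a samples-by-taxa integer matrix
#'
#' Count tables travel through the pipeline as wide tibbles with a
#' `sample_id` column followed by one non-negative integer column per taxon.
#' Internals (UniFrac, SRS, diversity) work on the equivalent matrix; this
#' converts between the two representations.
#'
#' @param counts A wide count tibble (`sample_id` + taxon columns) or a
#'   numeric matrix with sample row names.
#' @return `count_matrix()` returns an integer matrix with sample row names;
#'   `count_tibble()` returns the wide tibble form.
#' @export
count_matrix <- function(counts, integer = TRUE) {
  if (is.matrix(counts)) {
    validate_count_matrix(counts, integer = integer)
    return(counts)
  }
  stopifnot(is.data.frame(counts))
  if (!"sample_id" %in% names(counts)) {
    stop_oralhsct("count table must have a 'sample_id' column")
  }
  m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
  rownames(m) <- counts$sample_id
  storage.mode(m) <- "double"
  validate_count_matrix(m, integer = integer)
  m
}

#' @rdname count_matrix
#' @export
count_tibble <- function(counts, integer = TRUE) {
  m <- count_matrix(counts, integer = integer)
  bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

validate_count_matrix <- function(m, integer = TRUE) {
  if (is.null(rownames(m))) stop_oralhsct("count matrix must have sample row names")
  if (anyDuplicated(rownames(m))) stop_oralhsct("duplicated sample ids in count table")
  if (anyDuplicated(colnames(m))) stop_oralhsct("duplicated taxon ids in count table")
  bad <- which(is.na(m) | m < 0 | (integer & m != floor(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_oralhsct(sprintf(
      "count table cell [taxon '%s', sample '%s'] is not a non-negative integer (value: %s)",
      colnames(m)[bad[1, 2]], rownames(m)[bad[1, 1]], m[bad[1, 1], bad[1, 2]]
    ))
  }
  invisible(m)
}

#' Read and write count tables (taxa rows x sample columns TSV)
#'
#' The on-disk dialect follows the BIOM-TSV convention: a tab-separated file
#' whose first column (`taxon_id`) names taxa and whose remaining columns are
#' samples, cells holding non-negative integer read counts. In memory the
#' table is transposed to the samples-by-taxa wide tibble used everywhere
#' else. Writing then reading a table is the identity.
#'
#' @param path File path.
#' @param counts A count table (see [count_matrix()]).
#' @return `read_count_table()` returns a wide count tibble;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop_oralhsct("no taxa in count table")
  taxa <- as.character(raw[[1]])
  m <- t(as.matrix(raw[-1]))
  colnames(m) <- taxa
  if (!is.numeric(m)) {
    # locate first non-numeric cell for the error message
    mm <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
    bad <- which(is.na(mm) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_oralhsct(sprintf("count table cell [taxon '%s', sample '%s'] is not numeric",
                            colnames(m)[bad[1, 2]], rownames(m)[bad[1, 1]]))
    }
    m <- mm
  }
  storage.mode(m) <- "double"
  validate_count_matrix(m)
  count_tibble(m)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path) {
  m <- count_matrix(counts)
  out <- bind_cols(tibble(taxon_id = colnames(m)),
                   as_tibble(t(m), .name_repair = "minimal"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata links each sequenced sample to its patient, oral site
#' (GCF/OM/SB), clinical timepoint (P/A/E/E30/E75) and collection day
#' (integer offset from stem-cell infusion at day 0). The
#' (patient, site, timepoint) triple must be unique.
#'
#' @param path CSV file with columns `sample_id`, `patient_id`, `site`,
#'   `timepoint`, `day`.
#' @param meta Metadata tibble.
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                          show_col_types = FALSE)
  validate_metadata(meta)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  readr::write_csv(validate_metadata(meta), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_metadata
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "patient_id", "site", "timepoint", "day")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("metadata missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) stop_oralhsct("duplicated sample ids in metadata")
  bad_site <- setdiff(unique(meta$site), ORAL_SITES)
  if (length(bad_site) > 0) {
    stop_oralhsct(paste0("unknown oral site(s): ", paste(bad_site, collapse = ", ")))
  }
  bad_tp <- setdiff(unique(meta$timepoint), TIMEPOINTS)
  if (length(bad_tp) > 0) {
    stop_oralhsct(paste0("unknown timepoint(s): ", paste(bad_tp, collapse = ", ")))
  }
  dup <- meta |>
    dplyr::count(.data$patient_id, .data$site, .data$timepoint) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_oralhsct(sprintf("duplicated (patient, site, timepoint): %s/%s/%s",
                          dup$patient_id[1], dup$site[1], dup$timepoint[1]))
  }
  as_tibble(meta) |>
    mutate(timepoint = factor(.data$timepoint, levels = TIMEPOINTS),
           day = as.integer(.data$day))
}

#' Read and write antibiotic-course tables
#'
#' One row per administered course: patient, agent, antibiotic class, and
#' the closed interval of administration days (inclusive endpoints, days
#' relative to stem-cell infusion). `start_day <= end_day` is enforced.
#'
#' @param path CSV file with columns `patient_id`, `agent`, `class`,
#'   `start_day`, `end_day`.
#' @param abx Course tibble.
#' @return A validated course tibble.
#' @export
read_abx <- function(path) {
  validate_abx(readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                               show_col_types = FALSE))
}

#' @rdname read_abx
#' @export
write_abx <- function(abx, path) {
  readr::write_csv(validate_abx(abx), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_abx
#' @export
validate_abx <- function(abx) {
  need <- c("patient_id", "agent", "class", "start_day", "end_day")
  miss <- setdiff(need, names(abx))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("antibiotic table missing columns: ", paste(miss, collapse = ", ")))
  }
  bad <- which(abx$start_day > abx$end_day)
  if (length(bad) > 0) {
    stop_oralhsct(sprintf("antibiotic course for patient '%s' (%s) has start_day > end_day",
                          abx$patient_id[bad[1]], abx$agent[bad[1]]))
  }
  as_tibble(abx) |>
    mutate(start_day = as.integer(.data$start_day), end_day = as.integer(.data$end_day))
}

#' Read and write patient outcome tables
#'
#' One row per patient with follow-up time in days (> 0) and an event code:
#' 0 = censored, 1 = event of interest, 2 = competing event. Any further
#' columns are carried along as covariates.
#'
#' @param path CSV file with columns `patient_id`, `time`, `event`, plus
#'   covariates.
#' @param outcomes Outcome tibble.
#' @return A validated outcome tibble.
#' @export
read_outcomes <- function(path) {
  validate_outcomes(readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                                    show_col_types = FALSE))
}

#' @rdname read_outcomes
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(validate_outcomes(outcomes), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_outcomes
#' @export
validate_outcomes <- function(outcomes) {
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(outcomes))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("outcome table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(outcomes$time <= 0)) {
    stop_oralhsct(sprintf("non-positive follow-up time for patient '%s'",
                          outcomes$patient_id[which(outcomes$time <= 0)[1]]))
  }
  if (!all(outcomes$event %in% c(0, 1, 2))) {
    stop_oralhsct("event codes must be 0 (censored), 1 (event), or 2 (competing)")
  }
  as_tibble(outcomes)
}

#' Read and write rooted phylogenetic trees (newick)
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that check the
#' tree is rooted, has branch lengths, and (optionally) that its leaf set
#' covers the taxa of a count table.
#'
#' @param path Newick file path.
#' @param taxa Optional character vector of taxon ids that must all be tree
#'   leaves; missing taxa raise an error listing them.
#' @param tree An [ape::phylo] tree.
#' @return `read_newick()` returns an `ape::phylo` object.
#' @export
read_newick <- function(path, taxa = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_oralhsct("could not parse newick file (unmatched parentheses?)")
  if (is.null(tree$edge.length)) stop_oralhsct("tree has no branch lengths")
  # basal polytomies (e.g. star trees) are accepted: every parsed phylo has
  # a root node, which is all the UniFrac recursion needs
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, tree$tip.label)
    if (length(miss) > 0) {
      stop_oralhsct(paste0("taxa missing from tree: ", paste(miss, collapse = ", ")))
    }
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Exclude samples below a minimum sequencing depth
#'
#' Samples whose total read count falls below `min_reads` are removed before
#' profiling; the study design uses a 3,000-read cutoff. Samples with total
#' exactly equal to the cutoff are retained (the comparator is `>=`,
#' configurable via `strict`).
#'
#' @param counts A count table.
#' @param min_reads Minimum retained library size (default 3000).
#' @param strict If `TRUE`, retain only totals strictly greater than
#'   `min_reads`.
#' @return A list with `counts` (the retained wide tibble), `excluded`
#'   (tibble of `sample_id`, `total` for dropped samples), and `min_reads`.
#' @export
filter_min_depth <- function(counts, min_reads = 3000, strict = FALSE) {
  m <- count_matrix(counts)
  totals <- rowSums(m)
  keep <- if (strict) totals > min_reads else totals >= min_reads
  excluded <- tibble(sample_id = rownames(m)[!keep],
                     total = unname(totals[!keep]))
  list(counts = count_tibble(m[keep, , drop = FALSE]),
       excluded = excluded,
       min_reads = min_reads)
}

#' Referential-integrity report for a cohort's files
#'
#' Checks the cross-file links the pipeline relies on: every sample in the
#' count table has a metadata row (and vice versa), every taxon is a tree
#' leaf, and every antibiotic-course / outcome patient appears in the
#' metadata. Any break raises an error naming the offending ids.
#'
#' @param counts Count table.
#' @param meta Sample metadata.
#' @param tree Optional phylogenetic tree.
#' @param abx Optional antibiotic-course table.
#' @param outcomes Optional outcome table.
#' @return Invisibly `TRUE` when all checks pass.
#' @export
validate_cohort <- function(counts, meta, tree = NULL, abx = NULL, outcomes = NULL) {
  m <- count_matrix(counts)
  meta <- validate_metadata(meta)
  no_meta <- setdiff(rownames(m), meta$sample_id)
  if (length(no_meta) > 0) {
    stop_oralhsct(paste0("samples without metadata: ", paste(no_meta, collapse = ", ")))
  }
  no_counts <- setdiff(meta$sample_id, rownames(m))
  if (length(no_counts) > 0) {
    stop_oralhsct(paste0("metadata samples without counts: ", paste(no_counts, collapse = ", ")))
  }
  if (!is.null(tree)) {
    miss <- setdiff(colnames(m), tree$tip.label)
    if (length(miss) > 0) {
      stop_oralhsct(paste0("taxa missing from tree: ", paste(miss, collapse = ", ")))
    }
  }
  for (tblname in c("abx", "outcomes")) {
    tbl <- get(tblname)
    if (!is.null(tbl)) {
      unk <- setdiff(unique(tbl$patient_id), unique(meta$patient_id))
      if (length(unk) > 0) {
        stop_oralhsct(paste0(tblname, " references unknown patients: ",
                             paste(unk, collapse = ", ")))
      }
    }
  }
  invisible(TRUE)
}
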