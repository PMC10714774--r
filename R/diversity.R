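#' Scaling with ranked subsampling (SRS) normalization
#'
#' Normalizes a vector of read counts to a fixed total `c_min` without the
#' sampling noise of rarefaction. Each count is scaled by `c_min / total`;
#' integer parts are kept, and the remaining `c_min - sum(integer parts)`
#' units are distributed one each to the taxa ranked by descending
#' fractional part. Fractional-part ties are broken by descending scaled
#' value, remaining ties by a seeded random draw, so the procedure is fully
#' reproducible.
#'
#' @param x Non-negative integer count vector (one sample).
#' @param c_min Target depth; must not exceed `sum(x)`.
#' @param tie_seed Integer seed for the randomized tie-break.
#' @return An integer vector of the same length summing exactly to `c_min`.
#' @examples
#' srs_row(c(7, 3, 2), c_min = 6)  # -> 4 1 1
#' @export
srs_row <- function(x, c_min, tie_seed = 1L) {
  total <- sum(x)
  if (total < c_min) {
    stop_oralhsct(sprintf("sample total (%d) below target depth c_min (%d)", total, c_min))
  }
  scaled <- x * c_min / total
  base <- floor(scaled)
  frac <- scaled - base
  r <- as.integer(round(c_min - sum(base)))
  if (r > 0) {
    jitter <- local_seeded(tie_seed, runif(length(x)))
    ord <- order(-frac, -scaled, jitter)
    take <- ord[seq_len(r)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(x)
  out
}

#' SRS-normalize a whole count table
#'
#' Applies [srs_row()] to every sample. `c_min` defaults to the minimum
#' library size of the input (the depth-normalization rule used after the
#' low-depth exclusion filter); samples with totals below `c_min` are
#' flagged and omitted from the normalized table rather than silently
#' dropped.
#'
#' @param counts A count table (see [count_matrix()]).
#' @param c_min Target depth; default `NULL` uses the minimum library size.
#' @param tie_seed Integer seed for tie-breaking, shared across samples.
#' @return A list with `counts` (normalized wide tibble, every row summing
#'   to `c_min`), `flagged` (tibble of samples below `c_min`), and `c_min`.
#' @export
srs_normalize <- function(counts, c_min = NULL, tie_seed = 1L) {
  m <- count_matrix(counts)
  totals <- rowSums(m)
  if (is.null(c_min)) c_min <- min(totals)
  if (c_min < 1) stop_oralhsct("c_min must be >= 1")
  ok <- totals >= c_min
  flagged <- tibble(sample_id = rownames(m)[!ok], total = unname(totals[!ok]))
  norm <- t(apply(m[ok, , drop = FALSE], 1, srs_row, c_min = c_min, tie_seed = tie_seed))
  colnames(norm) <- colnames(m)
  list(counts = count_tibble(norm), flagged = flagged, c_min = c_min)
}

#' Gini-Simpson diversity index
#'
#' `1 - sum(p_i^2)`: the probability that two reads drawn at random belong
#' to different taxa. Bounded by `1 - 1/S` for `S` observed taxa; invariant
#' to appending zero-count taxa and to rescaling all counts by a common
#' factor.
#'
#' @param x Non-negative count (or relative abundance) vector with a
#'   positive total.
#' @return A number in `[0, 1)`.
#' @examples
#' gini_simpson(c(1, 1, 1, 1))  # 0.75
#' @export
gini_simpson <- function(x) {
  total <- sum(x)
  if (total <= 0) stop_oralhsct("Gini-Simpson undefined for an all-zero sample")
  p <- x / total
  1 - sum(p^2)
}

#' Per-sample diversity table
#'
#' SRS-normalizes the count table (unless `normalize = FALSE`) and computes
#' the Gini-Simpson index for every sample, joining sample metadata when
#' provided so the result is ready for trajectory and stability analyses.
#'
#' @inheritParams srs_normalize
#' @param meta Optional sample metadata (see [read_metadata()]).
#' @param normalize Apply SRS before computing diversity (default `TRUE`).
#' @return A tibble with `sample_id`, `diversity`, plus metadata columns.
#' @export
sample_diversity <- function(counts, meta = NULL, c_min = NULL, tie_seed = 1L,
                             normalize = TRUE) {
  m <- if (normalize) count_matrix(srs_normalize(counts, c_min, tie_seed)$counts)
       else count_matrix(counts)
  out <- tibble(sample_id = rownames(m),
                diversity = apply(m, 1, gini_simpson))
  if (!is.null(meta)) out <- left_join(out, validate_metadata(meta), by = "sample_id")
  out
}

#' Diversity resistance, resilience, and stability per patient and site
#'
#' Summarises each patient-site diversity trajectory around the engraftment
#' perturbation:
#' \describe{
#'   \item{resistance}{`D_E / D_P` — fraction of baseline (preconditioning)
#'     diversity retained at engraftment; 1 means no loss.}
#'   \item{resilience}{`(D_E30 - D_E) / (day_E30 - day_E)` — per-day rate of
#'     diversity gain after engraftment; negative when diversity keeps
#'     falling.}
#'   \item{stability}{`D_E30 / D_P` — fraction of baseline diversity
#'     retained 30 days after engraftment, the combined effect of
#'     resistance and resilience.}
#' }
#' Resistance needs P and E samples; resilience and stability additionally
#' need E30. `evaluable` is `FALSE` when any required timepoint is missing
#' or baseline diversity is zero; partially computable indices are still
#' reported.
#'
#' @param div A diversity table from [sample_diversity()] with `patient_id`,
#'   `site`, `timepoint`, `day`, `diversity` columns.
#' @return A tibble with one row per patient-site: `patient_id`, `site`,
#'   `resistance`, `resilience`, `stability`, `evaluable`.
#' @export
stability_indices <- function(div) {
  need <- c("patient_id", "site", "timepoint", "day", "diversity")
  miss <- setdiff(need, names(div))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("diversity table missing columns: ", paste(miss, collapse = ", ")))
  }
  one <- function(d) {
    g <- function(tp) {
      i <- which(d$timepoint == tp)
      if (length(i) == 0) NULL else list(div = d$diversity[i[1]], day = d$day[i[1]])
    }
    P <- g("P"); E <- g("E"); E30 <- g("E30")
    resistance <- resilience <- stability <- NA_real_
    if (!is.null(P) && !is.null(E) && P$div > 0) resistance <- E$div / P$div
    if (!is.null(E) && !is.null(E30)) resilience <- (E30$div - E$div) / (E30$day - E$day)
    if (!is.null(P) && !is.null(E30) && P$div > 0) stability <- E30$div / P$div
    evaluable <- !is.null(P) && !is.null(E) && !is.null(E30) && P$div > 0
    tibble(resistance = resistance, resilience = resilience,
           stability = stability, evaluable = evaluable)
  }
  div |>
    group_by(.data$patient_id, .data$site) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Plot diversity trajectories per oral site
#'
#' Gini-Simpson diversity against timepoint, one panel per oral site, one
#' light line per patient with the cohort median overlaid.
#'
#' @param div A diversity table from [sample_diversity()] including
#'   metadata columns.
#' @return A ggplot object.
#' @export
plot_diversity_trajectories <- function(div) {
  med <- div |>
    group_by(.data$site, .data$timepoint) |>
    summarise(diversity = median(.data$diversity), .groups = "drop")
  ggplot2::ggplot(div, ggplot2::aes(x = .data$timepoint, y = .data$diversity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id), alpha = 0.25) +
    ggplot2::geom_line(data = med, ggplot2::aes(group = 1), linewidth = 1.2,
                       colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "timepoint", y = "Gini-Simpson diversity") +
    ggplot2::theme_minimal()
}
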