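#' @noRd
# Edge decomposition of a rooted tree: for every edge, the set of tips
# descending from it, plus root-to-tip path lengths. Everything UniFrac
# needs, computed once per tree.
tree_edge_profile <- function(tree) {
  if (is.null(tree$edge.length)) stop_oralhsct("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  # incidence[tip, edge] = 1 if the tip descends from the edge's child node
  incidence <- matrix(0, nrow = n_tip, ncol = nrow(po$edge),
                      dimnames = list(tree$tip.label, NULL))
  below <- vector("list", max(po$edge))  # tips below each node
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    tips <- below[[child]]
    incidence[tips, e] <- 1
    below[[parent]] <- c(below[[parent]], tips)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  names(depths) <- tree$tip.label
  list(edge_length = po$edge.length, incidence = incidence, tip_depth = depths)
}

match_abundance <- function(p, tree) {
  tips <- tree$tip.label
  if (!is.null(names(p))) {
    miss <- setdiff(names(p), tips)
    if (length(miss) > 0) {
      stop_oralhsct(paste0("taxa missing from tree: ", paste(miss, collapse = ", ")))
    }
    full <- setNames(numeric(length(tips)), tips)
    full[names(p)] <- p
    full
  } else {
    if (length(p) != length(tips)) {
      stop_oralhsct("unnamed abundance vector must have one entry per tree leaf")
    }
    setNames(as.numeric(p), tips)
  }
}

#' Weighted UniFrac distance between two communities
#'
#' Tree-aware dissimilarity between two relative-abundance vectors. The raw
#' form is `sum_b l_b * |P_b - Q_b|` over all branches `b`, where `P_b` is
#' the fraction of community `p` descending from branch `b` and `l_b` the
#' branch length. The normalized form (default) divides by
#' `sum_leaf depth_leaf * (p_leaf + q_leaf)` — the maximum attainable raw
#' distance — and is bounded in `[0, 1]`, the scale on which the 0.5
#' recovery threshold is defined.
#'
#' @param p,q Relative-abundance vectors summing to 1, named by taxon
#'   (tree leaves) or given in tree leaf order.
#' @param tree A rooted [ape::phylo] tree with branch lengths whose leaves
#'   name the taxa.
#' @param normalized Return the bounded normalized form (default `TRUE`).
#' @return A single non-negative number.
#' @export
weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  prof <- tree_edge_profile(tree)
  p <- match_abundance(p, tree)
  q <- match_abundance(q, tree)
  pb <- as.numeric(p %*% prof$incidence)
  qb <- as.numeric(q %*% prof$incidence)
  w <- sum(prof$edge_length * abs(pb - qb))
  if (!normalized) return(w)
  denom <- sum(prof$tip_depth * (p + q))
  if (denom == 0) return(0)
  w / denom
}

#' Weighted UniFrac distance matrix for a count table
#'
#' Converts each sample to relative abundances (from the raw counts — depth
#' normalization is applied only for alpha diversity) and computes all
#' pairwise weighted UniFrac distances through a vectorized edge-mass
#' formulation: samples are projected onto branch masses once, after which
#' the raw distance is a branch-length-weighted Manhattan distance.
#'
#' @param counts A count table (see [count_matrix()]); rows are converted
#'   to relative abundances.
#' @param tree A rooted [ape::phylo] tree covering all taxa.
#' @param normalized Return the bounded normalized form (default `TRUE`).
#' @return A symmetric, zero-diagonal distance matrix with sample dimnames.
#' @export
unifrac_matrix <- function(counts, tree, normalized = TRUE) {
  m <- count_matrix(counts, integer = FALSE)
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss) > 0) {
    stop_oralhsct(paste0("taxa missing from tree: ", paste(miss, collapse = ", ")))
  }
  totals <- rowSums(m)
  if (any(totals == 0)) stop_oralhsct("all-zero sample in count table")
  ra <- m / totals
  prof <- tree_edge_profile(tree)
  full <- matrix(0, nrow = nrow(ra), ncol = length(tree$tip.label),
                 dimnames = list(rownames(ra), tree$tip.label))
  full[, colnames(ra)] <- ra
  branch_mass <- full %*% prof$incidence
  scaled <- sweep(branch_mass, 2, prof$edge_length, `*`)
  d <- as.matrix(stats::dist(scaled, method = "manhattan"))
  if (normalized) {
    a <- as.numeric(full %*% prof$tip_depth)
    denom <- outer(a, a, `+`)
    denom[denom == 0] <- 1
    d <- d / denom
    diag(d) <- 0
  }
  d
}

# Accept a dist or a square symmetric matrix; return the validated full
# matrix with sample dimnames.
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_oralhsct("distance matrix must be square")
  if (is.null(rownames(d))) stop_oralhsct("distance matrix must have sample dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop_oralhsct("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop_oralhsct("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop_oralhsct("distance matrix must be non-negative")
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering followed by eigendecomposition
#' (via [stats::cmdscale()]). Only axes with positive eigenvalues are
#' retained; negative eigenvalues (non-Euclidean distances) are reported but
#' their axes dropped. When the input is Euclidean-embeddable, pairwise
#' Euclidean distances across all retained axes reproduce the input exactly.
#'
#' @param d A distance matrix (square symmetric matrix or `dist`).
#' @return An object of class `oralhsct_pcoa`: list with `points` (tibble of
#'   `sample_id` and `Axis1..k` coordinates), `eig` (all eigenvalues,
#'   decreasing), and `prop_explained` (positive eigenvalues over their sum).
#' @export
pcoa_ord <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop_oralhsct("PCoA needs at least 3 samples")
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig), .Machine$double.eps) * 1e-8
  pos <- which(eig > tol)
  pos <- pos[pos <= ncol(sc$points)]
  pts <- sc$points[, pos, drop = FALSE]
  colnames(pts) <- if (length(pos)) paste0("Axis", seq_along(pos)) else character(0)
  structure(list(
    points = bind_cols(tibble(sample_id = rownames(d)), as_tibble(pts)),
    eig = eig,
    prop_explained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0)
  ), class = "oralhsct_pcoa")
}

#' @export
print.oralhsct_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (first two explain %.1f%% / %.1f%%)\n",
              nrow(x$points), length(x$prop_explained),
              100 * (x$prop_explained[1] %||% 0), 100 * (x$prop_explained[2] %||% 0)))
  invisible(x)
}

#' @export
autoplot.oralhsct_pcoa <- function(object, meta = NULL, colour = "timepoint", ...) {
  pts <- object$points
  if (!is.null(meta)) pts <- left_join(pts, meta, by = "sample_id")
  pe <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * (object$prop_explained[i] %||% 0))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(x = pe(1), y = pe(2)) +
    ggplot2::theme_minimal()
  if (!is.null(meta) && colour %in% names(pts)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_point()
  }
}

# SS decomposition used by PERMANOVA: total and within-group sums of
# squared distances, each divided by the relevant group size.
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  k <- length(unique(groups))
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor pseudo-F on a distance matrix:
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))` with
#' `SS_total = (1/n) * sum_{i<j} d_ij^2` and within-group sums computed
#' analogously per group. The p-value is the add-one permutation estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under seeded label
#' shuffling.
#'
#' @param d Distance matrix (square symmetric matrix or `dist`).
#' @param groups Group labels, one per sample (in `d` order).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `oralhsct_permanova` with fields `f`, `p`,
#'   `n_perm`, `seed`, `df` and `singleton_groups` (flag: some group has a
#'   single member).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as_distance_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop_oralhsct("one group label per sample required")
  k <- length(unique(groups))
  if (k < 2) stop_oralhsct("PERMANOVA needs at least 2 groups")
  singleton <- any(table(groups) < 2)
  if (singleton) warn("some group has a single member; pseudo-F may be unstable")
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  n_ge <- local_seeded(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, sample(groups)) >= f_obs
    }, logical(1)))
  })
  structure(list(f = f_obs, p = (1 + n_ge) / (1 + n_perm),
                 n_perm = n_perm, seed = as.integer(seed),
                 df = c(between = k - 1, within = nrow(d) - k),
                 singleton_groups = singleton),
            class = "oralhsct_permanova")
}

#' @export
print.oralhsct_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$f, x$df[1], x$df[2], x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.oralhsct_permanova <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, df.between = x$df[[1]],
         df.within = x$df[[2]], n.permutations = x$n_perm)
}

#' Distance from a sample to a group centroid (Gower identity)
#'
#' Squared distance to the implicit centroid of a group computed directly
#' from the distance matrix, with no embedding:
#' `d^2(x, c_G) = mean_g d^2(x, g) - (1 / (2|G|^2)) * sum_{g,g'} d^2(g, g')`.
#' A negative value (possible for non-Euclidean input) is clipped to zero
#' with a warning. Returns the square root.
#'
#' @param d Distance matrix.
#' @param group Character vector of sample ids forming the group.
#' @param x A single sample id.
#' @return A non-negative number.
#' @export
dist_to_group_centroid <- function(d, group, x) {
  d <- as_distance_matrix(d)
  if (length(group) == 0) stop_oralhsct("centroid group must be non-empty")
  miss <- setdiff(c(group, x), rownames(d))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("samples missing from distance matrix: ", paste(miss, collapse = ", ")))
  }
  d2 <- d^2
  v <- mean(d2[x, group]) - sum(d2[group, group]) / (2 * length(group)^2)
  if (v < 0) {
    if (v < -1e-10) warn("negative squared centroid distance clipped to 0 (non-Euclidean input)")
    v <- 0
  }
  sqrt(v)
}

#' Per-sample distances to timepoint centroids
#'
#' For every sample, the distance to the centroid of a reference group of
#' samples from the same oral site: either the preconditioning (P) samples
#' (`reference = "P"`, displacement from baseline) or the sample's own
#' timepoint (`reference = "own"`, inter-patient dispersion). The sample
#' itself is excluded from its own centroid group.
#'
#' @param d Distance matrix over samples.
#' @param meta Sample metadata.
#' @param reference `"P"` or `"own"`.
#' @return A tibble with `sample_id`, `patient_id`, `site`, `timepoint`,
#'   `dist_to_centroid`.
#' @export
centroid_distances <- function(d, meta, reference = c("P", "own")) {
  reference <- match.arg(reference)
  d <- as_distance_matrix(d)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(d))
  purrr::pmap_dfr(meta[c("sample_id", "patient_id", "site", "timepoint")],
    function(sample_id, patient_id, site, timepoint) {
      ref_tp <- if (reference == "P") "P" else as.character(timepoint)
      grp <- meta$sample_id[meta$site == site & meta$timepoint == ref_tp]
      grp <- setdiff(grp, sample_id)
      tibble(sample_id = sample_id, patient_id = patient_id, site = site,
             timepoint = timepoint,
             dist_to_centroid = if (length(grp) == 0) NA_real_
                                else dist_to_group_centroid(d, grp, sample_id))
    })
}

#' All within-group pairwise distances
#'
#' The `|G|(|G|-1)/2` distances among the members of a group — the
#' all-against-all dispersion summary computed per timepoint and site.
#'
#' @param d Distance matrix.
#' @param group Character vector of sample ids.
#' @return A tibble with `sample_a`, `sample_b`, `distance`.
#' @export
pairwise_dispersion <- function(d, group) {
  d <- as_distance_matrix(d)
  miss <- setdiff(group, rownames(d))
  if (length(miss) > 0) {
    stop_oralhsct(paste0("samples missing from distance matrix: ", paste(miss, collapse = ", ")))
  }
  if (length(group) < 2) return(tibble(sample_a = character(), sample_b = character(),
                                       distance = numeric()))
  pairs <- utils::combn(group, 2)
  tibble(sample_a = pairs[1, ], sample_b = pairs[2, ],
         distance = d[cbind(pairs[1, ], pairs[2, ])])
}

#' Minimum between-site distance per patient and timepoint
#'
#' For each patient-timepoint with at least two sampled oral sites, the
#' minimum weighted UniFrac distance over all available site pairs — a
#' measure of how compositionally distinct a patient's oral sites remain.
#'
#' @param d Distance matrix.
#' @param meta Sample metadata.
#' @return A tibble with `patient_id`, `timepoint`, `n_sites`,
#'   `min_distance` (`NA` when fewer than 2 sites), `evaluable`.
#' @export
min_between_site_distances <- function(d, meta) {
  d <- as_distance_matrix(d)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(d))
  meta |>
    group_by(.data$patient_id, .data$timepoint) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) {
        return(tibble(n_sites = nrow(g), min_distance = NA_real_, evaluable = FALSE))
      }
      pairs <- utils::combn(g$sample_id, 2)
      tibble(n_sites = nrow(g),
             min_distance = min(d[cbind(pairs[1, ], pairs[2, ])]),
             evaluable = TRUE)
    }) |>
    ungroup()
}

#' Day-adjusted compositional shift rates between consecutive timepoints
#'
#' For each patient-site and each pair of canonically consecutive
#' timepoints with both samples present, the distance between the two
#' samples divided by the days elapsed. Intervals with a missing endpoint
#' are skipped, never bridged across the gap.
#'
#' @param d Distance matrix.
#' @param meta Sample metadata.
#' @return A tibble with `patient_id`, `site`, `interval` (e.g. `"A-E"`),
#'   `distance`, `days`, `rate` (distance per day).
#' @export
consecutive_shift_rates <- function(d, meta) {
  d <- as_distance_matrix(d)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(d))
  meta |>
    group_by(.data$patient_id, .data$site) |>
    dplyr::group_modify(function(g, key) {
      out <- list()
      for (i in seq_len(length(TIMEPOINTS) - 1)) {
        a <- g[g$timepoint == TIMEPOINTS[i], ]
        b <- g[g$timepoint == TIMEPOINTS[i + 1], ]
        if (nrow(a) == 1 && nrow(b) == 1) {
          days <- b$day - a$day
          if (days == 0) stop_oralhsct("zero-day gap between consecutive timepoints")
          out[[length(out) + 1]] <- tibble(
            interval = paste(TIMEPOINTS[i], TIMEPOINTS[i + 1], sep = "-"),
            distance = d[a$sample_id, b$sample_id],
            days = as.numeric(days),
            rate = d[a$sample_id, b$sample_id] / days)
        }
      }
      bind_rows(out)
    }) |>
    ungroup()
}

#' Compositional stability per patient and site
#'
#' One minus the distance between a patient's preconditioning (P) and E30
#' samples at a site: 1 when the composition returned exactly to baseline,
#' 0 at the maximum of the (normalized, bounded) distance scale. Patients
#' missing either sample are unevaluable.
#'
#' @param d Distance matrix.
#' @param meta Sample metadata.
#' @return A tibble with `patient_id`, `site`, `stability`, `evaluable`.
#' @export
compositional_stability <- function(d, meta) {
  d <- as_distance_matrix(d)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(d))
  meta |>
    group_by(.data$patient_id, .data$site) |>
    dplyr::group_modify(function(g, key) {
      a <- g$sample_id[g$timepoint == "P"]
      b <- g$sample_id[g$timepoint == "E30"]
      if (length(a) == 1 && length(b) == 1) {
        tibble(stability = 1 - d[a, b], evaluable = TRUE)
      } else {
        tibble(stability = NA_real_, evaluable = FALSE)
      }
    }) |>
    ungroup()
}
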