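# Independent oracles and small fixture builders shared across tests.

# Brute-force weighted UniFrac: enumerate every edge's descendant tip set
# with phangorn, sum branch-length-weighted abundance differences directly.
# Kept deliberately independent of the package's edge-mass implementation.
brute_unifrac <- function(p, q, tree, normalized = TRUE) {
  tips <- tree$tip.label
  pv <- setNames(numeric(length(tips)), tips)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  w <- 0
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    desc <- if (node <= length(tips)) node else
      unlist(phangorn::Descendants(tree, node, type = "tips"))
    w <- w + tree$edge.length[e] * abs(sum(pv[desc]) - sum(qv[desc]))
  }
  if (!normalized) return(w)
  root <- length(tips) + 1
  depth <- ape::dist.nodes(tree)[root, seq_along(tips)]
  w / sum(depth * (pv + qv))
}

# Exhaustive bloom scan: per (patient, site, taxon), find runs of dominant
# post-P timepoints by direct iteration over the canonical timepoint order.
brute_bloom_scan <- function(ra, meta, baseline_max = 0.01, dominance_min = 0.30) {
  out <- list()
  for (pat in unique(meta$patient_id)) {
    for (s in unique(meta$site[meta$patient_id == pat])) {
      sub <- meta[meta$patient_id == pat & meta$site == s, ]
      p_id <- sub$sample_id[sub$timepoint == "P"]
      if (length(p_id) != 1) next
      post_tps <- intersect(oral_timepoints()[-1], as.character(sub$timepoint))
      for (tx in colnames(ra)) {
        if (ra[p_id, tx] >= baseline_max) next
        dom <- vapply(post_tps, function(tp) {
          sid <- sub$sample_id[sub$timepoint == tp]
          ra[sid, tx] >= dominance_min
        }, logical(1))
        i <- 1
        while (i <= length(dom)) {
          if (dom[i]) {
            j <- i
            while (j < length(dom) && dom[j + 1]) j <- j + 1
            out[[length(out) + 1]] <- data.frame(
              patient_id = pat, site = s, taxon = tx, onset = post_tps[i],
              run_length = j - i + 1)
            i <- j + 1
          } else i <- i + 1
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), site = character(), taxon = character(),
               onset = character(), run_length = integer())
}

# Random relative-abundance vector over a tree's tips.
random_composition <- function(tree) {
  x <- rgamma(length(tree$tip.label), 0.5)
  setNames(x / sum(x), tree$tip.label)
}

# Distance matrix of 1-D points (ordinary Euclidean distances).
line_dist <- function(x, ids = paste0("s", seq_along(x))) {
  d <- as.matrix(stats::dist(matrix(x, ncol = 1)))
  dimnames(d) <- list(ids, ids)
  d
}

# Minimal metadata tibble builder.
make_meta <- function(patient_id, site, timepoint, day) {
  tibble::tibble(
    sample_id = paste(patient_id, site, timepoint, sep = "_"),
    patient_id = patient_id, site = site, timepoint = timepoint, day = day)
}
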