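#' Relative abundances from a count table
#'
#' @param counts A count table (see [count_matrix()]).
#' @return A wide tibble of per-sample relative abundances.
#' @export
relative_abundance <- function(counts) {
  m <- count_matrix(counts)
  totals <- rowSums(m)
  if (any(totals == 0)) stop_oralhsct("all-zero sample in count table")
  count_tibble(m / totals, integer = FALSE)
}

#' Detect blooms of opportunistic taxa
#'
#' A bloom is a taxon whose relative abundance rises from below
#' `baseline_max` (strictly; default 1%) at the preconditioning (P) sample
#' to dominance (`>= dominance_min`; default 30%) at one or more subsequent
#' timepoints of the same patient-site. Each maximal run of consecutive
#' sampled dominant timepoints is reported as one event, with onset at the
#' run's first timepoint (`per_timepoint = TRUE` instead reports every
#' dominant timepoint as its own event). Patient-sites without a P sample
#' are unevaluable and listed in the `skipped` attribute.
#'
#' @param counts Count table (converted to relative abundances internally),
#'   or an already-relative table if `is_relative = TRUE`.
#' @param meta Sample metadata.
#' @param baseline_max Strict upper bound on baseline relative abundance
#'   (default 0.01).
#' @param dominance_min Inclusive dominance threshold (default 0.30).
#' @param per_timepoint Count each dominant timepoint as a separate event.
#' @param is_relative Set when `counts` already holds relative abundances.
#' @return A tibble of bloom events: `patient_id`, `site`, `taxon`,
#'   `onset` (first timepoint of the run), `peak_ra`, `run_length`,
#'   `baseline_ra`; attribute `skipped` lists unevaluable patient-sites.
#' @export
detect_blooms <- function(counts, meta, baseline_max = 0.01, dominance_min = 0.30,
                          per_timepoint = FALSE, is_relative = FALSE) {
  ra <- if (is_relative) count_matrix(counts, integer = FALSE)
        else count_matrix(relative_abundance(counts), integer = FALSE)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(ra))
  events <- list(); skipped <- list()
  for (pat in unique(meta$patient_id)) {
    for (s in unique(meta$site[meta$patient_id == pat])) {
      sub <- meta |>
        filter(.data$patient_id == pat, .data$site == s) |>
        arrange(.data$timepoint)
      p_sample <- sub$sample_id[sub$timepoint == "P"]
      if (length(p_sample) == 0) {
        skipped[[length(skipped) + 1]] <- tibble(patient_id = pat, site = s,
                                                 reason = "missing P sample")
        next
      }
      post <- sub |> filter(.data$timepoint != "P")
      if (nrow(post) == 0) next
      base_ra <- ra[p_sample, ]
      cand <- which(base_ra < baseline_max)
      for (tx in cand) {
        dom <- ra[post$sample_id, tx] >= dominance_min
        if (!any(dom)) next
        runs <- rle(dom)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        for (ri in which(runs$values)) {
          idx <- starts[ri]:ends[ri]
          if (per_timepoint) {
            for (j in idx) {
              events[[length(events) + 1]] <- tibble(
                patient_id = pat, site = s, taxon = colnames(ra)[tx],
                onset = as.character(post$timepoint[j]),
                peak_ra = unname(ra[post$sample_id[j], tx]),
                run_length = 1L, baseline_ra = unname(base_ra[tx]))
            }
          } else {
            events[[length(events) + 1]] <- tibble(
              patient_id = pat, site = s, taxon = colnames(ra)[tx],
              onset = as.character(post$timepoint[idx[1]]),
              peak_ra = max(ra[post$sample_id[idx], tx]),
              run_length = length(idx), baseline_ra = unname(base_ra[tx]))
          }
        }
      }
    }
  }
  out <- if (length(events)) bind_rows(events) else
    tibble(patient_id = character(), site = character(), taxon = character(),
           onset = character(), peak_ra = numeric(), run_length = integer(),
           baseline_ra = numeric())
  attr(out, "skipped") <- if (length(skipped)) bind_rows(skipped) else
    tibble(patient_id = character(), site = character(), reason = character())
  out
}

# Days covered by a course clipped to [window[1], window[2]] (closed
# intervals on both sides); empty when disjoint.
course_days <- function(start_day, end_day, window) {
  lo <- max(start_day, window[1])
  hi <- min(end_day, window[2])
  if (lo > hi) integer(0) else lo:hi
}

#' Antibiotic-exposure metrics (LOT, DOT, class usage) per patient
#'
#' Clips each course to the analysis window (default preconditioning to 30
#' days after engraftment, closed on both ends), drops prophylactic agents
#' on the deny-list, and computes per patient:
#' \describe{
#'   \item{LOT}{length of therapy — number of distinct calendar days covered
#'     by at least one course.}
#'   \item{DOT}{days of therapy — agent-days, summed over agents, so days
#'     with several concurrent agents count once per agent.}
#' }
#' Per-class usage flags mark any use of the class inside the window.
#' `LOT <= DOT` always, with equality when no day carries two agents.
#'
#' @param abx Antibiotic-course table (see [read_abx()]).
#' @param window Integer pair `(start_day, end_day)` of the analysis window.
#'   May also be a tibble with `patient_id`, `start_day`, `end_day` for
#'   per-patient windows (e.g. each patient's own E30 day).
#' @param deny_agents Prophylactic agents excluded from all metrics
#'   (default oral levofloxacin and sulfamethoxazole-trimethoprim).
#' @param patients Optional patient universe; patients with no (retained)
#'   courses are reported with zero exposure.
#' @return A tibble with `patient_id`, `lot`, `dot`, `n_agents`,
#'   `n_classes`, plus one logical `class_<name>` column per class observed
#'   in the window.
#' @export
compute_exposure <- function(abx, window = c(-10L, 44L),
                             deny_agents = c("levofloxacin", "sulfamethoxazole-trimethoprim"),
                             patients = NULL) {
  abx <- validate_abx(abx) |> filter(!(.data$agent %in% deny_agents))
  if (is.null(patients)) patients <- unique(abx$patient_id)
  per_patient_window <- is.data.frame(window)
  classes <- sort(unique(abx$class))
  rows <- purrr::map_dfr(patients, function(pat) {
    win <- if (per_patient_window) {
      w <- window |> filter(.data$patient_id == pat)
      if (nrow(w) == 0) return(NULL)
      c(w$start_day[1], w$end_day[1])
    } else window
    pc <- abx |> filter(.data$patient_id == pat)
    day_sets <- purrr::pmap(pc[c("start_day", "end_day")],
                            function(start_day, end_day) course_days(start_day, end_day, win))
    covered <- lengths(day_sets) > 0
    pc <- pc[covered, ]; day_sets <- day_sets[covered]
    agent_days <- tibble(agent = pc$agent, class = pc$class) |>
      mutate(days = day_sets) |>
      tidyr::unnest("days") |>
      distinct(.data$agent, .data$class, .data$days)
    lot <- dplyr::n_distinct(agent_days$days)
    dot <- nrow(agent_days)
    flags <- setNames(as.list(classes %in% unique(pc$class)), paste0("class_", classes))
    bind_cols(tibble(patient_id = pat, lot = lot, dot = dot,
                     n_agents = dplyr::n_distinct(pc$agent),
                     n_classes = dplyr::n_distinct(pc$class)),
              as_tibble(flags))
  })
  rows
}

#' Retain antibiotic classes used by a minimum fraction of patients
#'
#' Association tests over antibiotic classes only consider classes received
#' by at least `min_frac` of the patients (default 20%); the threshold count
#' is `ceiling(min_frac * n)`.
#'
#' @param exposure Output of [compute_exposure()].
#' @param min_frac Minimum fraction of patients (default 0.20).
#' @return Character vector of retained class names.
#' @export
class_prevalence_filter <- function(exposure, min_frac = 0.20) {
  flag_cols <- grep("^class_", names(exposure), value = TRUE)
  n <- nrow(exposure)
  need <- ceiling(min_frac * n)
  used <- vapply(exposure[flag_cols], sum, numeric(1))
  sub("^class_", "", flag_cols[used >= need])
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided exact test on a 2x2 contingency table. The reported odds ratio
#' is the conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model (not the sample cross-product ratio); a zero cell
#' yields an infinite (or zero) estimate, and a zero margin leaves the odds
#' ratio undefined with p = 1.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A tibble with `odds_ratio`, `p.value`, `conf.low`, `conf.high`.
#' @export
fisher_exact_or <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != floor(table))) {
    stop_oralhsct("2x2 table must hold non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(odds_ratio = NA_real_, p.value = 1,
                  conf.low = NA_real_, conf.high = NA_real_))
  }
  ft <- stats::fisher.test(table)
  tibble(odds_ratio = unname(ft$estimate), p.value = ft$p.value,
         conf.low = ft$conf.int[1], conf.high = ft$conf.int[2])
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value for small samples without ties, normal
#' approximation with tie correction otherwise (the [stats::wilcox.test()]
#' switching rule). The reported `u` is the U statistic for the first group.
#'
#' @param a,b Numeric vectors.
#' @return A tibble with `u` and `p.value`.
#' @export
mannwhitney <- function(a, b) {
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  tibble(u = unname(wt$statistic), p.value = wt$p.value)
}

#' Chi-square test of equal bloom prevalence across sites
#'
#' Pearson chi-square (without continuity correction) on a 2xk table of
#' patients showing / not showing blooms per oral site.
#'
#' @param affected Integer vector: patients with blooms per site.
#' @param total Integer vector: evaluable patients per site.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
chisq_prevalence <- function(affected, total) {
  stopifnot(length(affected) == length(total), all(affected <= total))
  tab <- rbind(affected, total - affected)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value)
}

#' Associate bloom occurrence with antibiotic-class usage
#'
#' For each retained antibiotic class (see [class_prevalence_filter()]) and
#' each oral site, tests whether patients who used the class bloomed more
#' often at that site (Fisher's exact test on the 2x2 usage-by-bloom
#' table), with Bonferroni adjustment over the retained classes within each
#' site. Blooms with onset at E75 are excluded, matching the exposure
#' window ending at E30.
#'
#' @param blooms Bloom events from [detect_blooms()].
#' @param exposure Exposure table from [compute_exposure()].
#' @param min_frac Class-prevalence threshold (default 0.20).
#' @param exclude_onsets Bloom onsets outside the exposure window
#'   (default `"E75"`).
#' @return A tibble with one row per site-class: counts, `odds_ratio`,
#'   `p.value`, `p.adjusted`.
#' @export
bloom_abx_association <- function(blooms, exposure, min_frac = 0.20,
                                  exclude_onsets = "E75") {
  classes <- class_prevalence_filter(exposure, min_frac)
  blooms <- blooms |> filter(!(.data$onset %in% exclude_onsets))
  purrr::map_dfr(unique(blooms$site), function(s) {
    bloomers <- unique(blooms$patient_id[blooms$site == s])
    purrr::map_dfr(classes, function(cl) {
      used <- exposure[[paste0("class_", cl)]]
      bloomed <- exposure$patient_id %in% bloomers
      tab <- matrix(c(sum(used & bloomed), sum(!used & bloomed),
                      sum(used & !bloomed), sum(!used & !bloomed)),
                    nrow = 2, byrow = TRUE)
      res <- fisher_exact_or(tab)
      tibble(site = s, class = cl,
             used_bloomed = tab[1, 1], nonused_bloomed = tab[1, 2],
             used_clean = tab[2, 1], nonused_clean = tab[2, 2],
             odds_ratio = res$odds_ratio, p.value = res$p.value)
    }) |>
      mutate(p.adjusted = pmin(1, .data$p.value * length(classes)))
  })
}
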