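#' Configuration for the synthetic allo-HSCT cohort generator
#'
#' Bundles every knob of [generate_cohort()] with validated defaults that
#' mirror the study design the pipeline targets: 31 patients, three oral
#' sites, five timepoints anchored to stem-cell infusion (day 0), severe
#' dysbiosis peaking at engraftment, patient-specific dysbiotic states
#' (so inter-patient dispersion is maximal at E), injected blooms,
#' antibiotic timelines, and survival outcomes in which true non-recoverers
#' carry a multiplied hazard.
#'
#' @param n_patients Number of patients (>= 2; default 31).
#' @param n_taxa Number of genera (>= 3; default 60).
#' @param sites Oral site labels (default GCF, OM, SB).
#' @param timepoint_days Named integer vector of day offsets for the ordered
#'   timepoints (default P=-10, A=7, E=14, E30=44, E75=89); must be strictly
#'   increasing.
#' @param library_size_range Min/max library size for the multinomial draw
#'   (default 5000-20000 reads).
#' @param dirichlet_concentration Named pair `c(baseline=, perturbed=)`:
#'   Dirichlet concentration of the compositional noise around the expected
#'   composition at unperturbed and fully perturbed timepoints; the
#'   effective concentration interpolates with the perturbation weight, so
#'   it is lowest (noisiest) at E and equals `baseline` everywhere when
#'   `perturbation_depth = 0`.
#' @param perturbation_depth Peak mixing weight in `[0, 1]` of the
#'   patient-specific dysbiotic composition at E (default 0.85).
#' @param bloom_rate Expected transient injected blooms per patient
#'   (default 1.8). True non-recoverers additionally carry a persistent
#'   opportunist domination in every site, so the total event rate at the
#'   defaults is about 2.6 per patient — roughly 80 events over 31 patients.
#' @param bloom_dominance Range (or scalar) of injected relative abundance
#'   for bloom taxa (default 0.35-0.6, comfortably above the 30% dominance
#'   definition).
#' @param recovery_prob Probability a patient truly recovers baseline
#'   composition by E30 (default 0.74, between the per-site 69-77% rates).
#' @param abx_model Tibble with one row per antibiotic class: `class`,
#'   `agent`, `prob` (per-patient usage probability), `mean_length` (mean
#'   course length, days). Default mirrors the usage spectrum of an
#'   allo-HSCT ward (cephalosporins/carbapenems/glycopeptides dominant).
#' @param hazard_model List: `base_rate` (events/day for the event of
#'   interest), `competing_rate`, `log_hr_nonrecovery` (log hazard ratio
#'   multiplying the event-of-interest hazard for true non-recoverers;
#'   default `log(5)`), `horizon` (administrative censoring day).
#' @param dropout Named fractions of E30/E75 samples lost to follow-up
#'   (default `c(E30 = 0.03, E75 = 0.15)`).
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate identical cohorts.
#' @return A validated list of class `oralhsct_cohort_config`.
#' @export
cohort_config <- function(n_patients = 31,
                          n_taxa = 60,
                          sites = ORAL_SITES,
                          timepoint_days = c(P = -10L, A = 7L, E = 14L, E30 = 44L, E75 = 89L),
                          library_size_range = c(5000L, 20000L),
                          dirichlet_concentration = c(baseline = 200, perturbed = 40),
                          perturbation_depth = 0.85,
                          bloom_rate = 1.8,
                          bloom_dominance = c(0.35, 0.6),
                          recovery_prob = 0.74,
                          abx_model = default_abx_model(),
                          hazard_model = list(base_rate = 1 / 600,
                                              competing_rate = 1 / 900,
                                              log_hr_nonrecovery = log(5),
                                              horizon = 1095),
                          dropout = c(E30 = 0.03, E75 = 0.15),
                          seed = 1L) {
  if (n_taxa < 3) stop_oralhsct("n_taxa must be >= 3")
  if (n_patients < 2) stop_oralhsct("n_patients must be >= 2")
  if (!identical(names(timepoint_days), TIMEPOINTS)) {
    stop_oralhsct("timepoint_days must be named P, A, E, E30, E75 in order")
  }
  if (any(diff(timepoint_days) <= 0)) stop_oralhsct("timepoint day offsets must be strictly increasing")
  if (perturbation_depth < 0 || perturbation_depth > 1) {
    stop_oralhsct("perturbation_depth must be in [0, 1]")
  }
  if (recovery_prob < 0 || recovery_prob > 1) stop_oralhsct("recovery_prob must be in [0, 1]")
  if (any(abx_model$prob < 0 | abx_model$prob > 1)) stop_oralhsct("abx usage probabilities must be in [0, 1]")
  if (any(library_size_range < 1) || library_size_range[1] > library_size_range[2]) {
    stop_oralhsct("library_size_range must be an increasing pair of positive counts")
  }
  if (any(dirichlet_concentration <= 0)) stop_oralhsct("Dirichlet concentrations must be positive")
  if (bloom_rate < 0) stop_oralhsct("bloom_rate must be non-negative")
  if (length(bloom_dominance) == 1) bloom_dominance <- rep(bloom_dominance, 2)
  structure(list(
    n_patients = as.integer(n_patients), n_taxa = as.integer(n_taxa),
    sites = sites, timepoint_days = timepoint_days,
    library_size_range = as.integer(library_size_range),
    dirichlet_concentration = dirichlet_concentration,
    perturbation_depth = perturbation_depth,
    bloom_rate = bloom_rate, bloom_dominance = bloom_dominance,
    recovery_prob = recovery_prob, abx_model = abx_model,
    hazard_model = hazard_model, dropout = dropout,
    seed = as.integer(seed)
  ), class = "oralhsct_cohort_config")
}

#' @rdname cohort_config
#' @export
default_abx_model <- function() {
  tibble(
    class = c("cephalosporins", "carbapenems", "glycopeptides", "penicillins",
              "oxazolidinones", "polymyxins", "tetracyclines", "fluoroquinolones",
              "macrolides", "aminoglycosides", "nitroimidazoles", "lipopeptides"),
    agent = c("cefepime", "meropenem", "vancomycin", "piperacillin-tazobactam",
              "linezolid", "polymyxin-b", "tigecycline", "ciprofloxacin",
              "azithromycin", "amikacin", "metronidazole", "daptomycin"),
    prob = c(0.73, 0.63, 0.60, 0.23, 0.16, 0.13, 0.10, 0.08, 0.06, 0.06, 0.05, 0.03),
    mean_length = c(8, 9, 10, 6, 7, 7, 6, 5, 4, 6, 5, 7)
  )
}

#' Random rooted tree over the taxon universe
#'
#' A random coalescent topology ([ape::rcoal()]) with strictly positive
#' branch lengths and leaves labelled `taxon_1..taxon_n` — the phylogeny
#' weighted UniFrac requires. Terminal (pendant) branches are lengthened by
#' `pendant` to mimic genus-level 16S trees, whose tip branches are long
#' relative to the internal backbone; this keeps phylogenetically disjoint
#' communities far apart on the bounded normalized UniFrac scale.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed; the same seed gives an identical newick string.
#' @param pendant Length added to every terminal branch (default 2, about
#'   the expected coalescent tree height).
#' @return A rooted binary [ape::phylo] tree.
#' @export
generate_tree <- function(n_taxa, seed = 1L, pendant = 2) {
  if (n_taxa < 2) stop_oralhsct("n_taxa must be >= 2")
  local_seeded(seed, random_tree(n_taxa, pendant))
}

random_tree <- function(n_taxa, pendant = 2) {
  tree <- ape::rcoal(n_taxa, tip.label = paste0("taxon_", seq_len(n_taxa)))
  tip_edges <- tree$edge[, 2] <= n_taxa
  tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] + pendant
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  tree
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic longitudinal multi-site cohort
#'
#' Draws, per patient and site, a baseline composition from a site-specific
#' Dirichlet; interpolates each timepoint's expected composition between
#' baseline and a patient-specific dysbiotic state (mixing weight peaking at
#' engraftment, persisting through E30/E75 for true non-recoverers); adds
#' Dirichlet compositional noise whose concentration drops with the
#' perturbation weight; injects blooms (a taxon rare at preconditioning
#' raised to dominance at a post-P timepoint); and draws multinomial read
#' counts at a library size uniform over `library_size_range`. Antibiotic
#' courses follow the per-class usage model, and survival outcomes are
#' exponential with the event-of-interest hazard multiplied by
#' `exp(log_hr_nonrecovery)` for true non-recoverers, with a latent
#' competing event and administrative censoring.
#'
#' @param config A [cohort_config()].
#' @return A list of class `oralhsct_cohort` with elements `counts` (wide
#'   count tibble), `meta`, `tree`, `abx`, `outcomes` (including the
#'   per-patient `e30_day` landmark), `truth` (list: `recovery` per patient,
#'   `blooms` injected (patient, site, taxon, timepoint) records), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "oralhsct_cohort_config"))
  local_seeded(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  taxa <- paste0("taxon_", seq_len(cfg$n_taxa))
  tree <- random_tree(cfg$n_taxa)
  patients <- sprintf("patient_%02d", seq_len(cfg$n_patients))
  tps <- names(cfg$timepoint_days)

  # global genus pool and site-specific mean compositions
  global <- rdirichlet1(rep(0.6, cfg$n_taxa))
  site_mean <- lapply(cfg$sites, function(s) rdirichlet1(global * 60 + 0.05))
  names(site_mean) <- cfg$sites

  # perturbation weight profile over timepoints; E30/E75 depend on true
  # recovery status (non-recoverers stay in the dysbiotic state)
  w_shape_rec <- c(P = 0, A = 0.55, E = 1, E30 = 0.15, E75 = 0.05)
  w_shape_non <- c(P = 0, A = 0.55, E = 1, E30 = 0.9, E75 = 0.8)

  recovered <- runif(cfg$n_patients) < cfg$recovery_prob
  names(recovered) <- patients

  # per-patient day jitter for post-engraftment visits (discharge schedules)
  e30_jitter <- sample(-8:8, cfg$n_patients, replace = TRUE)
  e75_jitter <- sample(-12:12, cfg$n_patients, replace = TRUE)

  # sample dropout at E30/E75, decided up-front so blooms are only injected
  # into samples that exist
  exists_tbl <- list()
  for (pi in seq_len(cfg$n_patients)) {
    for (s in cfg$sites) {
      keep <- setNames(rep(TRUE, length(tps)), tps)
      keep["E30"] <- runif(1) >= cfg$dropout[["E30"]]
      keep["E75"] <- runif(1) >= cfg$dropout[["E75"]]
      exists_tbl[[paste(patients[pi], s)]] <- keep
    }
  }

  # per patient-site baseline and dysbiotic target compositions
  baseline <- list(); dys <- list()
  for (pi in seq_len(cfg$n_patients)) {
    for (s in cfg$sites) {
      key <- paste(patients[pi], s)
      b <- rdirichlet1(site_mean[[s]] * cfg$dirichlet_concentration[["baseline"]] / 2 + 0.02)
      baseline[[key]] <- b
      # dysbiotic state: a sharp patient-specific tilt over taxa already
      # abundant at baseline, so blooms (rare -> dominant) never arise from
      # the dysbiosis mixture itself
      eligible <- which(b >= 0.04)
      if (length(eligible) < 3) eligible <- order(b, decreasing = TRUE)[1:6]
      k <- min(8, length(eligible))
      support <- sample(eligible, k, prob = b[eligible])
      dv <- numeric(cfg$n_taxa)
      dv[support] <- rdirichlet1(rep(0.3, k))
      dys[[key]] <- dv
    }
  }

  # Opportunist domination: each true non-recoverer converges to an
  # alternative state dominated by a taxon rare at baseline, in all oral
  # sites, from engraftment onward (the persistent-domination phenotype of
  # severe dysbiosis). These are genuine rare-to-dominant events and are
  # recorded in the bloom truth alongside the transient injected blooms.
  bloom_truth <- list()
  if (cfg$perturbation_depth > 0) {
    for (pi in seq_len(cfg$n_patients)) {
      if (recovered[pi]) next
      rare_all <- which(Reduce(`&`, lapply(cfg$sites, function(s) {
        baseline[[paste(patients[pi], s)]] < 0.003
      })))
      if (length(rare_all) == 0) next
      opp <- rare_all[sample.int(length(rare_all), 1)]
      r <- runif(1, 0.6, 0.85)
      for (s in cfg$sites) {
        key <- paste(patients[pi], s)
        for (tp in c("E", "E30", "E75")) {
          if (!exists_tbl[[key]][[tp]]) next
          bloom_truth[[length(bloom_truth) + 1]] <- tibble(
            patient_id = patients[pi], site = s, taxon = taxa[opp],
            timepoint = tp, dominance = r, kind = "domination")
        }
      }
    }
  }
  # transient blooms: Poisson number per patient, site uniform, timepoint
  # at aplasia or (mostly) engraftment, resolved afterwards
  tp_weight <- c(A = 0.35, E = 0.65)
  for (pi in seq_len(cfg$n_patients)) {
    n_bloom <- rpois(1, cfg$bloom_rate)
    for (b in seq_len(n_bloom)) {
      s <- sample(cfg$sites, 1)
      key <- paste(patients[pi], s)
      tp <- sample(names(tp_weight), 1, prob = tp_weight)
      rare <- which(baseline[[key]] < 0.003)
      if (length(rare) == 0) rare <- which.min(baseline[[key]])
      taxon <- rare[sample.int(length(rare), 1)]
      dom <- runif(1, cfg$bloom_dominance[1], cfg$bloom_dominance[2])
      bloom_truth[[length(bloom_truth) + 1]] <- tibble(
        patient_id = patients[pi], site = s, taxon = taxa[taxon],
        timepoint = tp, dominance = dom, kind = "transient")
    }
  }
  # injection plan: one row per (patient, site, taxon, timepoint);
  # concurrent same-sample injections are kept only while their joint mass
  # stays below 0.85 (domination first), so every retained injection
  # satisfies the dominance definition exactly
  blooms <- if (length(bloom_truth)) {
    bind_rows(bloom_truth) |>
      distinct(.data$patient_id, .data$site, .data$taxon, .data$timepoint,
               .keep_all = TRUE) |>
      group_by(.data$patient_id, .data$site, .data$timepoint) |>
      filter(cumsum(.data$dominance) <= 0.85) |>
      ungroup()
  } else {
    tibble(patient_id = character(), site = character(), taxon = character(),
           timepoint = character(), dominance = numeric(), kind = character())
  }
  # ground-truth events: one per (patient, site, taxon), onset at the
  # earliest injected timepoint
  bloom_events <- if (nrow(blooms) == 0) {
    tibble(patient_id = character(), site = character(), taxon = character(),
           kind = character(), onset = character(), dominance = numeric())
  } else {
    blooms |>
      mutate(.tp = factor(.data$timepoint, levels = TIMEPOINTS)) |>
      group_by(.data$patient_id, .data$site, .data$taxon, .data$kind) |>
      summarise(onset = as.character(sort(.data$.tp)[1]),
                dominance = max(.data$dominance), .groups = "drop")
  }

  conc_base <- cfg$dirichlet_concentration[["baseline"]]
  conc_pert <- cfg$dirichlet_concentration[["perturbed"]]

  bloom_by_key <- split(blooms, paste(blooms$patient_id, blooms$site))
  meta_rows <- list(); count_rows <- list()
  for (pi in seq_len(cfg$n_patients)) {
    pat <- patients[pi]
    days <- cfg$timepoint_days
    days[["E30"]] <- days[["E30"]] + e30_jitter[pi]
    days[["E75"]] <- days[["E75"]] + e75_jitter[pi]
    shape <- if (recovered[pat]) w_shape_rec else w_shape_non
    for (s in cfg$sites) {
      key <- paste(pat, s)
      for (tp in tps) {
        if (!exists_tbl[[key]][[tp]]) next
        w <- cfg$perturbation_depth * shape[[tp]]
        expected <- (1 - w) * baseline[[key]] + w * dys[[key]]
        conc <- (1 - w) * conc_base + w * conc_pert
        comp <- rdirichlet1(conc * expected)
        bl <- bloom_by_key[[key]]
        if (!is.null(bl) && nrow(bl) > 0) {
          idx <- match(bl$taxon, taxa)
          if (tp == "P") {
            # guarantee the injected taxa are rare at preconditioning
            over <- comp[idx] > 0.005
            if (any(over)) {
              comp[idx[over]] <- 0.005
              comp <- comp / sum(comp)
            }
          }
          hit <- bl$timepoint == tp
          if (any(hit)) {
            dom <- bl$dominance[hit]
            comp <- comp * (1 - sum(dom))
            comp[idx[hit]] <- comp[idx[hit]] + dom
          }
        }
        lib <- sample(cfg$library_size_range[1]:cfg$library_size_range[2], 1)
        cnt <- as.integer(rmultinom(1, lib, comp))
        sid <- paste(pat, s, tp, sep = "_")
        meta_rows[[sid]] <- tibble(sample_id = sid, patient_id = pat, site = s,
                                   timepoint = tp, day = as.integer(days[[tp]]))
        count_rows[[sid]] <- cnt
      }
    }
  }
  meta <- bind_rows(meta_rows) |> validate_metadata()
  m <- do.call(rbind, count_rows)
  rownames(m) <- names(count_rows); colnames(m) <- taxa

  # antibiotic courses
  abx_rows <- list()
  for (pi in seq_len(cfg$n_patients)) {
    for (ci in seq_len(nrow(cfg$abx_model))) {
      if (runif(1) < cfg$abx_model$prob[ci]) {
        n_courses <- 1 + rbinom(1, 1, 0.3)
        for (k in seq_len(n_courses)) {
          start <- round(runif(1, -8, 30))
          len <- 1 + rpois(1, cfg$abx_model$mean_length[ci] - 1)
          abx_rows[[length(abx_rows) + 1]] <- tibble(
            patient_id = patients[pi],
            agent = cfg$abx_model$agent[ci], class = cfg$abx_model$class[ci],
            start_day = as.integer(start), end_day = as.integer(start + len - 1))
        }
      }
    }
  }
  abx <- if (length(abx_rows)) bind_rows(abx_rows) else
    tibble(patient_id = character(), agent = character(), class = character(),
           start_day = integer(), end_day = integer())

  # survival outcomes: latent cause-specific exponential hazards, the
  # event-of-interest hazard multiplied for true non-recoverers
  hz <- cfg$hazard_model
  rate1 <- hz$base_rate * ifelse(recovered, 1, exp(hz$log_hr_nonrecovery))
  t1 <- rexp(cfg$n_patients, rate1)
  t2 <- rexp(cfg$n_patients, hz$competing_rate)
  tmin <- pmin(t1, t2)
  event <- ifelse(tmin >= hz$horizon, 0L, ifelse(t1 <= t2, 1L, 2L))
  time <- pmin(tmin, hz$horizon)
  e30_day <- cfg$timepoint_days[["E30"]] + e30_jitter
  outcomes <- tibble(
    patient_id = patients,
    time = pmax(round(time, 1), 0.5),
    event = event,
    age = round(pmin(pmax(rnorm(cfg$n_patients, 50, 12), 18), 75)),
    conditioning = sample(c("RIC", "MAC"), cfg$n_patients, replace = TRUE,
                          prob = c(0.61, 0.39)),
    e30_day = as.integer(e30_day)
  )

  structure(list(
    counts = count_tibble(m), meta = meta, tree = tree, abx = abx,
    outcomes = outcomes,
    truth = list(recovery = tibble(patient_id = patients,
                                   true_recovered = unname(recovered)),
                 blooms = bloom_events),
    config = cfg
  ), class = "oralhsct_cohort")
}

#' @export
print.oralhsct_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic allo-HSCT cohort: %d patients, %d samples, %d taxa, %d injected blooms\n",
    x$config$n_patients, nrow(x$meta), x$config$n_taxa, nrow(x$truth$blooms)))
  invisible(x)
}

#' Write or read a cohort bundle as plain-text files
#'
#' Serialises a cohort to a directory: `counts.tsv` (taxa rows x sample
#' columns), `metadata.csv`, `tree.nwk`, `abx.csv`, `outcomes.csv`,
#' `truth_recovery.csv`, `truth_blooms.csv`. `read_cohort()` restores the
#' bundle (minus the config).
#'
#' @param cohort An `oralhsct_cohort`.
#' @param dir Directory path (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   with the bundle's tables.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_metadata(cohort$meta, file.path(dir, "metadata.csv"))
  write_newick(cohort$tree, file.path(dir, "tree.nwk"))
  write_abx(cohort$abx, file.path(dir, "abx.csv"))
  write_outcomes(cohort$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(cohort$truth$recovery, file.path(dir, "truth_recovery.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$truth$blooms, file.path(dir, "truth_blooms.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  tree <- read_newick(file.path(dir, "tree.nwk"),
                      taxa = setdiff(names(counts), "sample_id"))
  list(counts = counts, meta = meta, tree = tree,
       abx = read_abx(file.path(dir, "abx.csv")),
       outcomes = read_outcomes(file.path(dir, "outcomes.csv")),
       truth = list(
         recovery = readr::read_csv(file.path(dir, "truth_recovery.csv"),
                                    col_types = readr::cols(), progress = FALSE,
                                    show_col_types = FALSE),
         blooms = readr::read_csv(file.path(dir, "truth_blooms.csv"),
                                  col_types = readr::cols(), progress = FALSE,
                                  show_col_types = FALSE)))
}
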