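ra_fixture <- function(values) {
  # values: named list timepoint -> named RA vector over taxa
  tps <- names(values)
  meta <- make_meta("p1", "GCF", tps, c(P = -10L, A = 7L, E = 14L, E30 = 44L,
                                        E75 = 89L)[tps])
  ra <- do.call(rbind, values)
  rownames(ra) <- meta$sample_id
  list(ra = ra, meta = meta)
}

test_that("bloom detection applies the strict baseline and dominance thresholds", {
  fx <- ra_fixture(list(P = c(t1 = 0.005, t2 = 0.995),
                        E = c(t1 = 0.35, t2 = 0.65)))
  ev <- detect_blooms(fx$ra, fx$meta, is_relative = TRUE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, "E")
  expect_equal(ev$taxon, "t1")
  # baseline exactly 1%: not a bloom (strict <)
  fx2 <- ra_fixture(list(P = c(t1 = 0.01, t2 = 0.99),
                         E = c(t1 = 0.40, t2 = 0.60)))
  expect_equal(nrow(detect_blooms(fx2$ra, fx2$meta, is_relative = TRUE)), 0)
  # dominance exactly 30% qualifies (inclusive >=)
  fx3 <- ra_fixture(list(P = c(t1 = 0, t2 = 1),
                         E = c(t1 = 0.30, t2 = 0.70)))
  expect_equal(nrow(detect_blooms(fx3$ra, fx3$meta, is_relative = TRUE)), 1)
})

test_that("a maximal run of dominant timepoints is one event with peak and length", {
  fx <- ra_fixture(list(P = c(t1 = 0, t2 = 1),
                        A = c(t1 = 0.02, t2 = 0.98),
                        E = c(t1 = 0.40, t2 = 0.60),
                        E30 = c(t1 = 0.45, t2 = 0.55),
                        E75 = c(t1 = 0.05, t2 = 0.95)))
  ev <- detect_blooms(fx$ra, fx$meta, is_relative = TRUE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, "E")
  expect_equal(ev$run_length, 2L)
  expect_equal(ev$peak_ra, 0.45)
  # per-timepoint counting splits the run
  ev2 <- detect_blooms(fx$ra, fx$meta, is_relative = TRUE, per_timepoint = TRUE)
  expect_equal(nrow(ev2), 2)
  expect_setequal(ev2$onset, c("E", "E30"))
})

test_that("patient-sites without a preconditioning sample are skipped with a report", {
  fx <- ra_fixture(list(A = c(t1 = 0.01, t2 = 0.99),
                        E = c(t1 = 0.5, t2 = 0.5)))
  ev <- detect_blooms(fx$ra, fx$meta, is_relative = TRUE)
  expect_equal(nrow(ev), 0)
  skipped <- attr(ev, "skipped")
  expect_equal(skipped$patient_id, "p1")
  expect_match(skipped$reason, "missing P")
})

test_that("the detector equals an exhaustive per-triple scan on random tables", {
  withr::local_seed(61)
  for (rep in 1:100) {
    n_pat <- sample(2:4, 1)
    tps <- c("P", sample(c("A", "E", "E30", "E75"), sample(2:4, 1)))
    tps <- intersect(oral_timepoints(), tps)
    meta <- purrr::map_dfr(seq_len(n_pat), function(i) {
      make_meta(paste0("p", i), "SB", tps,
                c(P = -10L, A = 7L, E = 14L, E30 = 44L, E75 = 89L)[tps])
    })
    ra <- t(vapply(seq_len(nrow(meta)), function(i) {
      x <- rgamma(6, 0.25); x / sum(x)
    }, numeric(6)))
    colnames(ra) <- paste0("t", 1:6)
    rownames(ra) <- meta$sample_id
    got <- detect_blooms(ra, meta, is_relative = TRUE) |>
      dplyr::arrange(patient_id, taxon, onset)
    want <- brute_bloom_scan(ra, meta) |>
      dplyr::arrange(patient_id, taxon, onset)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$patient_id, want$patient_id)
      expect_equal(got$taxon, want$taxon)
      expect_equal(got$onset, want$onset)
      expect_equal(got$run_length, want$run_length)
    }
  }
})

test_that("the detector recovers injected blooms on synthetic truth", {
  # strong injected dominance: the generator guarantees the definition holds
  total_truth <- 0; total_hit <- 0; total_false <- 0
  for (s in 1:20) {
    ch <- generate_cohort(cohort_config(n_patients = 20, n_taxa = 50,
                                        bloom_rate = 1, bloom_dominance = 0.5,
                                        seed = 700 + s))
    ev <- detect_blooms(ch$counts, ch$meta)
    truth <- ch$truth$blooms
    hits <- dplyr::inner_join(ev, truth, by = c("patient_id", "site", "taxon"))
    total_truth <- total_truth + nrow(truth)
    total_hit <- total_hit + nrow(hits)
    total_false <- total_false +
      nrow(dplyr::anti_join(ev, truth, by = c("patient_id", "site", "taxon")))
  }
  expect_gte(total_hit / total_truth, 0.95)
  expect_lte(total_false / max(total_truth, 1), 0.01)
})

test_that("injected blooms satisfy the detector definition exactly at the onset", {
  for (s in 1:3) {
    ch <- generate_cohort(cohort_config(n_patients = 10, n_taxa = 40, seed = 800 + s))
    ra <- count_matrix(relative_abundance(ch$counts), integer = FALSE)
    ok_base <- ok_dom <- TRUE
    for (i in seq_len(nrow(ch$truth$blooms))) {
      b <- ch$truth$blooms[i, ]
      p_id <- paste(b$patient_id, b$site, "P", sep = "_")
      t_id <- paste(b$patient_id, b$site, b$onset, sep = "_")
      if (!p_id %in% rownames(ra) || !t_id %in% rownames(ra)) next
      ok_base <- ok_base && ra[p_id, b$taxon] < 0.01
      ok_dom <- ok_dom && ra[t_id, b$taxon] >= 0.30
    }
    expect_true(ok_base)
    expect_true(ok_dom)
  }
})

test_that("LOT counts the day union while DOT counts agent-days", {
  mk <- function(...) {
    rows <- list(...)
    purrr::map_dfr(rows, function(r) {
      tibble::tibble(patient_id = "p1", agent = r[[1]], class = r[[2]],
                     start_day = as.integer(r[[3]]), end_day = as.integer(r[[4]]))
    })
  }
  w <- c(0L, 60L)
  e1 <- compute_exposure(mk(list("X", "cx", 1, 5), list("Y", "cy", 1, 5)), w)
  expect_equal(e1$lot, 5); expect_equal(e1$dot, 10)
  e2 <- compute_exposure(mk(list("X", "cx", 1, 3), list("Y", "cy", 5, 8)), w)
  expect_equal(e2$lot, 7); expect_equal(e2$dot, 7)
  e3 <- compute_exposure(mk(list("X", "cx", 1, 5), list("Y", "cy", 3, 7)), w)
  expect_equal(e3$lot, 7); expect_equal(e3$dot, 10)
  # clipping to the window, inclusive endpoints
  e4 <- compute_exposure(mk(list("X", "cx", -5, 2)), c(0L, 60L))
  expect_equal(e4$lot, 3)  # days 0,1,2
  # course entirely outside the window is ignored
  e5 <- compute_exposure(mk(list("X", "cx", 70, 80), list("Y", "cy", 1, 2)), w)
  expect_equal(e5$lot, 2); expect_equal(e5$dot, 2)
  expect_false(e5$class_cx)
  expect_true(e5$class_cy)
  # prophylaxis deny-list removes the agent everywhere
  e6 <- compute_exposure(mk(list("levofloxacin", "fluoroquinolones", 1, 30),
                            list("Y", "cy", 1, 2)), w)
  expect_equal(e6$lot, 2)
  expect_false("class_fluoroquinolones" %in% names(e6))
})

test_that("LOT never exceeds DOT and equals it without agent overlap", {
  withr::local_seed(67)
  for (i in 1:30) {
    n <- sample(1:6, 1)
    abx <- tibble::tibble(
      patient_id = "p", agent = paste0("a", seq_len(n)),
      class = paste0("c", seq_len(n)),
      start_day = as.integer(sample(-10:40, n, replace = TRUE))) |>
      dplyr::mutate(end_day = start_day + as.integer(sample(0:14, n, replace = TRUE)))
    e <- compute_exposure(abx, c(-10L, 44L))
    expect_lte(e$lot, e$dot)
    # day-by-day enumeration oracle
    days_by_agent <- purrr::pmap(abx[c("start_day", "end_day")], function(start_day, end_day) {
      intersect(start_day:end_day, -10:44)
    })
    expect_equal(e$lot, length(unique(unlist(days_by_agent))))
    expect_equal(e$dot, sum(lengths(days_by_agent)))
  }
})

test_that("class prevalence filter keeps classes at or above the patient fraction", {
  flags <- tibble::tibble(
    patient_id = paste0("p", 1:30),
    lot = 0, dot = 0, n_agents = 0, n_classes = 0,
    class_kept = c(rep(TRUE, 6), rep(FALSE, 24)),
    class_dropped = c(rep(TRUE, 5), rep(FALSE, 25)))
  expect_equal(class_prevalence_filter(flags), "kept")
  expect_setequal(class_prevalence_filter(flags, min_frac = 0),
                  c("kept", "dropped"))
})

test_that("Fisher conditional-MLE odds ratio matches known values", {
  # glycopeptide-usage by GCF-bloom table
  res <- fisher_exact_or(matrix(c(11, 1, 7, 11), 2, 2, byrow = TRUE))
  expect_equal(round(res$odds_ratio, 2), 15.65)
  expect_lt(res$p.value, 0.01)
  expect_equal(fisher_exact_or(matrix(1, 2, 2))$odds_ratio, 1)
  expect_equal(fisher_exact_or(diag(5, 2))$odds_ratio, Inf)
  zm <- fisher_exact_or(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_true(is.na(zm$odds_ratio))
  expect_equal(zm$p.value, 1)
})

test_that("Mann-Whitney U is exact for small samples and detects shifts", {
  res <- mannwhitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p.value, 1 / 3)  # 2 of 6 orderings as extreme
  expect_equal(mannwhitney(c(5, 6, 7), c(5, 6, 7))$p.value, 1)
  withr::local_seed(71)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  expect_lt(mannwhitney(a, b)$p.value, 0.01)
})

test_that("chi-square prevalence test matches the direct O-E formula", {
  expect_equal(chisq_prevalence(c(10, 10), c(20, 20))$statistic, 0)
  aff <- c(23, 14, 16); tot <- c(31, 31, 30)
  res <- chisq_prevalence(aff, tot)
  obs <- rbind(aff, tot - aff)
  exp_tab <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(res$statistic, sum((obs - exp_tab)^2 / exp_tab), tolerance = 1e-12)
  # column order invariance
  res2 <- chisq_prevalence(rev(aff), rev(tot))
  expect_equal(res2$statistic, res$statistic)
})

test_that("bloom-antibiotic association screens retained classes with Bonferroni", {
  ch <- generate_cohort(cohort_config(seed = 13))
  ev <- detect_blooms(ch$counts, ch$meta)
  expo <- compute_exposure(ch$abx, window = c(-10L, 44L),
                           patients = unique(ch$meta$patient_id))
  assoc <- bloom_abx_association(ev, expo)
  expect_true(all(assoc$p.adjusted >= assoc$p.value))
  expect_true(all(assoc$p.adjusted <= 1))
  retained <- class_prevalence_filter(expo)
  expect_setequal(unique(assoc$class), retained)
  counts <- assoc$used_bloomed + assoc$nonused_bloomed +
    assoc$used_clean + assoc$nonused_clean
  expect_true(all(counts == nrow(expo)))
})
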