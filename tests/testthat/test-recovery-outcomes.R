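test_that("recovery calls use a strict distance threshold and flag missing samples", {
  meta <- dplyr::bind_rows(
    make_meta("p1", "OM", c("P", "E30"), c(-10L, 44L)),
    make_meta("p2", "OM", c("P", "E30"), c(-10L, 44L)),
    make_meta("p3", "OM", "P", -10L))
  ids <- meta$sample_id
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  d["p1_OM_P", "p1_OM_E30"] <- d["p1_OM_E30", "p1_OM_P"] <- 0.49
  d["p2_OM_P", "p2_OM_E30"] <- d["p2_OM_E30", "p2_OM_P"] <- 0.50
  rc <- classify_recovery(d, meta)
  expect_true(rc$recovered[rc$patient_id == "p1"])
  expect_false(rc$recovered[rc$patient_id == "p2"])  # 0.50 is not < 0.5
  expect_false(rc$evaluable[rc$patient_id == "p3"])
  expect_true(is.na(rc$recovered[rc$patient_id == "p3"]))
})

test_that("recovery classification is monotone in the threshold", {
  withr::local_seed(73)
  meta <- purrr::map_dfr(1:8, function(i) {
    make_meta(paste0("p", i), "OM", c("P", "E30"), c(-10L, 44L))
  })
  ids <- meta$sample_id
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in 1:8) {
    v <- runif(1)
    d[2 * i - 1, 2 * i] <- d[2 * i, 2 * i - 1] <- v
  }
  thr <- sort(runif(5))
  calls <- lapply(thr, function(t) classify_recovery(d, meta, threshold = t)$recovered)
  for (k in seq_len(length(thr) - 1)) {
    expect_true(all(calls[[k]] <= calls[[k + 1]]))
  }
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  # ties: average ranks, matched against the direct rank formula
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 1, 4, 4, 6, 8)
  expect_equal(spearman_cor(x, y)$rho,
               stats::cor(rank(x), rank(y)))
})

test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  rec <- tibble::tibble(patient_id = paste0("p", 1:4),
                        time = c(2, 5, 7, 11), event = c(1L, 1L, 1L, 1L),
                        x = c(1, 0, 1, 0))
  fit <- cox_univariate(rec, "x", event_of_interest = 1)
  # no ties: the partial likelihood has a closed product form
  loglik <- function(b) {
    risk <- exp(b * rec$x)
    ord <- order(rec$time)
    sum(vapply(ord, function(i) {
      at_risk <- rec$time >= rec$time[i]
      b * rec$x[i] - log(sum(risk[at_risk]))
    }, numeric(1)))
  }
  grid <- seq(-4, 4, by = 1e-3)
  b_star <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_equal(fit$estimate, b_star, tolerance = 2e-3)
})

test_that("constant covariates yield a null hazard fit", {
  rec <- tibble::tibble(patient_id = paste0("p", 1:6), time = c(3, 6, 9, 12, 15, 18),
                        event = rep(1L, 6), x = rep(1, 6))
  fit <- cox_univariate(rec, "x")
  expect_equal(fit$hr, 1)
  expect_equal(fit$p.value, 1)
  expect_true("constant covariate" %in% fit$flags)
})

test_that("landmark exclusion removes patients with follow-up before E30", {
  rec <- tibble::tibble(patient_id = paste0("p", 1:6),
                        time = c(10, 200, 300, 400, 30, 500),
                        event = c(1L, 1L, 0L, 1L, 1L, 0L),
                        e30_day = rep(44L, 6),
                        x = c(0, 1, 0, 0, 0, 1))
  fit <- cox_univariate(rec, "x")
  expect_setequal(fit$excluded, c("p1", "p5"))
  expect_equal(fit$n, 4)
})

test_that("Cox estimates are invariant to positive time rescaling", {
  withr::local_seed(79)
  rec <- tibble::tibble(patient_id = paste0("p", 1:60),
                        time = rexp(60, 0.02), event = rbinom(60, 1, 0.8),
                        x = rnorm(60))
  f1 <- cox_univariate(rec, "x", event_of_interest = 1)
  f2 <- cox_univariate(rec |> dplyr::mutate(time = time * 3.7), "x",
                       event_of_interest = 1)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
})

test_that("Fine-Gray reduces exactly to Cox without competing events", {
  withr::local_seed(83)
  rec <- tibble::tibble(patient_id = paste0("p", 1:80),
                        time = rexp(80, 0.01), event = rbinom(80, 1, 0.7),
                        x = rnorm(80))
  fc <- cox_univariate(rec, "x", event_of_interest = 1)
  ff <- finegray_univariate(rec, "x")
  expect_lt(abs(fc$estimate - ff$estimate), 1e-8)
  expect_lt(abs(fc$se - ff$se), 1e-8)
})

test_that("Fine-Gray agrees with the cmprsk reference under competing risks", {
  withr::local_seed(89)
  n <- 250
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.01 * exp(-0.8 * x))
  t2 <- rexp(n, 0.008)
  cens <- runif(n, 50, 400)
  tm <- pmin(t1, t2, cens)
  ev <- ifelse(tm == cens, 0L, ifelse(t1 <= t2, 1L, 2L))
  rec <- tibble::tibble(patient_id = paste0("p", 1:n), time = tm, event = ev, x = x)
  ours <- finegray_univariate(rec, "x")
  ref <- cmprsk::crr(ftime = tm, fstatus = ev, cov1 = cbind(x = x))
  expect_equal(ours$estimate, unname(ref$coef), tolerance = 5e-3)
})

test_that("Fine-Gray recovers a simulated subdistribution hazard ratio", {
  # subdistribution model: P(cause 1 by t | x) = 1-(1-p(1-exp(-t)))^exp(b x)
  withr::local_seed(97)
  hits <- 0; n_rep <- 50
  for (r in seq_len(n_rep)) {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    b <- log(0.25)
    p0 <- 0.85  # high baseline cause-1 incidence keeps the fit informative
    u <- runif(n)
    cause1 <- u < 1 - (1 - p0)^exp(b * x)
    tm <- numeric(n)
    # cause-1 times from the conditional subdistribution; cause-2 exponential
    uu <- runif(n)
    frac <- 1 - (1 - uu * (1 - (1 - p0)^exp(b * x)))^(exp(-b * x))
    tm[cause1] <- -log(1 - frac[cause1] / p0)
    tm[!cause1] <- rexp(sum(!cause1), 1)
    ev <- ifelse(cause1, 1L, 2L)
    rec <- tibble::tibble(patient_id = paste0("p", 1:n),
                          time = pmax(tm, 1e-4), event = ev, x = x)
    f <- finegray_univariate(rec, "x")
    hits <- hits + (abs(f$estimate - b) <= 0.25)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("all-censored records yield a flagged, uninformative fit", {
  rec <- tibble::tibble(patient_id = paste0("p", 1:10), time = 1:10 * 10,
                        event = rep(0L, 10), x = rnorm(10))
  f <- finegray_univariate(rec, "x")
  expect_true(any(grepl("no events", f$flags)))
  expect_equal(f$hr, 1)
})

test_that("multivariate adjustment selects confounders and corrects the estimate", {
  withr::local_seed(101)
  n <- 400
  z <- rbinom(n, 1, 0.5)                       # confounder
  x <- rbinom(n, 1, plogis(-1 + 2.5 * z))      # exposure driven by z
  tm <- rexp(n, 0.01 * exp(0.0 * x + 1.2 * z)) # hazard driven by z only
  rec <- tibble::tibble(patient_id = paste0("p", 1:n), time = tm,
                        event = rep(1L, n), x = x, z = z)
  res <- multivariate_adjust(rec, "x", confounders = "z", model = "cox",
                             event_of_interest = 1)
  expect_identical(res$selected, "z")
  unadj <- cox_univariate(rec, "x", event_of_interest = 1)
  # true direct effect of x is zero: adjustment moves the estimate toward 0
  expect_lt(abs(res$fit$estimate), abs(unadj$estimate))
  # no significant confounders: equals the univariate fit
  rec2 <- rec |> dplyr::mutate(z = rnorm(n))
  tm2 <- rexp(n, 0.01 * exp(-0.7 * rec2$x))
  rec2$time <- tm2
  res2 <- multivariate_adjust(rec2, "x", confounders = "z", model = "cox",
                              event_of_interest = 1)
  if (length(res2$selected) == 0) {
    expect_equal(res2$fit$estimate,
                 cox_univariate(rec2, "x", event_of_interest = 1)$estimate,
                 tolerance = 1e-10)
  }
  # selection threshold 1 forces every candidate in
  res3 <- multivariate_adjust(rec, "x", confounders = "z", model = "cox",
                              select_p = 1, event_of_interest = 1)
  expect_identical(res3$selected, "z")
})

test_that("Kaplan-Meier and cumulative incidence satisfy their identities", {
  # no events: survival stays at 1
  rec0 <- tibble::tibble(patient_id = paste0("p", 1:5), time = 1:5 * 10,
                         event = rep(0L, 5))
  cv0 <- km_and_cif(rec0)
  expect_true(all(cv0$km$estimate == 1))
  # single event among n: one step of size 1/n
  rec1 <- tibble::tibble(patient_id = paste0("p", 1:5), time = c(10, 20, 30, 40, 50),
                         event = c(0L, 1L, 0L, 0L, 0L))
  cv1 <- km_and_cif(rec1)
  expect_equal(min(cv1$km$estimate), 1 - 1 / 4)  # 4 at risk at t=20
  # competing risks: cause-specific incidences sum to 1 - event-free KM
  withr::local_seed(103)
  n <- 120
  tm <- rexp(n, 0.02)
  ev <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  rec <- tibble::tibble(patient_id = paste0("p", 1:n), time = tm, event = ev)
  cv <- km_and_cif(rec)
  cif_sum <- cv$cif |>
    dplyr::group_by(time) |>
    dplyr::summarise(s = sum(estimate))
  km_at <- stats::approx(cv$km$time, cv$km$estimate, xout = cif_sum$time,
                         method = "constant", rule = 2)$y
  expect_equal(cif_sum$s, 1 - km_at, tolerance = 1e-8)
})

test_that("tidy and glance summarize hazard fits in broom style", {
  withr::local_seed(107)
  rec <- tibble::tibble(patient_id = paste0("p", 1:50), time = rexp(50, 0.02),
                        event = rbinom(50, 1, 0.8), x = rnorm(50))
  f <- cox_univariate(rec, "x", event_of_interest = 1)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "hr", "conf.low", "conf.high",
                    "p.value") %in% names(td)))
  expect_equal(td$hr, exp(td$estimate))
  expect_true(td$conf.low <= td$hr & td$hr <= td$conf.high)
  gl <- glance(f)
  expect_equal(gl$n, 50)
  expect_identical(gl$model, "Cox")
})
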