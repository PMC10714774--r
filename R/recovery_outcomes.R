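#' Classify recovery to baseline composition
#'
#' A patient-site recovers its baseline composition when the (normalized
#' weighted UniFrac) distance between its preconditioning (P) and E30
#' samples is strictly below `threshold` (default 0.5). Patient-sites
#' missing either sample are unevaluable and carry `recovered = NA`.
#' Classification is monotone in the threshold: raising it never turns a
#' recoverer into a non-recoverer.
#'
#' @param d Distance matrix over samples.
#' @param meta Sample metadata.
#' @param threshold Strict recovery threshold on the distance (default 0.5).
#' @return A tibble with `patient_id`, `site`, `distance_P_E30`,
#'   `recovered`, `evaluable`.
#' @export
classify_recovery <- function(d, meta, threshold = 0.5) {
  d <- as_distance_matrix(d)
  meta <- validate_metadata(meta) |> filter(.data$sample_id %in% rownames(d))
  meta |>
    group_by(.data$patient_id, .data$site) |>
    dplyr::group_modify(function(g, key) {
      a <- g$sample_id[g$timepoint == "P"]
      b <- g$sample_id[g$timepoint == "E30"]
      if (length(a) == 1 && length(b) == 1) {
        dist <- d[a, b]
        tibble(distance_P_E30 = dist, recovered = dist < threshold, evaluable = TRUE)
      } else {
        tibble(distance_P_E30 = NA_real_, recovered = NA, evaluable = FALSE)
      }
    }) |>
    ungroup()
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, two-sided p-value
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A tibble with `rho` and `p.value`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value)
}

# Landmark exclusion: patients whose follow-up ended (event or censoring)
# before their own E30 evaluation day contribute to no fit.
apply_landmark <- function(records, landmark_col = "e30_day") {
  if (!landmark_col %in% names(records)) {
    return(list(records = records, excluded = character(0)))
  }
  drop <- records$time < records[[landmark_col]]
  list(records = records[!drop, , drop = FALSE],
       excluded = records$patient_id[drop])
}

new_hazard_fit <- function(fit, model, covariate, data, excluded, flags = character(0)) {
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  idx <- grep(paste0("^", covariate), rownames(co))[1]
  if (is.na(idx)) idx <- 1
  est <- co[idx, "coef"]
  se <- co[idx, "se(coef)"]
  structure(list(
    model = model, covariate = covariate,
    estimate = est, hr = exp(est),
    conf.low = exp(est - 1.96 * se), conf.high = exp(est + 1.96 * se),
    se = se, p.value = co[idx, "Pr(>|z|)"],
    n = sm$n, n_events = sm$nevent,
    excluded = excluded, flags = flags, fit = fit
  ), class = "oralhsct_hazard_fit")
}

constant_covariate_fit <- function(model, covariate, n, excluded) {
  structure(list(model = model, covariate = covariate,
                 estimate = 0, hr = 1, conf.low = NA_real_, conf.high = NA_real_,
                 se = NA_real_, p.value = 1, n = n, n_events = NA_integer_,
                 excluded = excluded, flags = "constant covariate", fit = NULL),
            class = "oralhsct_hazard_fit")
}

#' @export
print.oralhsct_hazard_fit <- function(x, ...) {
  cat(sprintf("%s fit for '%s': HR = %.3g (95%% CI %.3g-%.3g), p = %.3g (n = %s, events = %s)\n",
              x$model, x$covariate, x$hr, x$conf.low, x$conf.high, x$p.value,
              x$n, x$n_events))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.oralhsct_hazard_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = x$covariate, estimate = x$estimate, std.error = x$se,
                  hr = x$hr, conf.low = x$conf.low, conf.high = x$conf.high,
                  p.value = x$p.value))
  }
  sm <- summary(x$fit)
  co <- sm$coefficients
  tibble(term = rownames(co), estimate = co[, "coef"],
         std.error = co[, "se(coef)"], hr = exp(co[, "coef"]),
         conf.low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
         conf.high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
         p.value = co[, "Pr(>|z|)"])
}

#' @export
glance.oralhsct_hazard_fit <- function(x, ...) {
  tibble(model = x$model, covariate = x$covariate, n = x$n,
         n.events = x$n_events, n.excluded = length(x$excluded),
         flagged = length(x$flags) > 0)
}

check_monotone <- function(fit) {
  if (any(abs(stats::coef(fit)) > 15)) "monotone likelihood (possible complete separation)"
  else character(0)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) of a single covariate on the
#' time to event, after landmark exclusion of patients whose follow-up
#' ended before their E30 evaluation day (`e30_day` column, when present).
#' By default any death (event codes 1 and 2) counts as the event, i.e. an
#' overall-survival analysis; pass `event_of_interest = 1` to censor
#' competing events instead.
#'
#' @param records Outcome tibble (see [read_outcomes()]), optionally with an
#'   `e30_day` landmark column, plus the covariate column.
#' @param covariate Name of the covariate column.
#' @param event_of_interest Event codes counted as events (default `c(1, 2)`).
#' @return An object of class `oralhsct_hazard_fit`; see [tidy()] /
#'   [glance()] methods.
#' @export
cox_univariate <- function(records, covariate, event_of_interest = c(1, 2)) {
  records <- validate_outcomes(records)
  lm <- apply_landmark(records)
  df <- lm$records
  df$.status <- as.integer(df$event %in% event_of_interest)
  if (length(unique(df[[covariate]])) < 2) {
    return(constant_covariate_fit("Cox", covariate, nrow(df), lm$excluded))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, .status) ~", covariate))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  new_hazard_fit(fit, "Cox", covariate, df, lm$excluded, check_monotone(fit))
}

#' Univariate Fine-Gray subdistribution-hazard fit
#'
#' Competing-risks regression on the subdistribution hazard of the event of
#' interest: subjects experiencing the competing event remain in the risk
#' set with inverse-probability-of-censoring weights
#' `w_i(t) = G(t) / G(min(T_i, t))` (`G` the Kaplan-Meier estimate of the
#' censoring distribution), and the weighted partial likelihood is
#' maximized as in Cox. Implemented through [survival::finegray()] followed
#' by a weighted [survival::coxph()]; with no competing events present the
#' expanded data collapse to the original records and the fit equals
#' [cox_univariate()] exactly. The same landmark exclusion applies.
#'
#' @inheritParams cox_univariate
#' @param event_of_interest The event code modelled (default 1); the other
#'   non-zero code is the competing event.
#' @return An object of class `oralhsct_hazard_fit`.
#' @export
finegray_univariate <- function(records, covariate, event_of_interest = 1) {
  records <- validate_outcomes(records)
  lm <- apply_landmark(records)
  df <- lm$records
  if (all(df$event == 0)) {
    return(constant_covariate_fit("Fine-Gray", covariate, nrow(df), lm$excluded) |>
             (\(x) { x$flags <- "no events (all censored)"; x })())
  }
  lv <- c("censor", "interest", "competing")
  df$.etype <- factor(ifelse(df$event == 0, "censor",
                             ifelse(df$event == event_of_interest, "interest", "competing")),
                      levels = lv)
  if (length(unique(df[[covariate]])) < 2) {
    return(constant_covariate_fit("Fine-Gray", covariate, nrow(df), lm$excluded))
  }
  fg <- survival::finegray(survival::Surv(time, .etype) ~ ., data = df,
                           etype = "interest")
  fml <- stats::as.formula(
    paste("survival::Surv(fgstart, fgstop, fgstatus) ~", covariate))
  fit <- survival::coxph(fml, data = fg, weights = fg$fgwt, ties = "efron")
  new_hazard_fit(fit, "Fine-Gray", covariate, fg, lm$excluded, check_monotone(fit))
}

#' Multivariate adjustment of the recovery-outcome association
#'
#' Selects, among candidate clinical confounders, those with univariate
#' p < `select_p` for the outcome, then fits a joint model (Cox or
#' Fine-Gray) of the primary covariate plus the selected confounders and
#' reports the primary covariate's adjusted hazard ratio. With no selected
#' confounder the fit equals the univariate one. Collinear covariates
#' (aliased coefficients) are flagged.
#'
#' @inheritParams cox_univariate
#' @param primary Name of the covariate of interest (e.g. recovery status).
#' @param confounders Candidate confounder column names.
#' @param model `"cox"` or `"finegray"`.
#' @param select_p Univariate selection threshold (default 0.05; 1 enters
#'   all candidates).
#' @return A list with `fit` (the adjusted `oralhsct_hazard_fit` for
#'   `primary`), `selected` (confounders entering the model), and
#'   `univariate` (tibble of the candidate screens).
#' @export
multivariate_adjust <- function(records, primary, confounders,
                                model = c("cox", "finegray"),
                                select_p = 0.05, event_of_interest = NULL) {
  model <- match.arg(model)
  eoi <- event_of_interest %||% if (model == "cox") c(1, 2) else 1
  uni_fun <- if (model == "cox") {
    function(v) cox_univariate(records, v, event_of_interest = eoi)
  } else {
    function(v) finegray_univariate(records, v, event_of_interest = eoi)
  }
  screens <- purrr::map_dfr(confounders, function(v) {
    f <- uni_fun(v)
    tibble(term = v, p.value = f$p.value)
  })
  selected <- screens$term[screens$p.value < select_p]
  records <- validate_outcomes(records)
  lm <- apply_landmark(records)
  df <- lm$records
  terms <- c(primary, selected)
  if (model == "cox") {
    df$.status <- as.integer(df$event %in% eoi)
    fml <- stats::as.formula(paste("survival::Surv(time, .status) ~",
                                   paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
  } else {
    df$.etype <- factor(ifelse(df$event == 0, "censor",
                               ifelse(df$event == eoi[1], "interest", "competing")),
                        levels = c("censor", "interest", "competing"))
    fg <- survival::finegray(survival::Surv(time, .etype) ~ ., data = df,
                             etype = "interest")
    fml <- stats::as.formula(paste("survival::Surv(fgstart, fgstop, fgstatus) ~",
                                   paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = fg, weights = fg$fgwt, ties = "efron")
  }
  flags <- character(0)
  if (any(is.na(stats::coef(fit)))) flags <- "collinear covariates (aliased coefficients)"
  out <- new_hazard_fit(fit, if (model == "cox") "Cox" else "Fine-Gray",
                        primary, df, lm$excluded, c(flags, check_monotone(fit)))
  list(fit = out, selected = selected, univariate = screens)
}

#' Kaplan-Meier survival and cumulative-incidence curves
#'
#' Product-limit survival estimate for the all-cause event, and
#' Aalen-Johansen cumulative incidence per competing cause, stratified by a
#' grouping variable. The per-cause incidences sum to one minus the
#' all-cause (event-free) Kaplan-Meier at every time.
#'
#' @param records Outcome tibble with `time` and `event` (0/1/2).
#' @param group Name of the grouping column (optional).
#' @return A list of class `oralhsct_curves` with `km` (tibble: `group`,
#'   `time`, `estimate`, `n.risk`, `n.event`) and `cif` (tibble: `group`,
#'   `cause`, `time`, `estimate`).
#' @export
km_and_cif <- function(records, group = NULL) {
  records <- validate_outcomes(records)
  df <- as.data.frame(records)
  df$.grp <- if (is.null(group)) "all" else as.character(df[[group]])
  km_fit <- survival::survfit(survival::Surv(time, event > 0) ~ .grp, data = df)
  km <- survfit_tibble(km_fit)
  if (all(df$event == 0)) {
    return(structure(list(
      km = km,
      cif = tibble(group = character(), cause = character(),
                   time = numeric(), estimate = numeric())),
      class = "oralhsct_curves"))
  }
  df$.etype <- factor(ifelse(df$event == 0, "censor",
                             ifelse(df$event == 1, "interest", "competing")),
                      levels = c("censor", "interest", "competing"))
  cif_fit <- survival::survfit(survival::Surv(time, .etype) ~ .grp, data = df)
  states <- cif_fit$states
  strata_names <- if (is.null(cif_fit$strata)) "all" else
    sub("^\\.grp=", "", names(cif_fit$strata))
  reps <- if (is.null(cif_fit$strata)) length(cif_fit$time) else cif_fit$strata
  grp_vec <- rep(strata_names, reps)
  prev <- cif_fit$pstate
  cif <- purrr::map_dfr(which(states != "(s0)"), function(j) {
    tibble(group = grp_vec, cause = states[j], time = cif_fit$time,
           estimate = prev[, j])
  })
  structure(list(km = km, cif = cif), class = "oralhsct_curves")
}

survfit_tibble <- function(fit) {
  strata_names <- if (is.null(fit$strata)) "all" else
    sub("^\\.grp=", "", names(fit$strata))
  reps <- if (is.null(fit$strata)) length(fit$time) else fit$strata
  tibble(group = rep(strata_names, reps), time = fit$time,
         estimate = fit$surv, n.risk = fit$n.risk, n.event = fit$n.event)
}

#' @export
autoplot.oralhsct_curves <- function(object, which = c("km", "cif"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    ggplot2::ggplot(object$km,
                    ggplot2::aes(x = .data$time, y = .data$estimate,
                                 colour = .data$group)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "days", y = "survival") +
      ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$cif,
                    ggplot2::aes(x = .data$time, y = .data$estimate,
                                 colour = .data$group,
                                 linetype = .data$cause)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "days", y = "cumulative incidence") +
      ggplot2::theme_minimal()
  }
}
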