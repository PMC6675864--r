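#' Percent of time spent in each vigilance state
#'
#' Fraction of epochs in each state within the analysis window
#' `[treatment_epoch, treatment_epoch + window_epochs)`, times 100.
#' Percentages always sum to 100. With `rems_split = TRUE` the window is
#' segmented into bouts, REMS bouts are reclassified with
#' [reclassify_rems()], and REMS time is reported separately for `REMS_S`
#' and `REMS_L`; otherwise REMS is reported combined.
#'
#' @param h A [hypnogram].
#' @param window_epochs Window length in epochs (default 2700 = 3 h at 4-s
#'   epochs).
#' @param rems_split Report REMS split by bout duration?
#' @param rems_cutoff_epochs Cutoff for the split (default 4).
#' @return Named numeric vector of percentages over [RAW_STATES] (or
#'   [SPLIT_STATES] when splitting), zeros included.
#' @export
percent_time <- function(h, window_epochs = 2700L, rems_split = FALSE,
                         rems_cutoff_epochs = 4L) {
  validate_hypnogram(h)
  from <- h$treatment_epoch
  if (from + window_epochs > length(h$states)) {
    stop("analysis window exceeds the recording")
  }
  states <- h$states[seq.int(from + 1L, from + window_epochs)]
  if (rems_split) {
    sub <- hypnogram(h$subject_id, h$treatment, states,
                     epoch_seconds = h$epoch_seconds)
    bouts <- reclassify_rems(segment_bouts(sub), rems_cutoff_epochs)
    states <- rep(bouts$state, bouts$n_epochs)
    lev <- SPLIT_STATES
  } else {
    lev <- if (any(states %in% c("REMS_S", "REMS_L"))) SPLIT_STATES else RAW_STATES
  }
  counts <- table(factor(states, levels = lev))
  stats::setNames(100 * as.vector(counts) / window_epochs, lev)
}

#' Tabulate bout counts by subject, treatment, state, and time bin
#'
#' Produces an exhaustive, zero-filled count table: every
#' `(subject_id, treatment)` pair present in the input gets one row for
#' every state-by-bin combination, with count 0 where no bout occurred.
#' Bouts outside the observation window (bin `NA`) are excluded, so the
#' table total equals the number of in-window bouts.
#'
#' @param bouts Study bout data frame from [study_bouts()] (reclassified and
#'   binned).
#' @param states State levels to tabulate (default [SPLIT_STATES]).
#' @param n_bins Number of time bins (default 3).
#' @return Data frame with columns `subject_id`, `treatment`, `state`,
#'   `bin`, `count`.
#' @export
count_bouts <- function(bouts, states = SPLIT_STATES, n_bins = 3L) {
  stopifnot(is.data.frame(bouts), "bin" %in% names(bouts))
  inw <- bouts[!is.na(bouts$bin), , drop = FALSE]
  pairs <- unique(bouts[, c("subject_id", "treatment")])
  grid <- merge(pairs,
                expand.grid(state = states, bin = seq.int(0L, n_bins - 1L),
                            stringsAsFactors = FALSE),
                by = NULL)
  agg <- stats::aggregate(list(count = rep(1L, nrow(inw))),
                          inw[, c("subject_id", "treatment", "state", "bin")],
                          FUN = sum)
  out <- merge(grid, agg,
               by = c("subject_id", "treatment", "state", "bin"),
               all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  out$count <- as.integer(out$count)
  out <- out[order(out$subject_id, out$treatment,
                   match(out$state, states), out$bin), ]
  rownames(out) <- NULL
  out
}

#' Bout-frequency ratios versus vehicle from negative binomial regression
#'
#' For one vigilance state, fits a log-link negative binomial model of bout
#' counts with treatment and time bin as unordered categorical fixed effects
#' and subject as a fixed blocking effect. The exponentiated treatment
#' coefficients are the multiplicative bout-frequency ratios of each dose
#' relative to vehicle, reported with 95% Wald confidence intervals. If the
#' negative binomial dispersion estimate diverges (no overdispersion), the
#' fit falls back to a Poisson model with a warning. A dose whose counts are
#' all zero is flagged "not estimable" instead of fitted, since its
#' coefficient lies on the boundary of the parameter space.
#'
#' @param counts Count table from [count_bouts()].
#' @param state The state to analyse.
#' @param vehicle Label of the reference (vehicle) treatment.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame with one row per non-vehicle dose: `state`, `dose`,
#'   `ratio`, `ci_low`, `ci_high`, `n_obs`, `estimable`, `model`
#'   (`"negbin"` or `"poisson"`). Non-estimable doses carry `NA` estimates.
#' @export
estimate_frequency_ratios <- function(counts, state, vehicle = "VEH",
                                      conf_level = 0.95) {
  stopifnot(is.data.frame(counts))
  d <- counts[counts$state == state, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no rows for state %s", state))
  trts <- unique(d$treatment)
  if (!(vehicle %in% trts) || length(trts) < 2L) {
    stop("need at least two treatment levels including the vehicle")
  }
  if (sum(d$count) == 0L) stop(sprintf("all counts zero for state %s", state))
  doses <- setdiff(trts, vehicle)
  zero_dose <- doses[vapply(doses, function(t)
    sum(d$count[d$treatment == t]) == 0L, logical(1))]
  keep <- d$treatment %in% c(vehicle, setdiff(doses, zero_dose))
  dd <- d[keep, , drop = FALSE]
  dd$treatment <- stats::relevel(factor(dd$treatment), ref = vehicle)
  dd$bin <- factor(dd$bin)
  dd$subject_id <- factor(dd$subject_id)
  model_type <- "negbin"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ treatment + bin + subject_id,
                                  data = dd)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("negative binomial dispersion not identifiable; using Poisson")
    model_type <- "poisson"
    fit <- stats::glm(count ~ treatment + bin + subject_id,
                      family = stats::poisson(), data = dd)
  }
  cf <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- lapply(doses, function(dose) {
    if (dose %in% zero_dose) {
      return(data.frame(state = state, dose = dose, ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_obs = sum(d$treatment %in% c(vehicle, dose)),
                        estimable = FALSE, model = model_type,
                        stringsAsFactors = FALSE))
    }
    term <- paste0("treatment", dose)
    est <- cf[term, "Estimate"]
    se <- cf[term, "Std. Error"]
    data.frame(state = state, dose = dose, ratio = exp(est),
               ci_low = exp(est - zq * se), ci_high = exp(est + zq * se),
               n_obs = sum(dd$treatment %in% c(vehicle, dose)),
               estimable = TRUE, model = model_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Linear model for log bout durations with time-by-treatment interaction
#'
#' Bout-duration distributions are heavily right-skewed, so durations are
#' log-transformed before fitting a linear model with treatment, time bin,
#' and their interaction as categorical terms, plus subject as a fixed
#' blocking effect. The interaction is tested by the F-ratio of residual
#' mean squares of the nested models with and without the interaction.
#' Cell-wise predicted mean log-durations with confidence intervals
#' (averaged over subjects) are returned; back-transform with `exp()` for
#' durations in seconds.
#'
#' @param bouts Study bout data frame (binned; rows with bin `NA` are
#'   dropped).
#' @param state The state to analyse.
#' @param conf_level Confidence level for predicted-mean intervals.
#' @return An object of class `duration_model_fit`: a list with `state`,
#'   `cell_means` (data frame: `treatment`, `bin`, `mean_log`, `ci_low`,
#'   `ci_high`, `n`), `f_statistic`, `df1`, `df2`, `p_value`, and the
#'   underlying `fit`.
#' @export
fit_duration_model <- function(bouts, state, conf_level = 0.95) {
  stopifnot(is.data.frame(bouts), "bin" %in% names(bouts))
  d <- bouts[bouts$state == state & !is.na(bouts$bin), , drop = FALSE]
  if (nrow(d) < 4L) stop(sprintf("too few bouts of state %s", state))
  d$log_dur <- log(d$duration_s)
  d$treatment <- factor(d$treatment)
  d$bin <- factor(d$bin)
  d$subject_id <- factor(d$subject_id)
  full <- stats::lm(log_dur ~ treatment * bin + subject_id, data = d)
  null <- stats::lm(log_dur ~ treatment + bin + subject_id, data = d)
  an <- stats::anova(null, full)
  f <- an$F[2]
  # constant responses leave both sums of squares at numerical zero; the
  # F ratio is then 0/0 noise and the interaction is exactly absent
  tss <- sum((d$log_dur - mean(d$log_dur))^2)
  if (is.na(f) || tss < 1e-10 * nrow(d)) f <- 0
  cells <- as.data.frame(emmeans::emmeans(full, ~ treatment * bin,
                                          level = conf_level))
  nn <- stats::aggregate(list(n = rep(1L, nrow(d))),
                         d[, c("treatment", "bin")], FUN = sum)
  cm <- merge(cells, nn, by = c("treatment", "bin"), all.x = TRUE)
  cm$n[is.na(cm$n)] <- 0L
  out <- data.frame(
    treatment = as.character(cm$treatment),
    bin = as.integer(as.character(cm$bin)),
    mean_log = cm$emmean,
    ci_low = cm$lower.CL,
    ci_high = cm$upper.CL,
    n = cm$n,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$treatment, out$bin), ]
  rownames(out) <- NULL
  structure(list(state = state, cell_means = out,
                 f_statistic = f, df1 = an$Df[2], df2 = an$Res.Df[2],
                 p_value = stats::pf(f, an$Df[2], an$Res.Df[2],
                                     lower.tail = FALSE),
                 fit = full),
            class = "duration_model_fit")
}

#' @export
print.duration_model_fit <- function(x, ...) {
  cat(sprintf(
    "log-duration model for %s: interaction F = %.3f (df %d, %d), p = %.4g\n",
    x$state, x$f_statistic, x$df1, x$df2, x$p_value))
  print(x$cell_means)
  invisible(x)
}

#' One-compartment pharmacokinetic decline over an observation period
#'
#' Under first-order elimination, the percent decline of plasma
#' concentration from its initial maximum after `duration_h` hours is
#' `100 * (1 - 2^(-duration_h / half_life_h))`. For a drug with a 22-h
#' half-life observed for 3 h this is about 9.0%, i.e. plasma levels are
#' effectively constant over the observation window.
#'
#' @param half_life_h Elimination half-life in hours (> 0).
#' @param duration_h Observation period in hours (> 0 allowed to be 0).
#' @return Percent decline (0–100).
#' @export
pk_decline_percent <- function(half_life_h, duration_h) {
  if (!is.finite(half_life_h) || half_life_h <= 0) {
    stop("half_life_h must be positive")
  }
  if (!is.finite(duration_h) || duration_h < 0) {
    stop("duration_h must be non-negative")
  }
  100 * (1 - 2^(-duration_h / half_life_h))
}
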