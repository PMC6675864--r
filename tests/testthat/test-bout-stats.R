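test_that("percent_time computes state time budgets that sum to 100", {
  h <- hypnogram("r", "VEH", c(rep("AW", 1350), rep("S2", 1350)))
  p <- percent_time(h)
  expect_equal(p[["AW"]], 50)
  expect_equal(p[["S2"]], 50)
  expect_equal(sum(p[c("PW", "S1", "IS", "REMS")]), 0)

  # all-REMS window, combined reporting
  hr <- hypnogram("r", "VEH", rep("REMS", 100))
  expect_equal(percent_time(hr, window_epochs = 100)[["REMS"]], 100)

  # split reporting conserves REMS time across REMS_S/REMS_L
  hs <- hypnogram("r", "VEH", c(rep("REMS", 3), rep("AW", 5), rep("REMS", 12)))
  ps <- percent_time(hs, window_epochs = 20, rems_split = TRUE)
  expect_equal(ps[["REMS_S"]], 15)
  expect_equal(ps[["REMS_L"]], 60)

  # conservation on random hypnograms
  set.seed(5)
  for (rep in 1:20) {
    h <- random_hypnogram(sample(100:2000, 1))
    w <- sample(50:length(h$states), 1)
    expect_equal(sum(percent_time(h, window_epochs = w)), 100)
    expect_equal(sum(percent_time(h, window_epochs = w, rems_split = TRUE)),
                 100)
  }

  expect_error(percent_time(hypnogram("r", "VEH", rep("AW", 10)),
                            window_epochs = 11), "window")
})

test_that("count_bouts zero-fills the full state-by-bin grid", {
  b <- data.frame(subject_id = "r1", treatment = "VEH",
                  state = c("AW", "PW", "AW"),
                  onset_epoch = c(0L, 2L, 5L), n_epochs = c(2L, 3L, 1L),
                  duration_s = c(8, 12, 4))
  tab <- count_bouts(bin_bouts(b))
  expect_identical(nrow(tab), length(SPLIT_STATES) * 3L)
  get <- function(s, bin) tab$count[tab$state == s & tab$bin == bin]
  expect_identical(get("AW", 0L), 2L)
  expect_identical(get("PW", 0L), 1L)
  # zero-filling: states with no bouts still present, with zeros
  expect_identical(get("IS", 0L), 0L)
  expect_identical(sum(tab$count), 3L)
})

test_that("count_bouts total equals the number of in-window bouts", {
  cfg <- default_sim_config(seed = 123L)
  cfg$n_subjects <- 2L
  bouts <- study_bouts(simulate_study(cfg))
  tab <- count_bouts(bouts)
  expect_identical(sum(tab$count), sum(!is.na(bouts$bin)))
  # every (subject, treatment) pair carries the full 7 x 3 grid
  expect_identical(nrow(tab), 2L * 3L * 7L * 3L)
})

make_count_table <- function(counts_by_trt, subjects = 6L, bins = 3L,
                             state = "AW") {
  grid <- expand.grid(subject_id = sprintf("r%d", seq_len(subjects)),
                      treatment = names(counts_by_trt),
                      bin = seq.int(0L, bins - 1L), stringsAsFactors = FALSE)
  grid$state <- state
  grid$count <- unlist(lapply(grid$treatment,
                              function(t) counts_by_trt[[t]]))
  grid
}

test_that("identical counts in dose and vehicle give a ratio of 1", {
  set.seed(2)
  base <- rpois(1, 20) + 5L
  tab <- make_count_table(list(VEH = base, AM10 = base))
  est <- suppressWarnings(estimate_frequency_ratios(tab, "AW"))
  expect_equal(est$ratio, 1, tolerance = 1e-6)
  expect_true(est$ci_low <= 1 && 1 <= est$ci_high)
  expect_true(est$estimable)
})

test_that("a dose with all-zero counts is flagged not estimable", {
  tab <- rbind(make_count_table(list(VEH = 10L, AM5 = 8L)),
               make_count_table(list(AM10 = 0L)))
  est <- suppressWarnings(estimate_frequency_ratios(tab, "AW"))
  am10 <- est[est$dose == "AM10", ]
  expect_false(am10$estimable)
  expect_true(is.na(am10$ratio))
  am5 <- est[est$dose == "AM5", ]
  expect_true(am5$estimable)  # remaining doses still fitted
  expect_error(estimate_frequency_ratios(tab, "REMS_L"), "no rows|zero")
})

test_that("no-effect simulations give ~95% CI coverage of ratio 1", {
  set.seed(31)
  covered <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    subj_eff <- exp(rnorm(6, 0, 0.3))
    bin_eff <- c(1, 1.4, 1.8)
    grid <- expand.grid(subject_id = sprintf("r%d", 1:6),
                        treatment = c("VEH", "AM10"),
                        bin = 0:2, stringsAsFactors = FALSE)
    grid$state <- "AW"
    mu <- 15 * subj_eff[as.integer(sub("r", "", grid$subject_id))] *
      bin_eff[grid$bin + 1]
    grid$count <- rpois(nrow(grid), mu)
    est <- suppressWarnings(estimate_frequency_ratios(grid, "AW"))
    if (est$ci_low <= 1 && 1 <= est$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.91)
  expect_lte(covered / n_rep, 0.99)
})

test_that("constant durations give flat cell means and no interaction", {
  b <- expand.grid(subject_id = sprintf("r%d", 1:3),
                   treatment = c("VEH", "AM10"), bin = 0:2,
                   rep = 1:3, stringsAsFactors = FALSE)
  b$state <- "PW"
  b$onset_epoch <- seq_len(nrow(b))
  b$n_epochs <- 2L
  b$duration_s <- 8
  fit <- suppressWarnings(fit_duration_model(b, "PW"))  # perfect fit warns
  expect_equal(fit$cell_means$mean_log, rep(log(8), 6), tolerance = 1e-10)
  expect_equal(fit$f_statistic, 0, tolerance = 1e-10)
})

test_that("duration model is equivariant under duration rescaling", {
  set.seed(13)
  b <- expand.grid(subject_id = sprintf("r%d", 1:4),
                   treatment = c("VEH", "AM5", "AM10"), bin = 0:2,
                   rep = 1:6, stringsAsFactors = FALSE)
  b$state <- "AW"
  b$onset_epoch <- seq_len(nrow(b))
  b$n_epochs <- 1L
  b$duration_s <- exp(rnorm(nrow(b), 2, 0.8))
  f1 <- fit_duration_model(b, "AW")
  b2 <- b
  b2$duration_s <- b$duration_s * 7
  f2 <- fit_duration_model(b2, "AW")
  expect_equal(f2$cell_means$mean_log, f1$cell_means$mean_log + log(7))
  expect_equal(f2$f_statistic, f1$f_statistic)
  expect_equal(f2$p_value, f1$p_value)
})

test_that("a shifted dose-by-bin cell is detected by the interaction test", {
  # one cell shifted by factor e: its CI must exclude the grand mean and
  # the interaction should be significant in most seeded replicates
  set.seed(17)
  hits_ci <- 0L
  hits_p <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    b <- expand.grid(subject_id = sprintf("r%d", 1:5),
                     treatment = c("VEH", "AM10"), bin = 0:2,
                     rep = 1:10, stringsAsFactors = FALSE)
    b$state <- "AW"
    b$onset_epoch <- seq_len(nrow(b))
    b$n_epochs <- 1L
    b$duration_s <- exp(rnorm(nrow(b), 2, 0.5))
    shift <- b$treatment == "AM10" & b$bin == 2
    b$duration_s[shift] <- b$duration_s[shift] * exp(1)
    fit <- fit_duration_model(b, "AW")
    gm <- mean(log(b$duration_s))
    cell <- fit$cell_means[fit$cell_means$treatment == "AM10" &
                             fit$cell_means$bin == 2, ]
    if (cell$ci_low > gm) hits_ci <- hits_ci + 1L
    if (fit$p_value < 0.05) hits_p <- hits_p + 1L
  }
  expect_gte(hits_p / n_rep, 0.9)
  expect_gte(hits_ci / n_rep, 0.9)
})

test_that("interaction test keeps its nominal size under the null", {
  set.seed(23)
  p_vals <- replicate(60, {
    b <- expand.grid(subject_id = sprintf("r%d", 1:4),
                     treatment = c("VEH", "AM10"), bin = 0:2,
                     rep = 1:8, stringsAsFactors = FALSE)
    b$state <- "AW"
    b$onset_epoch <- seq_len(nrow(b))
    b$n_epochs <- 1L
    b$duration_s <- exp(rnorm(nrow(b), 2, 0.6))
    fit_duration_model(b, "AW")$p_value
  })
  # approximately uniform: rejection rate near 5%, KS test not rejecting
  expect_lte(mean(p_vals < 0.05), 0.15)
  expect_gt(stats::ks.test(p_vals, "punif")$p.value, 0.01)
})

test_that("one-compartment decline percent follows first-order kinetics", {
  expect_lt(abs(pk_decline_percent(22, 3) - 9.01), 0.05)
  expect_equal(pk_decline_percent(10, 10), 50)  # one half-life
  expect_equal(pk_decline_percent(22, 0), 0)
  expect_error(pk_decline_percent(0, 3), "positive")
  expect_error(pk_decline_percent(22, -1), "non-negative")
})
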