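test_that("cross_tabulate counts bout successions within subjects only", {
  b <- data.frame(subject_id = "r1", treatment = "VEH",
                  state = c("AW", "PW", "AW", "S1"),
                  onset_epoch = c(0L, 2L, 5L, 6L),
                  n_epochs = c(2L, 3L, 1L, 1L),
                  duration_s = c(8, 12, 4, 4))
  t <- cross_tabulate(b, states = RAW_STATES)
  expect_identical(t$O["AW", "PW"], 1L)
  expect_identical(t$O["PW", "AW"], 1L)
  expect_identical(t$O["AW", "S1"], 1L)
  expect_identical(t$N, 3L)
  expect_true(all(diag(t$O) == 0L))

  # no transition across the subject boundary
  b2 <- rbind(b, within(b, subject_id <- "r2"))
  t2 <- cross_tabulate(b2, states = RAW_STATES)
  expect_identical(t2$N, 6L)
  expect_identical(t2$O["S1", "AW"], 0L)

  # a lone bout per subject yields an empty table
  lone <- b[1, ]
  expect_identical(cross_tabulate(lone, states = RAW_STATES)$N, 0L)
})

test_that("transitions straddling a bin boundary go to the successor bin", {
  b <- data.frame(subject_id = "r1", treatment = "VEH",
                  state = c("AW", "PW", "S1"),
                  onset_epoch = c(0L, 880L, 905L),
                  n_epochs = c(880L, 25L, 10L),
                  duration_s = c(3520, 100, 40))
  b <- bin_bouts(b)
  t0 <- cross_tabulate(b, bin = 0L, states = RAW_STATES)
  t1 <- cross_tabulate(b, bin = 1L, states = RAW_STATES)
  expect_identical(t0$O["AW", "PW"], 1L)  # successor onset 880 is in bin 0
  expect_identical(t1$O["PW", "S1"], 1L)  # successor onset 905 is in bin 1
  expect_identical(t0$N, 1L)
  expect_identical(t1$N, 1L)
})

test_that("cross_tabulate matches the pairwise-loop oracle on a simulated study", {
  cfg <- default_sim_config(seed = 77L)
  cfg$n_subjects <- 3L
  bouts <- study_bouts(simulate_study(cfg))
  for (trt in c("VEH", "AM10")) {
    sel <- bouts[bouts$treatment == trt, ]
    for (b in c(list(NULL), 0:2)) {
      got <- cross_tabulate(sel, bin = if (is.null(b)) NULL else b)
      want <- naive_cross_tabulate(sel, SPLIT_STATES,
                                   bin = if (is.null(b)) NULL else b)
      expect_identical(unclass(got$O), unclass(want))
    }
  }
})

test_that("z-statistics reproduce the hand-computed worked example", {
  t <- z_statistics(worked_example_table())
  # E[A,B] = 12*14/30 = 5.6; Z = (10-5.6)/sqrt(5.6)
  expect_equal(t$E["A", "B"], 5.6)
  expect_equal(t$Z["A", "B"], (10 - 5.6) / sqrt(5.6))
  expect_equal(t$Z["A", "B"], 1.859, tolerance = 1e-3)
  expect_equal(t$Z["B", "A"], 2)
  # adjusted denominator sqrt(5.6 * (1 - 12/30) * (1 - 14/30))
  ta <- z_statistics(worked_example_table(), method = "adjusted")
  expect_equal(ta$Z["A", "B"],
               (10 - 5.6) / sqrt(5.6 * (1 - 12 / 30) * (1 - 14 / 30)))
  expect_equal(ta$Z["A", "B"], 3.29, tolerance = 1e-2)
  # a cell where O equals E has z exactly 0: E[C,A] = 6*10/30 = 2 = O[C,A]
  expect_equal(t$E["C", "A"], t$O["C", "A"])
  expect_equal(t$Z["C", "A"], 0)
  expect_error(z_statistics(transition_table(matrix(0L, 2, 2,
    dimnames = list(c("A", "B"), c("A", "B"))))), "empty")
})

test_that("vectorized z equals the scalar oracle and conserves marginals", {
  set.seed(101)
  for (rep in 1:100) {
    K <- sample(2:7, 1)
    O <- random_zero_diag_table(K)
    if (sum(O) == 0) next
    for (m in c("pearson", "adjusted")) {
      t <- z_statistics(transition_table(O), method = m)
      expect_equal(unname(t$Z), naive_z(O, m), tolerance = 1e-12)
    }
    t <- z_statistics(transition_table(O))
    expect_equal(sum(t$O), t$N)
    expect_equal(sum(t$E), t$N)
    expect_equal(unname(rowSums(t$E)), unname(t$R))
    expect_equal(unname(colSums(t$E)), unname(t$C))
    expect_equal(sum(t$p_obs), 1)
  }
})

test_that("probability-scale residuals are count residuals over sqrt(N)", {
  t <- worked_example_table()
  tc <- z_statistics(t, scale = "counts")
  tp <- z_statistics(t, scale = "probabilities")
  expect_equal(tp$Z, tc$Z / sqrt(tc$N))
})

test_that("masking removes the diagonal and low-count cells", {
  t <- apply_mask(z_statistics(worked_example_table()), min_count = 5)
  expect_identical(sum(!t$mask), 2L)  # only A->B (10) and B->A (8) survive
  expect_false(t$mask["A", "B"] || t$mask["B", "A"])
  expect_true(all(is.na(t$Z[t$mask])))

  # min_count 0: only the structural diagonal is masked
  t0 <- apply_mask(worked_example_table(), min_count = 0)
  expect_identical(sum(t0$mask), 3L)
  expect_true(all(diag(t0$mask)))

  # all-zero off-diagonal table: everything masked
  O <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_true(all(apply_mask(transition_table(O))$mask))
})

test_that("exported CSV round-trips z values at full precision", {
  t <- apply_mask(z_statistics(worked_example_table()))
  csv <- withr::local_tempfile(fileext = ".csv")
  heatmap_export(t, csv)
  back <- utils::read.csv(csv)
  d <- as.data.frame(t)
  expect_identical(back$z, d$z)
  expect_identical(back$observed, d$observed)
  expect_identical(back$masked, d$masked)
})

test_that("heatmaps render with masked tiles and a shared grid scale", {
  t <- apply_mask(z_statistics(worked_example_table()))
  p <- transition_heatmap(t)
  expect_s3_class(p, "ggplot")

  # fully masked table still renders (all tiles gray)
  O <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tm <- apply_mask(transition_table(O))
  expect_s3_class(transition_heatmap(tm), "ggplot")

  cfg <- default_sim_config(seed = 5L)
  cfg$n_subjects <- 2L
  bouts <- study_bouts(simulate_study(cfg))
  g <- heatmap_grid(bouts)
  expect_length(g$tables, 9L)
  expect_s3_class(g$plot, "ggplot")
  zmax <- max(vapply(g$tables, function(t)
    if (all(is.na(t$Z))) -Inf else max(abs(t$Z), na.rm = TRUE), numeric(1)))
  expect_equal(g$zlim, max(zmax, 2))
})

test_that("the +/-2 rule stays near nominal at panel-scale table sizes", {
  # a pooled 6-subject hourly panel carries a few hundred transitions;
  # at that size the structural-zero distortion of the independence
  # expectation is modest and unmasked |z| > 2 stays near its nominal rate
  set.seed(303)
  p <- c(0.25, 0.20, 0.20, 0.15, 0.10, 0.10)
  q <- c(0.15, 0.25, 0.15, 0.20, 0.15, 0.10)
  exceed <- 0L
  cells <- 0L
  for (rep in 1:200) {
    t <- apply_mask(z_statistics(simulate_null_table(300, p, q)),
                    min_count = 5)
    z <- t$Z[!t$mask]
    exceed <- exceed + sum(abs(z) > 2, na.rm = TRUE)
    cells <- cells + sum(!is.na(z))
  }
  prop <- exceed / cells
  expect_gte(prop, 0.02)
  expect_lte(prop, 0.12)
})
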