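cfg <- analysis_config()

test_that("the Lilliefors statistic matches the reference implementation", {
  withr::local_seed(12)
  x <- rexp(60)
  got <- lilliefors_test(x, n_mc = 2000, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  # both should firmly reject normality of exponential data
  expect_lt(got$p, 0.01)
  expect_lt(ref$p.value, 0.01)
  # and agree that Gaussian data look Gaussian
  y <- rnorm(60)
  expect_gt(lilliefors_test(y, n_mc = 1000, seed = 2)$p, 0.05)
})

test_that("degenerate normality-test inputs are rejected", {
  expect_error(lilliefors_test(rep(3, 10)),
               class = "polspike_degenerate_error")
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
})

test_that("noiseless linear data are recovered exactly with the linear model kept", {
  ladder <- c(0.99, 0.35, 0.1, 0.05, 0.002)
  df <- data.frame(neuron_id = rep(paste0("n", 1:4), each = 5),
                   cell_type = "TL2", dop = rep(ladder, 4))
  df$A <- 3 + 20 * df$dop
  df$r <- 0.5 * df$dop
  df$mean_rate <- 10
  rg <- suppressWarnings(fit_dop_regression(df, "A", "TL2", cfg))
  expect_equal(rg$model_form, "linear_dop")
  expect_equal(rg$slope, 20, tolerance = 1e-9)
  expect_equal(rg$intercept, 3, tolerance = 1e-9)
  expect_equal(rg$r_squared, 1, tolerance = 1e-9)
})

test_that("only neurons tested at three or more DoPs enter the regression", {
  df <- data.frame(neuron_id = c(rep("a", 5), rep("b", 2)),
                   cell_type = "TL2",
                   dop = c(0.99, 0.35, 0.1, 0.05, 0.002, 0.99, 0.35))
  df$A <- 1 + df$dop; df$r <- df$dop; df$mean_rate <- 1
  rg <- suppressWarnings(fit_dop_regression(df, "A", "TL2", cfg))
  expect_equal(rg$neurons_used, "a")
  expect_equal(rg$n_points, 5L)
  # nobody eligible -> empty result with a reason
  rg0 <- fit_dop_regression(df[df$neuron_id == "b", ], "A", "TL2", cfg)
  expect_true(is.na(rg0$slope))
  expect_match(rg0$reason, "3 DoPs")
})

test_that("regression slope is equivariant under rescaling of the response", {
  withr::local_seed(40)
  ladder <- c(0.99, 0.35, 0.1, 0.05, 0.002)
  df <- data.frame(neuron_id = rep(paste0("n", 1:10), each = 5),
                   cell_type = "TB1", dop = rep(ladder, 10))
  df$A <- 3 + 20 * df$dop + rnorm(50, 0, 0.5)
  df$r <- df$dop; df$mean_rate <- 1
  cfg_fixed <- analysis_config(rng_seed = 5)
  r1 <- fit_dop_regression(df, "A", "TB1", cfg_fixed)
  df2 <- df; df2$A <- 7 * df$A + 2
  r2 <- fit_dop_regression(df2, "A", "TB1", cfg_fixed)
  expect_equal(r2$slope, 7 * r1$slope, tolerance = 1e-9)
  expect_equal(r2$model_form, r1$model_form)
  expect_equal(r2$r_squared, r1$r_squared, tolerance = 1e-9)
})

test_that("significance tallies count responses per cell type and DoP", {
  df <- data.frame(neuron_id = rep(c("a", "b", "c"), each = 2),
                   cell_type = rep(c("TL2", "TL2", "TB1"), each = 2),
                   dop = rep(c(0.99, 0.1), 3),
                   significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  tal <- significance_tally(df, cfg)
  row <- tal[tal$cell_type == "TL2" & tal$dop == 0.1, ]
  expect_equal(row$n_significant, 1L)
  expect_equal(row$n_tested, 2L)
  expect_equal(nrow(significance_tally(df[0, ], cfg)), 0L)
  # an all-significant cohort tallies full everywhere
  df$significant <- TRUE
  tal2 <- significance_tally(df, cfg)
  expect_true(all(tal2$n_significant == tal2$n_tested))
})

test_that("the no-stimulus confidence limit matches the t closed form", {
  lim <- nostim_confidence_limit(c(0.1, 0.2, 0.3), cfg)
  expect_equal(lim$mean, 0.2)
  expect_equal(lim$upper, 0.2 + qt(0.975, 2) * 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(lim$upper, 0.4484, tolerance = 1e-3)
  # zero-variance controls collapse the interval
  lim0 <- nostim_confidence_limit(rep(0.07, 5), cfg)
  expect_equal(lim0$upper, 0.07)
  expect_error(nostim_confidence_limit(c(0.1, 0.2), cfg),
               class = "polspike_insufficient_controls")
})

test_that("the t-interval for the mean null r has close to nominal coverage", {
  withr::local_seed(88)
  n_angles <- 200
  true_mean <- mean(vapply(1:4000, function(i)
    axial_mean(runif(n_angles) * 360)$r, 0))
  hits <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    ctl <- vapply(1:10, function(j) axial_mean(runif(n_angles) * 360)$r, 0)
    lim <- nostim_confidence_limit(ctl, cfg)
    hits <- hits + (true_mean >= lim$lower && true_mean <= lim$upper)
  }
  expect_gt(hits / reps, 0.91)
  expect_lt(hits / reps, 0.985)
})

test_that("the threshold walks the ladder and demands all responses pass", {
  mk <- function(r_by_dop) {
    do.call(rbind, lapply(names(r_by_dop), function(d)
      data.frame(neuron_id = paste0("n", seq_along(r_by_dop[[d]])),
                 cell_type = "TL2", dop = as.numeric(d),
                 r = r_by_dop[[d]], A = r_by_dop[[d]] * 100,
                 significant = TRUE, mean_rate = 10)))
  }
  controls <- c(0.05, 0.06, 0.07, 0.05, 0.06)   # upper limit ~0.069
  # passing down to 0.1, one failure at 0.05
  df <- mk(list(`0.99` = c(0.5, 0.4), `0.35` = c(0.3, 0.35),
                `0.1` = c(0.2, 0.25), `0.05` = c(0.21, 0.04)))
  th <- estimate_threshold(df, controls, "TL2", "r", cfg)
  expect_equal(th$threshold_dop, 0.1)
  expect_equal(th$per_dop_pass$n_above[th$per_dop_pass$dop == 0.05], 1L)
  # invariant: at and above the threshold every response is above the limit
  above <- th$per_dop_pass[th$per_dop_pass$dop >= th$threshold_dop, ]
  expect_true(all(above$n_above == above$n_total))

  # all responses below the limit at every DoP -> no threshold
  df_low <- mk(list(`0.99` = c(0.01, 0.02), `0.35` = c(0.01, 0.03)))
  expect_true(is.na(estimate_threshold(df_low, controls, "TL2", "r",
                                       cfg)$threshold_dop))

  # a single neuron always above passes down to the lowest DoP tested
  df_one <- mk(list(`0.99` = 0.5, `0.35` = 0.4, `0.1` = 0.3, `0.05` = 0.2,
                    `0.002` = 0.15))
  expect_equal(estimate_threshold(df_one, controls, "TL2", "r",
                                  cfg)$threshold_dop, 0.002)

  # an outlier at a higher DoP voids all lower candidates
  df_out <- mk(list(`0.99` = c(0.5, 0.5), `0.35` = c(0.3, 0.01),
                    `0.1` = c(0.3, 0.3)))
  expect_equal(estimate_threshold(df_out, controls, "TL2", "r",
                                  cfg)$threshold_dop, 0.99)
})

test_that("raising the control limit never lowers the threshold", {
  withr::local_seed(91)
  ladder <- c(0.99, 0.35, 0.1, 0.05, 0.002)
  for (i in 1:25) {
    df <- data.frame(neuron_id = rep(paste0("n", 1:3), times = 5),
                     cell_type = "TL2",
                     dop = rep(ladder, each = 3),
                     r = runif(15, 0, 0.4))
    df$A <- df$r; df$significant <- TRUE; df$mean_rate <- 1
    c1 <- runif(5, 0, 0.1)
    t1 <- estimate_threshold(df, c1, "TL2", "r", cfg)$threshold_dop
    t2 <- estimate_threshold(df, c1 + 0.05, "TL2", "r", cfg)$threshold_dop
    if (is.na(t1)) expect_true(is.na(t2))
    else if (!is.na(t2)) expect_gte(t2, t1)
  }
})
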