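test_that("normality screening has power against heavy tails and calibrates on normals", {
  set.seed(101)
  flagged <- replicate(100, {
    any(normality_check(stats::rlnorm(20, 0, 2))$p_value < 0.05, na.rm = TRUE)
  })
  expect_gte(mean(flagged), 0.90)
  set.seed(102)
  big <- normality_check(rnorm(5000))
  expect_true(all(big$p_value > 0.05))
  expect_error(normality_check(rnorm(3)), "n >= 4")
  expect_warning(p <- normality_check(rep(1, 10)), "constant")
  expect_true(all(p$p_value < 0.05))
})

test_that("Friedman test behaves at the extremes", {
  tbl <- null_sweep_table(n_rec = 20)
  tbl$value <- 1                                   # identical everywhere
  fr <- friedman_across_rates(tbl, "p1")
  expect_equal(fr$p_value, 1)
  expect_equal(fr$statistic, 0)

  set.seed(7)
  tbl2 <- null_sweep_table(n_rec = 20)
  tbl2$value[tbl2$fps == 8000] <- tbl2$value[tbl2$fps == 8000] + 10
  expect_lt(friedman_across_rates(tbl2, "p1")$p_value, 0.001)

  expect_error(
    friedman_across_rates(null_sweep_table(n_rec = 1), "p1"),
    "2 complete"
  )
})

test_that("Friedman p-values are uniform under the i.i.d. null", {
  set.seed(202)
  ps <- replicate(200, {
    friedman_across_rates(null_sweep_table(n_rec = 20), "p1")$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pairwise Wilcoxon runs all rate pairs at the corrected level", {
  set.seed(9)
  tbl <- null_sweep_table(n_rec = 20)
  pw <- pairwise_wilcoxon(tbl, "p1", alpha_family = 0.05)
  expect_equal(pw$alpha_corrected, 0.05 / 14)
  expect_equal(pw$alpha_corrected, 0.0036, tolerance = 0.01)
  expect_equal(sum(!is.na(pw$p[upper.tri(pw$p)])), choose(15, 2))  # 105 tests
  expect_true(isSymmetric(pw$p))
  expect_identical(pw$significant, t(pw$significant))
  expect_false(any(diag(pw$significant)))
})

test_that("identical paired samples are never significant", {
  tbl <- null_sweep_table(n_rec = 10, rates = c(1000, 2000, 3000))
  tbl <- dplyr::group_by(tbl, fps) |>
    dplyr::mutate(value = dplyr::row_number()) |>   # same values at each rate
    dplyr::ungroup()
  pw <- pairwise_wilcoxon(tbl, "p1")
  expect_false(any(pw$significant))
})

test_that("interval merging follows the greedy rule", {
  rates <- seq(1000, 15000, 1000)
  none <- merge_stable_intervals(sig_matrix(15), rates)
  expect_equal(nrow(none), 1)
  expect_equal(c(none$start_rate, none$end_rate), c(1000, 15000))

  all_pairs <- sig_matrix(15, lapply(asplit(utils::combn(15, 2), 2), identity))
  singles <- merge_stable_intervals(all_pairs, rates)
  expect_equal(nrow(singles), 15)
  expect_true(all(singles$n_rates == 1))

  # significant only when one rate is below 8 kfps: {1}..{7}, {8..15}
  low <- utils::combn(15, 2)
  keep <- low[, low[1, ] <= 7]
  m <- sig_matrix(15, lapply(asplit(keep, 2), identity))
  iv <- merge_stable_intervals(m, rates)
  expect_equal(nrow(iv), 8)
  expect_equal(iv$start_rate, c(seq(1000, 7000, 1000), 8000))
  expect_equal(iv$end_rate[8], 15000)
  expect_equal(sum(iv$n_rates), 15)
})

test_that("gray bridges are flagged between differing plateaus", {
  m <- sig_matrix(5, list(c(1, 3), c(1, 5), c(3, 5)))
  iv <- merge_stable_intervals(m, 1:5)
  expect_equal(iv$n_rates, c(2, 2, 1))
  expect_equal(iv$gray, c(FALSE, TRUE, FALSE))
})

test_that("group classification matches the four-group taxonomy", {
  rates <- seq(1000, 15000, 1000)
  full <- merge_stable_intervals(sig_matrix(15), rates)
  expect_equal(classify_group(full, 15), 1L)

  iv2 <- tibble::tibble(start_rate = c(1000, 2000, 8000),
                        end_rate = c(1000, 7000, 15000),
                        n_rates = c(1, 6, 8), gray = FALSE)
  expect_equal(classify_group(iv2, 15), 2L)

  iv3 <- tibble::tibble(start_rate = c(1000, 8000, 15000),
                        end_rate = c(7000, 14000, 15000),
                        n_rates = c(7, 7, 1), gray = FALSE)
  expect_equal(classify_group(iv3, 15), 3L)

  # a final stable pair (14-15 kfps) is too short to leave group 4
  iv4 <- tibble::tibble(
    start_rate = c(seq(1000, 13000, 1000), 14000),
    end_rate = c(seq(1000, 13000, 1000), 15000),
    n_rates = c(rep(1, 13), 2), gray = FALSE
  )
  expect_equal(classify_group(iv4, 15), 4L)

  expect_error(classify_group(iv4[-1, ], 15), "cover")
})

test_that("adding a significant pair only tightens the greedy partition", {
  # Adding constraints can re-cut a run so that a *later* run extends
  # further, but it can never grow the leading interval nor reduce the
  # number of intervals.
  set.seed(55)
  rates <- 1:10
  for (i in 1:20) {
    base_pairs <- utils::combn(10, 2)[, sample(45, 8)]
    m0 <- sig_matrix(10, lapply(asplit(base_pairs, 2), identity))
    iv0 <- merge_stable_intervals(m0, rates)
    extra <- utils::combn(10, 2)[, sample(45, 1)]
    m1 <- m0
    m1[extra[1], extra[2]] <- m1[extra[2], extra[1]] <- TRUE
    iv1 <- merge_stable_intervals(m1, rates)
    expect_lte(iv1$end_rate[1], iv0$end_rate[1])
    expect_gte(nrow(iv1), nrow(iv0))
    expect_equal(sum(iv1$n_rates), 10)          # still a partition
  }
})

test_that("the report gates pairwise testing on Friedman significance", {
  set.seed(13)
  tbl <- null_sweep_table(n_rec = 20, params = c("flat", "shifted"))
  tbl$value[tbl$parameter == "flat"] <- 1
  sel <- tbl$parameter == "shifted" & tbl$fps <= 4000
  tbl$value[sel] <- tbl$value[sel] + 8
  rep <- build_stability_report(tbl)
  expect_equal(rep$parameters$flat$group, 1L)
  expect_true(all(is.na(rep$parameters$flat$pairwise$p)))
  expect_gte(rep$parameters$shifted$group, 2L)
  expect_true(any(rep$parameters$shifted$pairwise$significant))
  expect_equal(rep$alpha_corrected, 0.05 / 14)

  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_true(all(c("parameter", "friedman_p", "group", "stable_from") %in%
                    names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_parameters, 2)
  expect_equal(gl$n_group1 + gl$n_group2 + gl$n_group3 + gl$n_group4, 2)
  expect_error(build_stability_report(tbl[0, ]), "empty")
})

test_that("stability report serializes to JSON and CSV", {
  set.seed(3)
  tbl <- null_sweep_table(n_rec = 8, rates = seq(1000, 5000, 1000),
                          params = c("a", "b"))
  rep <- build_stability_report(tbl)
  js <- file.path(tempdir(), "report.json")
  cs <- file.path(tempdir(), "report.csv")
  write_stability_report(rep, js)
  write_stability_report(rep, cs)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(length(j$parameters$parameter), 2)
  flat <- readr::read_csv(cs, show_col_types = FALSE)
  expect_equal(nrow(flat), 2)
  unlink(c(js, cs))
})

test_that("report plots and printers produce their objects", {
  set.seed(4)
  tbl <- null_sweep_table(n_rec = 6, rates = seq(1000, 4000, 1000),
                          params = c("a", "b"))
  rep <- build_stability_report(tbl)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_parameter_sweep(tbl), "ggplot")
  g <- generate_gaw(kinematic_params(n_cycles = 4))
  expect_s3_class(autoplot(g), "ggplot")
  expect_output(print(rep), "gaw_stability_report")
  expect_output(print(kinematic_params()), "kinematic_params")
})
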