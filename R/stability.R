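#' Normality check (Shapiro-Wilk and Lilliefors)
#'
#' Screens a sample with the Shapiro-Wilk test and the Lilliefors
#' modification of the Kolmogorov-Smirnov test. The repeated-measures
#' pipeline proceeds nonparametrically when either p-value falls below 0.05
#' for any parameter. Constant samples are reported as non-normal (p = 0)
#' by convention, with a warning.
#'
#' @param x Numeric sample, `n >= 4`.
#' @return A tibble with columns `test` (`"shapiro"`, `"lilliefors"`) and
#'   `p_value`.
#' @export
#' @examples
#' normality_check(rexp(20))
normality_check <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) abort("normality check needs n >= 4.")
  if (length(unique(x)) == 1L) {
    warn("constant sample: reported as non-normal by convention.")
    return(tibble(test = c("shapiro", "lilliefors"), p_value = c(0, 0)))
  }
  sw <- shapiro.test(x)$p.value
  lf <- if (length(x) >= 5) {
    nortest::lillie.test(x)$p.value
  } else {
    warn("Lilliefors test needs n >= 5; returning NA.")
    NA_real_
  }
  tibble(test = c("shapiro", "lilliefors"), p_value = c(sw, lf))
}

# parameter x rate matrix (rows = recordings/blocks, cols = rates),
# listwise-dropping recordings with any missing value.
sweep_value_matrix <- function(table, parameter) {
  sub <- table[table$parameter == parameter, , drop = FALSE]
  if (!nrow(sub)) abort(sprintf("parameter '%s' not in table.", parameter))
  wide <- tidyr::pivot_wider(sub, id_cols = "recording_id",
                             names_from = "fps", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$recording_id
  rates <- as.numeric(colnames(m))
  m <- m[, order(rates), drop = FALSE]
  complete <- stats::complete.cases(m)
  list(values = m[complete, , drop = FALSE],
       rates = sort(rates),
       n_dropped = sum(!complete))
}

#' Friedman test across frame rates
#'
#' Tests whether a parameter's values differ across the recording frame
#' rates, treating recordings as blocks and rates as the repeated
#' treatments (chi-square approximation). Recordings with missing values at
#' any rate are dropped listwise. A parameter identical across all rates
#' yields statistic 0 and p = 1.
#'
#' @param table Long sweep table from [sweep_parameters()] (columns
#'   `recording_id`, `fps`, `parameter`, `value`).
#' @param parameter Parameter name to test.
#' @return A one-row tibble with `parameter`, `statistic`, `df`, `p_value`,
#'   `n_blocks`.
#' @export
friedman_across_rates <- function(table, parameter) {
  vm <- sweep_value_matrix(table, parameter)
  if (ncol(vm$values) < 3) abort("need at least 3 rates.")
  if (nrow(vm$values) < 2) abort("need at least 2 complete recordings.")
  ft <- suppressWarnings(friedman.test(vm$values))
  p <- ft$p.value
  stat <- unname(ft$statistic)
  if (!is.finite(p)) {            # all-tied ranks: statistic 0, no evidence
    p <- 1
    stat <- 0
  }
  tibble(parameter = parameter, statistic = stat,
         df = unname(ft$parameter), p_value = p, n_blocks = nrow(vm$values))
}

# Paired Wilcoxon signed-rank p-value with the common zero-discard
# convention; exact p for n <= 25 without tied magnitudes, normal
# approximation otherwise. All-zero differences give p = 1.
signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  if (!length(d)) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(wilcox.test(d, mu = 0, exact = exact)$p.value)
}

#' Pairwise Wilcoxon tests between all frame-rate pairs
#'
#' Runs the paired signed-rank test for every unordered pair of rates (105
#' pairs for 15 rates) and flags significance at the Bonferroni-corrected
#' level `alpha_family / (n_rates - 1)` — each rate takes part in
#' `n_rates - 1` comparisons, so 15 rates at family level 0.05 give the
#' corrected level 0.05/14 = 0.0036. Zero differences are discarded before
#' testing; a pair with all-zero differences is non-significant by
#' convention.
#'
#' @param table Long sweep table from [sweep_parameters()].
#' @param parameter Parameter name to test.
#' @param alpha_family Family-wise significance level.
#' @return A list with `p` (symmetric p-value matrix, diagonal `NA`),
#'   `significant` (symmetric logical matrix, diagonal `FALSE`), `rates`,
#'   and `alpha_corrected`.
#' @export
pairwise_wilcoxon <- function(table, parameter, alpha_family = 0.05) {
  vm <- sweep_value_matrix(table, parameter)
  m <- vm$values
  k <- ncol(m)
  if (k < 2) abort("need at least 2 rates.")
  alpha_corrected <- alpha_family / (k - 1)
  p <- matrix(NA_real_, k, k, dimnames = list(vm$rates, vm$rates))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- signed_rank_p(m[, i], m[, j])
    }
  }
  sig <- !is.na(p) & p < alpha_corrected
  diag(sig) <- FALSE
  list(p = p, significant = sig, rates = vm$rates,
       alpha_corrected = alpha_corrected)
}

#' Merge frame rates into stable intervals
#'
#' Greedy left-to-right merging of consecutive rates: an interval grows
#' while it contains no internally significant pair, then a new interval
#' starts. Additionally, an interior interval is marked "gray" when it is
#' not significantly different from either neighbouring interval while
#' those neighbours differ from each other — a bridge between two plateaus.
#'
#' @param significant Symmetric logical matrix over ascending rates from
#'   [pairwise_wilcoxon()].
#' @param rates Ascending rate vector (taken from the matrix dimnames when
#'   omitted).
#' @return A tibble with one row per interval: `start_rate`, `end_rate`,
#'   `n_rates`, `gray`.
#' @export
#' @examples
#' sig <- matrix(FALSE, 4, 4)
#' merge_stable_intervals(sig, rates = c(1000, 2000, 3000, 4000))
merge_stable_intervals <- function(significant, rates = NULL) {
  k <- nrow(significant)
  rates <- rates %||% as.numeric(rownames(significant))
  if (is.null(rates) || length(rates) != k) {
    abort("supply `rates` matching the matrix dimension.")
  }
  runs <- list()
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && !any(significant[i:(j + 1), i:(j + 1)])) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  n_runs <- length(runs)
  gray <- logical(n_runs)
  if (n_runs >= 3) {
    # gray bridge: adjacent to both neighbours without a significant step
    # across either boundary, while the neighbours differ from each other
    for (m in 2:(n_runs - 1)) {
      L <- runs[[m - 1]][1]:runs[[m - 1]][2]
      R <- runs[[m]][1]:runs[[m]][2]
      N <- runs[[m + 1]][1]:runs[[m + 1]][2]
      gray[m] <- !significant[max(L), min(R)] &&
        !significant[max(R), min(N)] &&
        any(significant[L, N])
    }
  }
  tibble(
    start_rate = rates[vapply(runs, `[`, numeric(1), 1)],
    end_rate = rates[vapply(runs, `[`, numeric(1), 2)],
    n_rates = vapply(runs, function(r) r[2] - r[1] + 1, numeric(1)),
    gray = gray
  )
}

#' Classify a parameter's frame-rate stability group
#'
#' Four-group taxonomy of how a parameter behaves across recording rates:
#' Group 1 — a single stable interval spans every rate (rate-independent);
#' Group 2 — unstable at low rates, then stable from some rate up to the
#' top rate (final interval spans at least 4 rates); Group 3 — stable
#' within an interior range of at least 4 rates but changing again at
#' higher rates; Group 4 — no stable stretch longer than 3 rates anywhere.
#'
#' @param intervals Interval tibble from [merge_stable_intervals()].
#' @param n_rates Total number of rates in the sweep.
#' @return Integer group label 1-4.
#' @export
#' @examples
#' iv <- merge_stable_intervals(matrix(FALSE, 3, 3), rates = 1:3)
#' classify_group(iv, n_rates = 3)
classify_group <- function(intervals, n_rates = 15) {
  if (sum(intervals$n_rates) != n_rates) {
    abort("intervals must cover all rates exactly.")
  }
  spans <- intervals$n_rates
  m <- length(spans)
  if (m == 1L) return(1L)
  if (spans[m] >= 4) return(2L)
  if (any(spans[-m] >= 4)) return(3L)
  4L
}

#' Full frame-rate stability report
#'
#' Runs the complete repeated-measures procedure on a long sweep table:
#' per-parameter normality screening, a Friedman test across rates, and —
#' only when the Friedman test is significant at `alpha` — pairwise
#' Wilcoxon signed-rank tests at the Bonferroni-corrected level
#' `alpha / (n_rates - 1)`. Non-significant Friedman tests gate the
#' parameter straight into a single all-rate stable interval (Group 1).
#' Rates are then merged into stable intervals (with the min-max range of
#' the per-rate means attached) and each parameter receives its Group 1-4
#' label.
#'
#' @param table Long sweep table from [sweep_parameters()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `gaw_stability_report`: a list with per-parameter entries
#'   (`friedman`, `pairwise`, `intervals`, `group`, `normality`) plus
#'   `rates`, `alpha` and `alpha_corrected`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
build_stability_report <- function(table, alpha = 0.05) {
  if (!nrow(table)) abort("empty sweep table.")
  params <- unique(table$parameter)
  rates <- sort(unique(table$fps))
  k <- length(rates)
  per_rate_means <- table |>
    dplyr::group_by(.data$parameter, .data$fps) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
  entries <- lapply(params, function(pn) {
    vm <- sweep_value_matrix(table, pn)
    norm <- tryCatch(suppressWarnings(normality_check(as.vector(vm$values))),
                     error = function(e) tibble(test = character(),
                                                p_value = numeric()))
    fr <- tryCatch(friedman_across_rates(table, pn), error = function(e) {
      tibble(parameter = pn, statistic = NA_real_, df = NA_real_,
             p_value = NA_real_, n_blocks = nrow(vm$values))
    })
    gated <- is.finite(fr$p_value) && fr$p_value < alpha
    pw <- if (gated) {
      pairwise_wilcoxon(table, pn, alpha_family = alpha)
    } else {
      sig <- matrix(FALSE, k, k, dimnames = list(rates, rates))
      list(p = matrix(NA_real_, k, k, dimnames = list(rates, rates)),
           significant = sig, rates = rates,
           alpha_corrected = alpha / (k - 1))
    }
    iv <- merge_stable_intervals(pw$significant, pw$rates)
    mns <- per_rate_means[per_rate_means$parameter == pn, ]
    iv$mean_min <- iv$mean_max <- NA_real_
    for (r in seq_len(nrow(iv))) {
      inside <- mns$fps >= iv$start_rate[r] & mns$fps <= iv$end_rate[r]
      iv$mean_min[r] <- min(mns$mean[inside])
      iv$mean_max[r] <- max(mns$mean[inside])
    }
    list(parameter = pn, normality = norm, friedman = fr, pairwise = pw,
         intervals = iv, group = classify_group(iv, k),
         n_dropped = vm$n_dropped)
  })
  names(entries) <- params
  structure(
    list(parameters = entries, rates = rates, alpha = alpha,
         alpha_corrected = alpha / (k - 1)),
    class = "gaw_stability_report"
  )
}

#' @export
print.gaw_stability_report <- function(x, ...) {
  cat(sprintf("<gaw_stability_report> %d parameters x %d rates (alpha %g, corrected %.4g)\n",
              length(x$parameters), length(x$rates), x$alpha,
              x$alpha_corrected))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a stability report
#'
#' @param x A `gaw_stability_report`.
#' @param ... Unused.
#' @return One row per parameter: `parameter`, `friedman_p`, `group`,
#'   `n_intervals`, `stable_from` (start of the interval containing the top
#'   rate), `intervals` (list-column of interval tibbles).
#' @method tidy gaw_stability_report
#' @export
tidy.gaw_stability_report <- function(x, ...) {
  purrr::map_dfr(x$parameters, function(e) {
    iv <- e$intervals
    tibble(
      parameter = e$parameter,
      friedman_p = e$friedman$p_value,
      group = e$group,
      n_intervals = nrow(iv),
      stable_from = iv$start_rate[nrow(iv)],
      intervals = list(iv)
    )
  })
}

#' Summarise a stability report
#'
#' @param x A `gaw_stability_report`.
#' @param ... Unused.
#' @return A one-row tibble: parameter counts per stability group, the
#'   number of rates, and the corrected significance level.
#' @method glance gaw_stability_report
#' @export
glance.gaw_stability_report <- function(x, ...) {
  groups <- vapply(x$parameters, `[[`, integer(1), "group")
  tibble(
    n_parameters = length(groups),
    n_group1 = sum(groups == 1L), n_group2 = sum(groups == 2L),
    n_group3 = sum(groups == 3L), n_group4 = sum(groups == 4L),
    n_rates = length(x$rates),
    alpha_corrected = x$alpha_corrected
  )
}

#' Write a stability report
#'
#' Serializes the per-parameter results as JSON (full detail: Friedman p,
#' pairwise p matrix, intervals, group) and, for a `.csv` path, as a flat
#' table with one row per parameter and its merged intervals rendered as
#' text.
#'
#' @param report A `gaw_stability_report`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    flat <- tidy(report) |>
      dplyr::mutate(intervals = vapply(.data$intervals, function(iv) {
        paste(sprintf("%g-%g[%.4g,%.4g]%s", iv$start_rate, iv$end_rate,
                      iv$mean_min, iv$mean_max,
                      ifelse(iv$gray, "(gray)", "")), collapse = " ")
      }, character(1)))
    readr::write_csv(flat, path)
  } else {
    out <- lapply(report$parameters, function(e) {
      list(parameter = e$parameter,
           friedman_p = e$friedman$p_value,
           group = e$group,
           intervals = e$intervals,
           pairwise_p = e$pairwise$p)
    })
    jsonlite::write_json(
      list(alpha = report$alpha, alpha_corrected = report$alpha_corrected,
           rates = report$rates, parameters = unname(out)),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}
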