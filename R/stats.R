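#' Summarise fitted influence coefficients across sessions
#'
#' Sample mean and standard deviation (n - 1 denominator) of the fitted
#' coefficient per setting, the across-session dispersion the empirical
#' decay-law model is built from.
#'
#' @param fits A tibble from [fit_sessions()] (columns `setting`, `d`, `c`).
#' @return A tibble with columns `setting`, `d`, `n`, `mean`, `sd`.
#' @export
summarize_coefficients <- function(fits) {
  fits <- fits[!is.na(fits$c), ]
  out <- fits |>
    dplyr::group_by(.data$setting, .data$d) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$c),
      sd = sd(.data$c),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    abort("At least 2 fitted values per setting are required to summarise.")
  }
  out
}

#' Two-sided test for a difference in coefficient means
#'
#' Default is Welch's unequal-variance two-sample t-test of the null that the
#' two means are equal; a permutation test on the mean difference is available
#' as an alternative.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param method `"welch"` or `"permutation"`.
#' @param n_perm Number of permutations for the permutation test.
#' @param seed Seed for the permutation test.
#' @return The two-sided p-value.
#' @export
mean_difference_test <- function(a, b, method = c("welch", "permutation"),
                                 n_perm = 2000, seed = NULL) {
  method <- arg_match(method)
  if (length(a) < 2 || length(b) < 2) abort("Each sample must contain at least 2 values.")
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  if (method == "welch") {
    t.test(a, b, var.equal = FALSE)$p.value
  } else {
    obs <- abs(mean(a) - mean(b))
    pooled <- c(a, b)
    na <- length(a)
    with_seed(seed, {
      exceed <- sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), na)
        abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs
      }, logical(1)))
      (exceed + 1) / (n_perm + 1)
    })
  }
}

#' Detect outlying sessions
#'
#' Three detectors over a per-session statistic (typically the fitted
#' coefficient of one setting): `zscore` flags values at least `z_cut`
#' standard deviations from the mean; `tukey` flags values outside
#' `[Q1 - k IQR, Q3 + k IQR]`; `mean_regression` scores each value by how much
#' the sample mean changes when it is removed, flagging scores above
#' `mr_k * median(score)`.
#'
#' @param values Numeric per-session statistic (>= 4 values).
#' @param method `"zscore"`, `"tukey"` or `"mean_regression"`.
#' @param ids Optional session identifiers (defaults to `seq_along(values)`).
#' @param z_cut Z-score cutoff (default 2).
#' @param tukey_k IQR multiplier (default 1.5).
#' @param mr_k Mean-regression score multiplier (default 3).
#' @return A tibble with columns `id`, `value`, `score`, `flagged`, and the
#'   `method` as an attribute.
#' @export
detect_outliers <- function(values, method = c("zscore", "tukey", "mean_regression"),
                            ids = NULL, z_cut = 2, tukey_k = 1.5, mr_k = 3) {
  method <- arg_match(method)
  if (length(values) < 4) abort("At least 4 values are required for outlier detection.")
  ids <- ids %||% seq_along(values)
  if (sd(values) == 0) {
    warn("All values identical: no outliers can be detected.")
    return(structure(
      tibble(id = ids, value = values, score = 0, flagged = FALSE),
      method = method
    ))
  }
  if (method == "zscore") {
    score <- abs(values - mean(values)) / sd(values)
    flagged <- score >= z_cut
  } else if (method == "tukey") {
    q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - tukey_k * iqr
    hi <- q[2] + tukey_k * iqr
    score <- pmax(lo - values, values - hi, 0)
    flagged <- values < lo | values > hi
  } else {
    full <- mean(values)
    score <- vapply(seq_along(values), function(i) abs(full - mean(values[-i])), numeric(1))
    flagged <- score > mr_k * median(score)
  }
  structure(
    tibble(id = ids, value = values, score = score, flagged = flagged),
    method = method
  )
}

#' Identify stubborn participants in a setting
#'
#' If the modal colour of the final round covers at least
#' `consensus_threshold` of the seats (a group consensus exists), every
#' participant whose colour differed from it in both of the last two played
#' rounds is flagged as stubborn; with no near-consensus nobody is flagged.
#' Bot seats are excluded by default since their policy is known.
#'
#' @param records Round records for one setting.
#' @param consensus_threshold Minimal modal share defining a consensus
#'   (default 0.8).
#' @param include_bots Also consider bot seats.
#' @return Integer vector of flagged node labels (possibly empty).
#' @export
detect_stubborn <- function(records, consensus_threshold = 0.8,
                            include_bots = FALSE) {
  last_round <- max(records$round)
  final <- records[records$round == last_round, ]
  modal_innov <- mean(final$chose_innovation) >= 0.5
  share <- mean(final$chose_innovation == modal_innov)
  if (share < consensus_threshold) return(integer(0))
  last_two <- records[records$round >= last_round - 1L, ]
  cand <- last_two |>
    dplyr::group_by(.data$node, .data$role) |>
    dplyr::summarise(
      never_modal = all(.data$chose_innovation != modal_innov),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$never_modal)
  if (!include_bots) cand <- cand[cand$role != "bot", ]
  sort(as.integer(cand$node))
}

#' Linear decay of influence with social distance
#'
#' Least-squares line through the per-setting mean coefficients as a function
#' of distance d, anchored at the direct-influence strength (d = 1, c = 1).
#' Mean coefficients near (1, 2/3, 1/3) at d = (1, 2, 3) give the law
#' `c_d = (4 - d)/3`.
#'
#' @param summary A [summarize_coefficients()] tibble (columns `d`, `mean`),
#'   or any tibble with those columns.
#' @param anchor Include the point (d = 1, mean = 1) (default TRUE).
#' @return A list with `slope`, `intercept`, the fitted `lm` object and the
#'   points used.
#' @export
linear_decay_fit <- function(summary, anchor = TRUE) {
  pts <- tibble(d = summary$d, mean = summary$mean)
  if (anchor) pts <- dplyr::bind_rows(tibble(d = 1, mean = 1), pts)
  if (nrow(pts) < 2) abort("At least 2 points are required to fit a line.")
  fit <- lm(mean ~ d, data = pts)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    model = fit,
    points = pts
  )
}
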