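#' Parameter grid for curve fitting
#'
#' Defaults match the estimation procedure used throughout the package: the
#' indirect influence strength c is searched over \[0, 1\] in steps of 0.01,
#' the time horizon T over 10-1000 in steps of 10, and the adoption threshold
#' over \{0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99\}.
#'
#' @param c_values Candidate coefficients.
#' @param T_values Candidate time horizons.
#' @param delta_values Candidate thresholds.
#' @return A list of class `fit_grid`.
#' @export
fit_grid <- function(c_values = seq(0, 1, by = 0.01),
                     T_values = seq(10, 1000, by = 10),
                     delta_values = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99)) {
  if (length(c_values) == 0 || length(T_values) == 0 || length(delta_values) == 0) {
    abort("All fit-grid dimensions must be nonempty.")
  }
  structure(
    list(
      c_values = sort(c_values),
      T_values = sort(T_values),
      delta_values = sort(delta_values)
    ),
    class = "fit_grid"
  )
}

#' Model-predicted adopter curve for one setting
#'
#' Composes the pipeline used in fitting: build the generator
#' `L_1 + c L_d` (just `L_1` when `d` is NULL, as in setting I), evolve the
#' binary initial state over `r` rounds equidistributed on `[0, T]`, and
#' threshold into a cumulative adopter curve.
#'
#' @param laps A [path_laplacians()] object.
#' @param d Circle distance of the single free coefficient, or `NULL`.
#' @param c Coefficient value (ignored when `d` is NULL).
#' @param delta Adoption threshold.
#' @param T_total Time horizon.
#' @param r Number of rounds.
#' @param u0 Binary initial state.
#' @param normalize See [adopter_curve()].
#' @return A tibble with columns `round`, `proportion`.
#' @export
predict_curve <- function(laps, d, c, delta, T_total, r, u0, normalize = TRUE) {
  coefficients <- if (is.null(d)) NULL else setNames(c, as.character(d))
  M <- build_generator(laps, coefficients)
  states <- evolve(M, u0, discretize_rounds(T_total, r))
  adopter_curve(states, u0, delta, normalize = normalize)
}

# Cumulative adopter proportions for every (T, delta) cell of a grid at one
# coefficient value, sharing a single eigendecomposition. Returns an array
# [round, T, delta].
curve_grid_at_c <- function(M, u0, r, T_values, delta_values, normalize) {
  eg <- eigen(M, symmetric = TRUE)
  w <- drop(crossprod(eg$vectors, u0))
  fracs <- seq(0, 1, length.out = r)
  times <- as.vector(outer(fracs, T_values))       # column blocks of length r per T
  U <- eg$vectors %*% (w * exp(-outer(eg$values, times)))
  nT <- length(T_values)
  n <- length(u0)
  ubar <- mean(u0)
  out <- array(NA_real_, dim = c(r, nT, length(delta_values)))
  for (k in seq_along(delta_values)) {
    thr <- if (normalize) delta_values[k] * ubar else delta_values[k]
    ind <- U > thr
    dim(ind) <- c(n, r, nT)
    acc <- matrix(FALSE, n, nT)
    for (j in seq_len(r)) {
      acc <- acc | ind[, j, ]
      out[j, , k] <- colMeans(acc)
    }
  }
  out
}

#' Grid-search fit of an observed adopter curve
#'
#' Exhaustively evaluates the model curve at every grid combination of the
#' setting's free coefficient c, threshold delta and time horizon T, and
#' returns the combination minimising the mean squared error against the
#' observed per-round adopter proportions (the Pearson correlation at the
#' optimum is reported alongside). Ties in MSE are broken towards the
#' smallest c, then smallest T, then smallest delta — the most parsimonious
#' model — and a message is emitted when a tie occurred.
#'
#' @param observed Observed adopter proportions: a numeric vector or a tibble
#'   with a `proportion` column (one entry per round, round 1 first).
#' @param laps A [path_laplacians()] object for the session network.
#' @param setting_d Distance of the free coefficient (2, 3 or 4), or `NULL`
#'   for the direct-influence-only model of setting I (no free c).
#' @param u0 Binary initial adopter state used in the session.
#' @param grid A [fit_grid()].
#' @param normalize See [adopter_curve()].
#' @return An object of class `innovation_fit` with the fitted parameters,
#'   `mse`, `pearson`, observed and predicted curves. Use [tidy()],
#'   [glance()], [augment()] or [autoplot()] on it.
#' @export
grid_search <- function(observed, laps, setting_d, u0, grid = fit_grid(),
                        normalize = TRUE) {
  if (is.data.frame(observed)) observed <- observed$proportion
  r <- length(observed)
  if (r < 3) abort("The observed curve must have at least 3 rounds.")
  if (length(u0) != laps$n) abort("u0 length does not match the network size.")
  if (!is.null(setting_d) && (setting_d < 2 || setting_d > laps$diameter)) {
    abort(paste0("setting_d must lie in [2, ", laps$diameter, "]."))
  }

  L1 <- laps$laplacians[[1]]
  Ld <- if (is.null(setting_d)) NULL else laps$laplacians[[setting_d]]
  c_values <- if (is.null(setting_d)) 0 else grid$c_values

  best <- list(mse = Inf, c = NA_real_, T = NA_real_, delta = NA_real_)
  n_at_best <- 0L
  for (ci in seq_along(c_values)) {
    M <- if (is.null(Ld)) L1 else L1 + c_values[ci] * Ld
    props <- curve_grid_at_c(M, u0, r, grid$T_values, grid$delta_values, normalize)
    err <- sweep(props, 1, observed)             # round x T x delta residuals
    mse <- apply(err^2, c(2, 3), mean)           # T x delta
    m <- min(mse)
    if (m < best$mse) {
      hit <- which(mse == m, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      best <- list(
        mse = m,
        c = if (is.null(setting_d)) NA_real_ else c_values[ci],
        T = grid$T_values[hit[1, 1]],
        delta = grid$delta_values[hit[1, 2]]
      )
      n_at_best <- sum(mse == m)
    } else if (m == best$mse) {
      n_at_best <- n_at_best + sum(mse == m)
    }
  }
  if (n_at_best > 1L) {
    inform(paste0(
      "MSE tie among ", n_at_best,
      " grid points; kept the smallest (c, T, delta)."
    ))
  }

  predicted <- predict_curve(
    laps, setting_d, if (is.null(setting_d)) 0 else best$c,
    best$delta, best$T, r, u0, normalize = normalize
  )
  pearson <- if (sd(observed) == 0 || sd(predicted$proportion) == 0) {
    warn("Constant curve: Pearson correlation is undefined and reported as NA.")
    NA_real_
  } else {
    cor(predicted$proportion, observed)
  }

  structure(
    list(
      setting_d = setting_d,
      c = best$c, delta = best$delta, T = best$T,
      mse = best$mse, pearson = pearson,
      observed = observed, predicted = predicted$proportion,
      normalize = normalize, grid = grid, n = laps$n
    ),
    class = "innovation_fit"
  )
}

#' @export
print.innovation_fit <- function(x, ...) {
  cat("<innovation_fit>",
      if (is.null(x$setting_d)) "direct influence only" else paste0("free coefficient c_", x$setting_d),
      "\n")
  cat(sprintf("  c = %s, delta = %.2f, T = %g, MSE = %.3g, Pearson = %.3f\n",
              ifelse(is.na(x$c), "-", format(x$c)), x$delta, x$T, x$mse, x$pearson))
  invisible(x)
}

#' @rdname tidy
#' @param x An `innovation_fit` object.
#' @param ... Unused.
#' @method tidy innovation_fit
#' @export
tidy.innovation_fit <- function(x, ...) {
  tibble(
    term = c(if (!is.null(x$setting_d)) paste0("c_", x$setting_d), "delta", "T"),
    estimate = c(if (!is.null(x$setting_d)) x$c, x$delta, x$T)
  )
}

#' @rdname glance
#' @param x An `innovation_fit` object.
#' @param ... Unused.
#' @method glance innovation_fit
#' @export
glance.innovation_fit <- function(x, ...) {
  tibble(
    setting_d = x$setting_d %||% NA_integer_,
    c = x$c, delta = x$delta, T = x$T,
    mse = x$mse, pearson = x$pearson,
    n_rounds = length(x$observed)
  )
}

#' @rdname augment
#' @param x An `innovation_fit` object.
#' @param ... Unused.
#' @method augment innovation_fit
#' @export
augment.innovation_fit <- function(x, ...) {
  tibble(
    round = seq_along(x$observed),
    observed = x$observed,
    predicted = x$predicted,
    residual = x$observed - x$predicted
  )
}

#' Fit every session-setting in a set of round records
#'
#' Computes each session-setting's observed adopter curve (optionally padded
#' at the consensus value), the session's initial adopter state, and runs
#' [grid_search()] with the setting's free coefficient (none for setting I,
#' c_2/c_3/c_4 for settings II-IV).
#'
#' @param records Round records (possibly several sessions and settings).
#' @param laps A [path_laplacians()] object for the network the sessions ran
#'   on.
#' @param grid A [fit_grid()].
#' @param pad_to Pad observed curves to this many rounds (NULL = no padding).
#' @param normalize See [adopter_curve()].
#' @return A tibble with one row per session-setting: `session_id`, `setting`,
#'   `d`, `c`, `delta`, `T`, `mse`, `pearson`, `n_rounds`.
#' @export
fit_sessions <- function(records, laps, grid = fit_grid(), pad_to = NULL,
                         normalize = TRUE) {
  curves <- observed_curve(records, pad_to = pad_to)
  groups <- curves |> dplyr::distinct(.data$session_id, .data$setting)
  purrr::pmap_dfr(groups, function(session_id, setting) {
    cv <- curves[curves$session_id == session_id & curves$setting == setting, ]
    rec1 <- records[records$session_id == session_id &
                      records$setting == setting & records$round == 1L, ]
    u0 <- as.integer(rec1$chose_innovation[order(rec1$node)])
    d <- setting_spec(setting)$display_distance
    if (is.na(d)) d <- NULL
    fit <- grid_search(cv$proportion, laps, d, u0, grid = grid,
                       normalize = normalize)
    g <- glance(fit)
    tibble(
      session_id = session_id, setting = setting,
      d = g$setting_d, c = g$c, delta = g$delta, T = g$T,
      mse = g$mse, pearson = g$pearson, n_rounds = g$n_rounds
    )
  })
}

#' Joint grid search over several simultaneous coefficients
#'
#' Optional multi-term variant: exhaustively searches a user-supplied (coarse)
#' coefficient grid applied to every distance in `ds` simultaneously, i.e.
#' the generator `L_1 + sum_d c_d L_d`. Runtime grows as
#' `length(c_values)^length(ds)`, so keep the grids coarse.
#'
#' @inheritParams grid_search
#' @param ds Distances fitted jointly, e.g. `c(2, 3)`.
#' @param c_values Candidate values for each coefficient.
#' @return A list with fitted `coefficients`, `delta`, `T`, `mse`, `pearson`.
#' @export
grid_search_joint <- function(observed, laps, ds, u0,
                              c_values = seq(0, 1, by = 0.1),
                              T_values = seq(10, 1000, by = 10),
                              delta_values = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.99),
                              normalize = TRUE) {
  if (is.data.frame(observed)) observed <- observed$proportion
  r <- length(observed)
  combos <- do.call(expand.grid, rep(list(c_values), length(ds)))
  names(combos) <- as.character(ds)
  L1 <- laps$laplacians[[1]]
  best <- list(mse = Inf)
  for (i in seq_len(nrow(combos))) {
    M <- L1
    for (j in seq_along(ds)) M <- M + combos[i, j] * laps$laplacians[[ds[j]]]
    props <- curve_grid_at_c(M, u0, r, T_values, delta_values, normalize)
    mse <- apply(sweep(props, 1, observed)^2, c(2, 3), mean)
    m <- min(mse)
    if (m < best$mse) {
      hit <- which(mse == m, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      best <- list(
        mse = m,
        coefficients = setNames(as.numeric(combos[i, ]), as.character(ds)),
        T = T_values[hit[1, 1]], delta = delta_values[hit[1, 2]]
      )
    }
  }
  M <- build_generator(laps, best$coefficients)
  states <- evolve(M, u0, discretize_rounds(best$T, r))
  pred <- adopter_curve(states, u0, best$delta, normalize = normalize)$proportion
  best$pearson <- if (sd(observed) == 0 || sd(pred) == 0) NA_real_ else cor(pred, observed)
  best
}
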