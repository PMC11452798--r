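#' Diffusion generator combining direct and indirect influence
#'
#' Builds the operator `M = L_1 + sum_{d >= 2} c_d L_d` that drives the
#' consensus dynamics `du/dt = -M u`. The nearest-neighbour strength is fixed
#' at `c_1 = 1`; each `c_d` scales the pressure exerted by a node's d-th
#' circle of influence relative to its direct neighbours.
#'
#' @param laps A [path_laplacians()] object.
#' @param coefficients Named numeric vector of influence strengths, names are
#'   distances (e.g. `c("2" = 0.65, "3" = 0.37)`). Distances not named get
#'   coefficient 0. May be `NULL` for direct influence only.
#' @param allow_negative Permit negative coefficients (for sensitivity
#'   analysis); by default negative strengths are an error.
#' @return A symmetric positive semidefinite matrix with zero row sums.
#' @export
build_generator <- function(laps, coefficients = NULL, allow_negative = FALSE) {
  stopifnot(inherits(laps, "path_laplacian_set"))
  M <- laps$laplacians[[1]]
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
      abort("`coefficients` must be named by distance, e.g. c(`2` = 0.5).")
    }
    ds <- as.integer(names(coefficients))
    if (any(is.na(ds)) || any(ds < 2) || any(ds > laps$diameter)) {
      abort(paste0("Coefficient distances must be integers in [2, ", laps$diameter, "]."))
    }
    if (!allow_negative && any(coefficients < 0)) {
      abort("Negative influence strengths are not allowed (set allow_negative = TRUE to override).")
    }
    for (i in seq_along(ds)) {
      Ld <- laps$laplacians[[ds[i]]]
      if (!identical(dim(Ld), dim(M))) abort("Laplacian dimension mismatch.")
      M <- M + coefficients[i] * Ld
    }
  }
  M
}

#' Evolve adoption propensities under the consensus dynamics
#'
#' Solves `du/dt = -M u, u(0) = u0` at the requested times via the matrix
#' exponential `u(t) = exp(-t M) u0`, computed from the eigendecomposition of
#' the symmetric generator. The mean of `u` is conserved: every node relaxes
#' toward the consensus value `mean(u0)`.
#'
#' @param generator Symmetric generator matrix from [build_generator()].
#' @param u0 Numeric initial propensity vector (length `nrow(generator)`).
#' @param times Nondecreasing vector of nonnegative times.
#' @return A numeric matrix with one column per time, rows in node order.
#' @export
evolve <- function(generator, u0, times) {
  n <- nrow(generator)
  if (length(u0) != n) abort("u0 length does not match the generator dimension.")
  if (any(times < 0)) abort("Evolution times must be nonnegative.")
  if (is.unsorted(times)) abort("Evolution times must be sorted.")
  eg <- eigen(generator, symmetric = TRUE)
  w <- drop(crossprod(eg$vectors, u0))
  # exp(-t M) u0 = V diag(exp(-t lambda)) V' u0
  E <- exp(-outer(eg$values, times))
  out <- eg$vectors %*% (E * w)
  dimnames(out) <- list(rownames(generator), NULL)
  out
}

#' Equidistributed round times
#'
#' Maps `r` experimental rounds onto the continuous interval `[0, T]`:
#' `t_i = (i - 1) T / (r - 1)`, so round 1 sits at time 0 (reproducing the
#' initial condition) and round `r` at time `T`.
#'
#' @param T_total Total continuous time horizon (> 0).
#' @param r Number of rounds (>= 2).
#' @return Numeric vector of length `r`.
#' @export
discretize_rounds <- function(T_total, r) {
  if (T_total <= 0) abort("T_total must be positive.")
  if (r < 2) abort("At least 2 rounds are required to discretize.")
  seq(0, 1, length.out = r) * T_total
}

#' Threshold-based cumulative adopter curve
#'
#' Discretizes continuous propensities into adopter counts: node i counts as
#' an adopter at round k if its propensity exceeded the adoption threshold at
#' any round up to k (once an adopter, always an adopter). With
#' `normalize = TRUE` (default) the threshold is `delta * mean(u0)`, i.e. a
#' node adopts when it reaches a fraction `delta` of the consensus value; with
#' `normalize = FALSE` the raw propensity is compared with `delta` directly.
#'
#' @param states Matrix of propensities from [evolve()] (nodes x rounds).
#' @param u0 Binary initial state (1 = initial adopter); at least one 0 and
#'   one 1.
#' @param delta Threshold in (0, 1].
#' @param normalize Compare `u / mean(u0)` (default) rather than `u` with
#'   `delta`.
#' @return A tibble with columns `round` and `proportion` (nondecreasing,
#'   starting at the initial adopter fraction).
#' @export
adopter_curve <- function(states, u0, delta, normalize = TRUE) {
  if (!all(u0 %in% c(0, 1))) abort("u0 must be binary (0/1 adopter indicators).")
  if (all(u0 == 0) || all(u0 == 1)) {
    abort("u0 must contain at least one adopter and one non-adopter.")
  }
  if (delta <= 0 || delta > 1) abort("delta must lie in (0, 1].")
  thr <- if (normalize) delta * mean(u0) else delta
  adopted <- states > thr
  cum <- apply(adopted, 1, cummax)            # rounds x nodes
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = ncol(states))
  tibble(round = seq_len(ncol(states)), proportion = rowMeans(cum))
}

#' Distance-decay laws for indirect influence strength
#'
#' Closed-form laws for how peer pressure decays with social distance d:
#' `linear_3` is `(4 - d)/3`, `linear_4` is `(5 - d)/4` and `harmonic` is
#' `2/(1 + d)`. Both linear laws equal 1 at `d = 1`; under `linear_3` the
#' second and third circles exert two-thirds and one-third of the direct
#' pressure. Negative linear values (e.g. `linear_3` at `d >= 4`) are clamped
#' to zero by default, since influence strengths are nonnegative and negative
#' coefficients can destroy positive semidefiniteness of the generator.
#'
#' @param name One of `"linear_3"`, `"linear_4"`, `"harmonic"`.
#' @param d Distance(s), >= 1.
#' @param clamp Clamp negative values to 0 (default `TRUE`).
#' @return Numeric coefficient(s).
#' @export
#' @examples
#' decay_law("linear_3", 2:3)  # 2/3, 1/3
decay_law <- function(name, d, clamp = TRUE) {
  if (any(d < 1)) abort("d must be >= 1.")
  name <- arg_match(name, c("linear_3", "linear_4", "harmonic"))
  val <- switch(name,
    linear_3 = (4 - d) / 3,
    linear_4 = (5 - d) / 4,
    harmonic = 2 / (1 + d)
  )
  if (clamp) val <- pmax(0, val)
  val
}

#' Coefficients of a decay law over all circles of a network
#'
#' @param name Law name as in [decay_law()], or `"direct_only"` for no
#'   indirect influence at all.
#' @param diameter Network diameter D.
#' @param clamp See [decay_law()].
#' @return Named coefficient vector for distances `2..D` (empty for
#'   `"direct_only"`), suitable for [build_generator()].
#' @export
decay_law_coefficients <- function(name, diameter, clamp = TRUE) {
  if (identical(name, "direct_only")) {
    return(setNames(numeric(0), character(0)))
  }
  ds <- seq(2, diameter)
  setNames(decay_law(name, ds, clamp = clamp), as.character(ds))
}
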