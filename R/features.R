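#' Build the decision-level classification table
#'
#' One row per human decision from round 2 on (round-1 colours are the
#' assigned initialisation, not decisions). The label is whether the
#' participant chose the innovation colour that round; the features are the
#' pieces of information available to them:
#' * `f_initial` — innovation was their initial colour;
#' * `f_majority` — the innovation is the majority colour among all peers
#'   displayed to them (ties count as not-majority);
#' * `f_direct` — fraction of their two displayed direct neighbours showing
#'   the innovation;
#' * `f_distant` — fraction of their two displayed distance-k neighbours
#'   showing the innovation (0 and constant in setting I).
#'
#' @param records Round records from [simulate_setting()] /
#'   [simulate_session()].
#' @param include_bots Include rows decided by bots (default FALSE: the bot
#'   policy is known and would dilute the human signal).
#' @return A tibble with columns `setting`, `node`, `round`,
#'   `chose_innovation` and the four features.
#' @export
build_decision_table <- function(records, include_bots = FALSE) {
  initial <- records |>
    dplyr::filter(.data$round == 1L) |>
    dplyr::select("session_id", "setting", "node",
                  f_initial = "chose_innovation")
  rows <- records |> dplyr::filter(.data$round >= 2L)
  if (!include_bots) rows <- rows |> dplyr::filter(.data$active, .data$role != "bot")
  missing_display <- is.na(rows$d1_innov)
  if (any(missing_display)) {
    inform(paste0("Skipped ", sum(missing_display), " row(s) without display data."))
    rows <- rows[!missing_display, ]
  }
  shown <- cbind(rows$d1_innov, rows$d2_innov, rows$k1_innov, rows$k2_innov)
  n_shown <- rowSums(!is.na(shown))
  n_innov <- rowSums(shown, na.rm = TRUE)
  rows |>
    dplyr::left_join(initial, by = c("session_id", "setting", "node")) |>
    dplyr::mutate(
      f_initial = as.numeric(.data$f_initial),
      f_majority = as.numeric(n_innov > n_shown / 2),
      f_distant = ifelse(is.na(.data$f_distant), 0, .data$f_distant)
    ) |>
    dplyr::select("session_id", "setting", "node", "round",
                  "chose_innovation", "f_initial", "f_majority",
                  "f_direct", "f_distant")
}

feature_names <- function() c("f_initial", "f_majority", "f_direct", "f_distant")

rf_fit <- function(x, y, ntree, maxnodes) {
  randomForest::randomForest(
    x = x, y = y, ntree = ntree,
    maxnodes = if (is.na(maxnodes)) NULL else maxnodes
  )
}

#' Nested cross-validated classification accuracy
#'
#' Estimates how well the four informational features predict per-round
#' colour choices with a bagged random forest: the outer 5-fold loop measures
#' test accuracy, the inner 5-fold loop selects the hyperparameters (number
#' of trees and maximum terminal nodes) on the training folds only.
#'
#' @param table A [build_decision_table()] tibble (>= 50 rows, both classes
#'   present).
#' @param seed Integer seed.
#' @param trees Candidate tree counts.
#' @param maxnodes Candidate maximum-terminal-node counts (`NA` = unrestricted
#'   depth).
#' @param outer_k,inner_k Fold counts (default 5/5).
#' @param max_rows Optional cap on table size (random subsample) to bound
#'   runtime on large session collections.
#' @return A list with `accuracy` (mean outer-fold accuracy), per-fold
#'   accuracies and the selected hyperparameters per fold.
#' @export
nested_cv_accuracy <- function(table, seed = NULL, trees = c(100, 300),
                               maxnodes = c(NA, 32), outer_k = 5, inner_k = 5,
                               max_rows = NULL) {
  y <- factor(table$chose_innovation, levels = c(FALSE, TRUE))
  if (nrow(table) < 50) abort("At least 50 decisions are required.")
  if (length(unique(y)) < 2) abort("Both classes must be present in the decision table.")
  x <- as.data.frame(table[, feature_names()])
  with_seed(seed, {
    if (!is.null(max_rows) && nrow(x) > max_rows) {
      keep <- sample.int(nrow(x), max_rows)
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
    n <- nrow(x)
    outer_fold <- sample(rep_len(seq_len(outer_k), n))
    combos <- expand.grid(ntree = trees, maxnodes = maxnodes)
    fold_acc <- numeric(outer_k)
    chosen <- vector("list", outer_k)
    for (f in seq_len(outer_k)) {
      tr <- which(outer_fold != f)
      te <- which(outer_fold == f)
      inner_fold <- sample(rep_len(seq_len(inner_k), length(tr)))
      inner_acc <- vapply(seq_len(nrow(combos)), function(j) {
        mean(vapply(seq_len(inner_k), function(g) {
          itr <- tr[inner_fold != g]
          ite <- tr[inner_fold == g]
          m <- rf_fit(x[itr, , drop = FALSE], y[itr],
                      combos$ntree[j], combos$maxnodes[j])
          mean(stats::predict(m, x[ite, , drop = FALSE]) == y[ite])
        }, numeric(1)))
      }, numeric(1))
      j_best <- which.max(inner_acc)
      chosen[[f]] <- combos[j_best, ]
      m <- rf_fit(x[tr, , drop = FALSE], y[tr],
                  combos$ntree[j_best], combos$maxnodes[j_best])
      fold_acc[f] <- mean(stats::predict(m, x[te, , drop = FALSE]) == y[te])
    }
    list(
      accuracy = mean(fold_acc),
      fold_accuracy = fold_acc,
      hyperparameters = dplyr::bind_rows(chosen),
      n = n
    )
  })
}

#' Out-of-bag permutation feature importance, per setting
#'
#' Fits one random forest per informational setting and reports, for each
#' feature, the mean increase in out-of-bag classification error when that
#' feature is permuted within the OOB samples (randomForest's unscaled mean
#' decrease in accuracy). Nonpositive importances are reported as-is; a
#' feature that is constant within a setting (e.g. the distance-k fraction in
#' setting I) gets importance ~ 0.
#'
#' @param table A [build_decision_table()] tibble.
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @return A tibble with columns `setting`, `feature`, `importance`, `rank`
#'   (1 = most important within the setting).
#' @export
permutation_importance <- function(table, seed = NULL, ntree = 300) {
  feats <- feature_names()
  with_seed(seed, {
    purrr::map_dfr(sort(unique(table$setting)), function(s) {
      sub <- table[table$setting == s, ]
      y <- factor(sub$chose_innovation, levels = c(FALSE, TRUE))
      if (length(unique(y)) < 2) {
        warn(paste0("Setting ", s, " has a single decision class; importance is undefined."))
        return(tibble(setting = s, feature = feats,
                      importance = NA_real_, rank = NA_integer_))
      }
      constant <- vapply(feats, function(f) sd(sub[[f]]) == 0, logical(1))
      if (any(constant)) {
        warn(paste0("Constant feature(s) in setting ", s, ": ",
                    paste(feats[constant], collapse = ", "),
                    "; importance will be ~ 0."))
      }
      m <- randomForest::randomForest(
        x = as.data.frame(sub[, feats]), y = y,
        ntree = ntree, importance = TRUE
      )
      imp <- randomForest::importance(m, type = 1, scale = FALSE)[, 1]
      tibble(
        setting = s, feature = feats,
        importance = unname(imp[feats]),
        rank = rank(-imp[feats], ties.method = "first")
      )
    })
  })
}
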