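#' Write and read session round records
#'
#' Tidy CSV with one round record per line (the flattened display columns
#' produced by [simulate_setting()]) plus a `schema_version` column.
#'
#' @param records Round records tibble.
#' @param path CSV file path.
#' @return `path` invisibly (writer); the records tibble (reader).
#' @export
write_session_csv <- function(records, path) {
  out <- dplyr::mutate(records, schema_version = schema_version())
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_integer(),
      setting = readr::col_character(),
      display_distance = readr::col_integer(),
      round = readr::col_integer(),
      node = readr::col_integer(),
      role = readr::col_character(),
      active = readr::col_logical(),
      chose_innovation = readr::col_logical(),
      color = readr::col_character(),
      f_direct = readr::col_double(),
      f_distant = readr::col_double(),
      d1 = readr::col_integer(), d2 = readr::col_integer(),
      k1 = readr::col_integer(), k2 = readr::col_integer(),
      d1_innov = readr::col_logical(), d2_innov = readr::col_logical(),
      k1_innov = readr::col_logical(), k2_innov = readr::col_logical(),
      schema_version = readr::col_character()
    )
  ) |>
    dplyr::select(-"schema_version")
}

#' Write and read adoption curves
#'
#' CSV with columns `session_id`, `setting`, `round`, `proportion`.
#'
#' @param curve A tibble from [observed_curve()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); the curve tibble (reader).
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(curve, path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_integer(),
    setting = readr::col_character(),
    round = readr::col_integer(),
    proportion = readr::col_double()
  ))
}
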