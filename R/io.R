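#' Read and write tidy time-course tables
#'
#' Time courses travel as tidy CSV with columns `background`, `time_s`,
#' `species`, `mean_copies`, `sem`, `n_cells`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_timecourse_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    background = readr::col_character(),
                    species = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname read_timecourse_csv
#' @param data Tidy time-course tibble.
#' @export
write_timecourse_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write rate constants as JSON
#'
#' @param path File path.
#' @return A [rate_constants()] object.
#' @export
read_rate_constants_json <- function(path) {
  do.call(rate_constants, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_rate_constants_json
#' @param params A [rate_constants()] object.
#' @export
write_rate_constants_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write localization tables
#'
#' Localizations travel as CSV with columns `x_nm`, `y_nm`, `z_nm`,
#' `channel`, `cell_id`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_localizations_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    channel = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname read_localizations_csv
#' @param data Localization tibble.
#' @export
write_localizations_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
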