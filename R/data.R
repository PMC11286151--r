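#' Assemble a state/driver time-series table for cusp modelling
#'
#' Validates and standardises the table that every fitting function in the
#' package consumes: one observed state variable (e.g. spawning stock
#' biomass, or a PC1 score summarising a community matrix) and two candidate
#' control drivers, observed at equally spaced time steps. The first driver
#' (`driver_a`) is the candidate *asymmetry* driver (e.g. fishing pressure),
#' the one expected to push the system between alternative states; the
#' second (`driver_b`) is the candidate *bifurcation* driver (e.g.
#' temperature), the one expected to fold the response from continuous to
#' discontinuous.
#'
#' @param data A data frame with one row per time step.
#' @param time,state,driver_a,driver_b Column names (unquoted or as strings)
#'   holding the time index, the state variable and the two drivers.
#'   Defaults are the column names themselves.
#' @return A tibble of class `cusp_data` with columns `time`, `state`,
#'   `driver_a`, `driver_b`.
#' @examples
#' df <- data.frame(time = 1:20, state = rnorm(20),
#'                  driver_a = rnorm(20), driver_b = rnorm(20))
#' cusp_data(df)
#' @export
cusp_data <- function(data, time = "time", state = "state",
                      driver_a = "driver_a", driver_b = "driver_b") {
  stopifnot(is.data.frame(data))
  cols <- c(
    time = rlang::as_name(rlang::ensym(time)),
    state = rlang::as_name(rlang::ensym(state)),
    driver_a = rlang::as_name(rlang::ensym(driver_a)),
    driver_b = rlang::as_name(rlang::ensym(driver_b))
  )
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cuspra_input_error")
  }
  out <- tibble::tibble(
    time = data[[cols[["time"]]]],
    state = as.numeric(data[[cols[["state"]]]]),
    driver_a = as.numeric(data[[cols[["driver_a"]]]]),
    driver_b = as.numeric(data[[cols[["driver_b"]]]])
  )
  validate_cusp_data(out)
  class(out) <- c("cusp_data", class(out))
  out
}

validate_cusp_data <- function(x) {
  n <- nrow(x)
  if (n < 10) {
    abort(sprintf("need at least 10 time steps, got %d", n),
          class = "cuspra_input_error")
  }
  bad <- !complete.cases(x[c("state", "driver_a", "driver_b")]) |
    !is.finite(x$state) | !is.finite(x$driver_a) | !is.finite(x$driver_b)
  if (any(bad)) {
    abort(paste0("missing or non-finite values in rows: ",
                 paste(utils::head(which(bad), 10), collapse = ", ")),
          class = "cuspra_input_error")
  }
  tt <- as.numeric(x$time)
  if (anyNA(tt) || any(diff(tt) <= 0)) {
    abort("`time` must be strictly increasing with no missing values",
          class = "cuspra_input_error")
  }
  if (n > 2) {
    steps <- diff(tt)
    if (max(steps) - min(steps) > 1e-8 * max(abs(steps))) {
      abort("`time` must be equally spaced", class = "cuspra_input_error")
    }
  }
  for (col in c("state", "driver_a", "driver_b")) {
    if (sd(x[[col]]) == 0) {
      abort(sprintf("`%s` has zero variance", col),
            class = "cuspra_input_error")
    }
  }
  invisible(x)
}

as_cusp_data <- function(data) {
  if (inherits(data, "cusp_data")) {
    validate_cusp_data(data)
    return(data)
  }
  cusp_data(data)
}

#' Read a state/driver time series from a delimited text file
#'
#' Thin wrapper around [readr::read_delim()] that maps user-named columns
#' onto the `cusp_data` layout and reports offending rows when values are
#' missing.
#'
#' @inheritParams cusp_data
#' @param file Path to a CSV/TSV file with a header row.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` gives tab, anything else comma).
#' @return A `cusp_data` tibble.
#' @export
read_cusp_data <- function(file, time = "time", state = "state",
                           driver_a = "driver_a", driver_b = "driver_b",
                           delim = NULL) {
  if (!file.exists(file)) {
    abort(paste0("cannot read input file: ", file),
          class = "cuspra_input_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  cusp_data(raw,
            time = !!rlang::ensym(time), state = !!rlang::ensym(state),
            driver_a = !!rlang::ensym(driver_a),
            driver_b = !!rlang::ensym(driver_b))
}
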