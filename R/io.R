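#' Read a dataset from delimited text
#'
#' Accepts CSV or whitespace-delimited text with a header row. For
#' univariate data the file is a single numeric column; for regression the
#' response is the column named by `response` (default: a column named
#' `y`, otherwise the first column) and every remaining column is a
#' covariate. Non-numeric or missing cells are reported with their row
#' number.
#'
#' @param path file path.
#' @param response response column name, or `NULL` for the default rule.
#' @return a [div_data()].
#' @export
read_dataset <- function(path, response = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset file: ", path)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", names(df)[j], "', row ",
             bad[1L])
      df[[j]] <- vn
    }
    if (anyNA(df[[j]]))
      stop("missing value in column '", names(df)[j], "', row ",
           which(is.na(df[[j]]))[1L])
  }
  rcol <- if (!is.null(response)) {
    if (!response %in% names(df))
      stop("no column named '", response, "' in ", path)
    response
  } else if ("y" %in% names(df)) "y" else names(df)[1L]
  y <- df[[rcol]]
  Xdf <- df[setdiff(names(df), rcol)]
  X <- if (length(Xdf)) as.matrix(Xdf) else NULL
  div_data(y, X, note = path)
}

#' Serialize and restore results as JSON
#'
#' [div_select()][select_gamma()] selections, [div_fit()] fits and
#' [run_study()] summaries are written as JSON with full double precision
#' (17 significant digits) so that a written result re-parses to an equal
#' object.
#'
#' @param x a `div_fit`, `div_select` or `scenario_summary` object.
#' @param path output file path.
#' @return `write_result_json()` returns `path` invisibly;
#'   `read_result_json()` returns the parsed list.
#' @export
write_result_json <- function(x, path) {
  obj <- if (inherits(x, "div_select")) {
    list(type = "selection", kind = x$kind, family = x$family,
         gamma_grid = x$gamma_grid, h_scores = x$h_scores,
         gamma_opt = x$gamma_opt,
         params_opt = as.list(x$fit_opt$params),
         skipped = x$skipped, lambda = x$lambda)
  } else if (inherits(x, "div_fit")) {
    list(type = "fit", kind = x$kind, family = x$family, gamma = x$gamma,
         params = as.list(x$params), objective = x$objective,
         converged = x$converged, iterations = x$iterations,
         grad_norm = x$grad_norm, lambda = x$lambda)
  } else if (inherits(x, "scenario_summary")) {
    sc <- x$scenario
    list(type = "study",
         scenario = list(family = sc$family$id,
                         params = as.list(sc$params), n = sc$n,
                         omega = sc$omega, shift = sc$shift),
         R = x$R, R_effective = vapply(x$estimators, `[[`, 0L,
                                       "R_effective"),
         seed = x$seed, scale = x$scale,
         estimators = lapply(x$estimators, function(e)
           e[!vapply(e, is.null, TRUE)]),
         failures = as.list(x$failures))
  } else stop("cannot serialize object of class ", class(x)[1L])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
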