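#' Read a reporter time-series table
#'
#' Accepts the canonical long format (columns \code{strain}, \code{reporter},
#' \code{time_h}, \code{mean_cps}, \code{sd_cps}, \code{n}) or a wide format
#' with a \code{time_h} column plus one column per series named
#' \code{strain.reporter} (means only). Validates the schema and per-series
#' invariants with row-level diagnostics.
#'
#' @param path CSV file path.
#' @return Long-format data.frame.
#' @export
readTimeseries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_cols <- c("strain", "reporter", "time_h", "mean_cps", "sd_cps", "n")
  if (all(long_cols %in% names(d))) {
    d <- d[, long_cols]
  } else if ("time_h" %in% names(d)) {
    series_cols <- setdiff(names(d), "time_h")
    if (length(series_cols) == 0 || !all(grepl("\\.", series_cols)))
      stop("wide format requires columns named <strain>.<reporter>")
    d <- do.call(rbind, lapply(series_cols, function(cl) {
      parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
      data.frame(strain = parts[1], reporter = parts[2], time_h = d$time_h,
                 mean_cps = d[[cl]], sd_cps = 0, n = 1L,
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("file must have columns ", paste(long_cols, collapse = ", "),
         " (long) or time_h plus <strain>.<reporter> columns (wide)")
  }
  num <- c("time_h", "mean_cps", "sd_cps", "n")
  for (cl in num) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[cl]]))))
    if (length(bad) > 0)
      stop("non-numeric or missing value in column '", cl, "' at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    d[[cl]] <- as.numeric(d[[cl]])
  }
  bad_sd <- which(d$sd_cps < 0)
  if (length(bad_sd) > 0)
    stop("negative SD at row(s) ", paste(head(bad_sd, 5), collapse = ", "))
  if (any(d$n < 1)) stop("replicate count n must be >= 1")
  key <- paste(d$strain, d$reporter, d$time_h)
  if (anyDuplicated(key))
    stop("duplicate (strain, reporter, time) at row(s) ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))
  d <- d[order(d$strain, d$reporter, d$time_h), ]
  for (k in unique(paste(d$strain, d$reporter))) {
    sub <- d[paste(d$strain, d$reporter) == k, ]
    if (any(diff(sub$time_h) <= 0))
      stop("non-increasing time grid in series ", k)
  }
  rownames(d) <- NULL
  d$n <- as.integer(d$n)
  d
}

#' @rdname readTimeseries
#' @param dataset long-format data.frame to write.
#' @export
writeTimeseries <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' Read/write kinetic parameters as two-column delimited text
#'
#' Tab-separated name/value tables with a header line naming the units
#' (rates per hour, concentrations in a.u.). Unknown names are rejected
#' against the model's parameter registry with nearest-name suggestions;
#' missing parameters are an error.
#'
#' @param path file path.
#' @return \code{readParams} returns a \code{ClockParameters} object.
#' @export
readParams <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("name", "value") %in% names(d)))
    stop("parameter file must have columns 'name' and 'value'")
  clockParameters(setNames(as.numeric(d$value), d$name))
}

#' @rdname readParams
#' @param params a \code{ClockParameters} object or named vector to write.
#' @export
writeParams <- function(params, path) {
  params <- .asParams(params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# clock model kinetic parameters",
               "# units: rates per hour; concentrations and Michaelis constants in a.u.;",
               "#        light coupling per hour per light a.u."), con)
  utils::write.table(data.frame(name = names(params),
                                value = as.numeric(params)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
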