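#' Counting-process (start/stop) event-history data
#'
#' Validates and normalizes long-format survival data: one row per subject
#' interval with columns `id`, `start`, `stop`, `event` (0/1, attributed to
#' the interval's stop time) and any number of covariate columns whose values
#' are constant on the interval (last observation carried forward between
#' measurement updates).  The at-risk convention throughout the package is
#' left-open/right-closed: an interval `(start, stop]` covers time `t` iff
#' `start < t <= stop`.
#'
#' @param data `data.frame` with at least columns `id`, `start`, `stop`,
#'   `event`; remaining columns are treated as covariates.
#' @return The validated `data.frame`, ordered by `(id, start)`, with class
#'   `c("cpdata", "data.frame")` and attribute `"covariates"`.
#' @export
counting_process_data <- function(data) {
  data <- as.data.frame(data)
  req <- c("id", "start", "stop", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data$start <- as.numeric(data$start)
  data$stop <- as.numeric(data$stop)
  data$event <- as.integer(data$event)
  if (any(is.na(data$start) | is.na(data$stop))) {
    stop("start/stop must be numeric and non-missing", call. = FALSE)
  }
  bad <- which(data$start >= data$stop)
  if (length(bad)) {
    stop("start must be < stop; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (!all(data$event %in% c(0L, 1L))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  data <- data[order(data$id, data$start), , drop = FALSE]
  rownames(data) <- NULL
  # per-subject: non-overlapping intervals, event only on the last interval
  for (s in split(seq_len(nrow(data)), data$id)) {
    st <- data$start[s]; sp <- data$stop[s]; ev <- data$event[s]
    if (length(s) > 1 && any(st[-1] < sp[-length(s)] - 1e-12)) {
      stop("overlapping intervals for subject ", data$id[s[1]],
           "; offending row(s): ",
           paste(s[-1][st[-1] < sp[-length(s)] - 1e-12], collapse = ", "),
           call. = FALSE)
    }
    if (any(ev[-length(s)] == 1L)) {
      stop("event before the last interval for subject ", data$id[s[1]],
           call. = FALSE)
    }
  }
  covs <- setdiff(names(data), req)
  structure(data, covariates = covs, class = c("cpdata", "data.frame"))
}

#' Read/write counting-process CSV files
#'
#' CSV dialect: comma separator, `.` decimal, UTF-8, mandatory header with
#' columns `id`, `start`, `stop`, `event`, then covariates.
#'
#' @param path file path.
#' @return `read_counting_process_csv` returns a validated
#'   [counting_process_data()] object.
#' @export
read_counting_process_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counting_process_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param data a [counting_process_data()] object (or coercible data.frame).
#' @rdname read_counting_process_csv
#' @export
write_counting_process_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.cpdata <- function(x, ...) {
  out <- x
  attributes(out) <- list(names = names(x), row.names = attr(x, "row.names"),
                          class = "data.frame")
  out
}

# Logical at-risk index for time t under the (start, stop] convention.
at_risk_index <- function(data, t) data$start < t & t <= data$stop
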