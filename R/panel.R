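#' Longitudinal panel data on a common time grid
#'
#' Container for subjects x common discrete times x variables, with missing
#' entries allowed.  This is the input to the linear increment model: per-time
#' regressions of process increments on lagged process values.
#'
#' @param values 3-dimensional numeric array `n x T x V` (subjects, times,
#'   variables), or a long `data.frame` with columns `id`, `time`, `variable`,
#'   `value`.
#' @param ids,times,vars dimension names; taken from `dimnames(values)` or the
#'   long data when omitted.
#' @return Object of class `"panel_data"`: list with `ids`, `times`
#'   (strictly increasing numeric), `vars` and the `values` array.
#' @export
panel_data <- function(values, ids = NULL, times = NULL, vars = NULL) {
  if (is.data.frame(values)) {
    req <- c("id", "time", "variable", "value")
    miss <- setdiff(req, names(values))
    if (length(miss)) stop("long panel needs column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(values[c("id", "time", "variable")])) {
      stop("duplicate (id, time, variable) entries", call. = FALSE)
    }
    ids <- ids %||% sort(unique(values$id))
    times <- times %||% sort(unique(values$time))
    vars <- vars %||% sort(unique(as.character(values$variable)))
    arr <- array(NA_real_, dim = c(length(ids), length(times), length(vars)),
                 dimnames = list(as.character(ids), as.character(times), vars))
    arr[cbind(match(values$id, ids), match(values$time, times),
              match(as.character(values$variable), vars))] <- values$value
    values <- arr
  }
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be an n x T x V array or a long data.frame", call. = FALSE)
  }
  dn <- dimnames(values) %||% vector("list", 3)
  ids <- as.character(ids %||% dn[[1]] %||% seq_len(dim(values)[1]))
  times <- as.numeric(times %||% dn[[2]] %||% seq_len(dim(values)[2]))
  vars <- as.character(vars %||% dn[[3]] %||% paste0("V", seq_len(dim(values)[3])))
  if (length(ids) != dim(values)[1] || length(times) != dim(values)[2] ||
      length(vars) != dim(values)[3]) {
    stop("dimension names do not match the value array", call. = FALSE)
  }
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing with at least 2 points", call. = FALSE)
  }
  if (anyDuplicated(ids) || anyDuplicated(vars)) {
    stop("ids and variable names must be unique", call. = FALSE)
  }
  dimnames(values) <- list(ids, as.character(times), vars)
  # each variable observed for >= 1 subject at >= 2 consecutive times
  for (v in vars) {
    obs <- !is.na(values[, , v, drop = FALSE][, , 1, drop = TRUE])
    obs <- matrix(obs, length(ids), length(times))
    if (!any(obs[, -ncol(obs), drop = FALSE] & obs[, -1, drop = FALSE])) {
      stop(sprintf("variable '%s' is never observed at two consecutive times", v),
           call. = FALSE)
    }
  }
  structure(list(ids = ids, times = times, vars = vars, values = values),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("Panel: %d subjects, %d times (%g..%g), variables: %s; %d missing values\n",
              length(x$ids), length(x$times), min(x$times), max(x$times),
              paste(x$vars, collapse = ", "), nmiss))
  invisible(x)
}

#' Long-format view of a panel
#'
#' @param x a [panel_data()] object.
#' @param ... unused.
#' @return `data.frame` with columns `id`, `time`, `variable`, `value`
#'   (missing entries omitted).
#' @export
as.data.frame.panel_data <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  out <- data.frame(id = x$ids[idx[, 1]],
                    time = x$times[idx[, 2]],
                    variable = x$vars[idx[, 3]],
                    value = x$values[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id, out$time, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write panel CSV files
#'
#' Two layouts are accepted and produce identical objects: *long*
#' (`id, time, variable, value`) and *wide* (`id, time`, one column per
#' variable).  Empty cells in the wide layout are recorded as missing.
#'
#' @param path file path.
#' @param layout `"auto"` (detect from the header), `"long"` or `"wide"`.
#' @return `read_panel_csv` returns a [panel_data()] object.
#' @export
read_panel_csv <- function(path, layout = c("auto", "long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "auto") {
    layout <- if (all(c("variable", "value") %in% names(df))) "long" else "wide"
  }
  if (layout == "long") return(panel_data(df))
  if (!all(c("id", "time") %in% names(df))) {
    stop("wide panel needs columns id, time", call. = FALSE)
  }
  if (anyDuplicated(df[c("id", "time")])) {
    stop("duplicate (id, time) rows in wide panel", call. = FALSE)
  }
  vars <- setdiff(names(df), c("id", "time"))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(id = df$id, time = df$time, variable = v, value = df[[v]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  ids <- sort(unique(df$id))
  times <- sort(unique(df$time))
  panel_data(long, ids = ids, times = times, vars = vars)
}

#' @param panel a [panel_data()] object.
#' @param layout output layout, `"long"` or `"wide"`.
#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(panel, "panel_data"))
  if (layout == "long") {
    utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  } else {
    wide <- data.frame(id = rep(panel$ids, each = length(panel$times)),
                       time = rep(panel$times, times = length(panel$ids)))
    for (v in panel$vars) {
      wide[[v]] <- as.vector(t(matrix(panel$values[, , v],
                                      length(panel$ids), length(panel$times))))
    }
    utils::write.csv(wide, path, row.names = FALSE)
  }
  invisible(path)
}
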