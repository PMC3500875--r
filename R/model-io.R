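#' Read or write a linear-system model JSON file
#'
#' Schema: `{"schema": "dynpath-model/1", "labels": [...], "drift": [[...]],
#' "input": null | {"constant": [...]}, "noise_cov": [[...]]}`.  The drift is
#' row-major: `drift[i][j]` is the effect of process `j`'s level on process
#' `i`'s drift.
#'
#' @param path file path.
#' @return `read_sde_model` returns a [linear_sde()] object.
#' @export
read_sde_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$labels) || is.null(j$drift)) {
    stop("model JSON needs 'labels' and 'drift'", call. = FALSE)
  }
  as_row_matrix <- function(x, p) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = p, byrow = TRUE)
  }
  drift <- as_row_matrix(j$drift, length(j$labels))
  input <- NULL
  if (!is.null(j$input) && !is.null(j$input$constant)) {
    input <- as.numeric(j$input$constant)
  }
  noise <- if (!is.null(j$noise_cov)) as_row_matrix(j$noise_cov, length(j$labels))
  linear_sde(drift, labels = as.character(j$labels), input = input,
             noise_cov = noise)
}

#' @param model a [linear_sde()] object.  Function-valued inputs cannot be
#'   serialized; only `NULL` or constant inputs are written.
#' @rdname read_sde_model
#' @export
write_sde_model <- function(model, path) {
  stopifnot(inherits(model, "linear_sde"))
  input <- NULL
  if (!is.null(model$input)) {
    const <- attr(model$input, "constant")
    if (is.null(const)) {
      stop("only constant inputs can be written to JSON", call. = FALSE)
    }
    input <- list(constant = const)
  }
  obj <- list(schema = "dynpath-model/1",
              labels = model$labels,
              drift = unname(model$drift),        # serialized as rows
              input = input,
              noise_cov = unname(model$noise_cov))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
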