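#' Write a tabular result with a provenance header
#'
#' Writes any of the pipeline's tabular outputs (lead matrices, rankings,
#' orderings, persistence diagrams, carpet counts) as a deterministic CSV
#' whose first line is a `#`-prefixed one-line JSON comment recording
#' provenance: the operation that produced the table, its parameters, the
#' seed (if any), and the package version. Values are printed with 17
#' significant digits so a write/read round trip is lossless to double
#' precision.
#'
#' @param obj a matrix (with column names) or data frame.
#' @param path output file path.
#' @param operation short name of the producing operation (stored in the
#'   provenance header).
#' @param parameters named list of parameters to record.
#' @param seed RNG seed to record, or `NULL`.
#' @return `path`, invisibly.
#' @seealso [read_ca_table()]
#' @export
write_ca_table <- function(obj, path, operation = class(obj)[1L],
                           parameters = list(), seed = NULL) {
  if (is.matrix(obj)) {
    df <- as.data.frame(obj, stringsAsFactors = FALSE)
    if (!is.null(colnames(obj))) names(df) <- colnames(obj)
  } else if (is.data.frame(obj)) {
    df <- obj
  } else {
    stop_ca("cyclicity_error_not_tabular", "cannot write a %s as a table", class(obj)[1L])
  }
  prov <- list(operation = operation, parameters = parameters,
               package = "cyclicity",
               version = as.character(utils::packageVersion("cyclicity")))
  if (!is.null(seed)) prov$seed <- seed
  fmt <- function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g") else as.character(col)
  }
  body <- do.call(cbind, lapply(df, fmt))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_ca("cyclicity_error_unwritable",
                                              "cannot open %s for writing", path))
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(prov, auto_unbox = TRUE, null = "null")), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L)
    writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a table written by [write_ca_table()]
#'
#' @param path file path.
#' @return a data frame; the parsed provenance header is attached as
#'   attribute `"provenance"`.
#' @export
read_ca_table <- function(path) {
  if (!file.exists(path))
    stop_ca("cyclicity_error_missing_file", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prov <- NULL
  if (length(lines) && startsWith(lines[1L], "#")) {
    prov <- jsonlite::fromJSON(sub("^#\\s*", "", lines[1L]))
    lines <- lines[-1L]
  }
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  if (length(body)) {
    cells <- strsplit(body, ",", fixed = TRUE)
    m <- do.call(rbind, cells)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- header
    for (j in seq_along(df)) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(num)) df[[j]] <- num
    }
  } else {
    df <- as.data.frame(matrix(nrow = 0L, ncol = length(header)))
    names(df) <- header
  }
  attr(df, "provenance") <- prov
  df
}
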