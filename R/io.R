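# Plain-text interchange: long CSV well/panel tables, GCT-like expression
# matrices with a parallel P/A calls table, GMT gene sets, GRP tag lists.

#' Read or write a plate well table
#'
#' Long CSV with columns `plate_id`, `row`, `col`, `role`, `compound_id`,
#' `concentration_uM`, `line_or_sample_id`, `fluorescence`.
#'
#' @param path File path.
#' @return `read_plate_csv()`: a well tibble.
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    row = readr::col_character(),
    col = readr::col_integer(),
    role = readr::col_character(),
    compound_id = readr::col_character(),
    concentration_uM = readr::col_double(),
    line_or_sample_id = readr::col_character(),
    fluorescence = readr::col_double()
  ))
}

#' @rdname read_plate_csv
#' @param wells Well tibble.
#' @export
write_plate_csv <- function(wells, path) {
  readr::write_csv(wells, path)
  invisible(path)
}

#' Read or write a GCT-like expression matrix
#'
#' Tab-delimited text: a `#1.2` version line, a dimensions line
#' (`n_probes n_conditions`), then a header `Name`, `Description`, one
#' column per condition, and one row per probe.
#'
#' @param path File path.
#' @return `read_gct()`: tibble with `probe_id`, `description`, one numeric
#'   column per condition.
#' @export
read_gct <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.")) {
    abort("not a GCT-like file: missing '#1.x' version line.")
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  body <- readr::read_tsv(I(lines[-(1:2)]), col_types = readr::cols(
    Name = readr::col_character(),
    Description = readr::col_character(),
    .default = readr::col_double()
  ))
  if (nrow(body) != dims[1]) {
    abort(sprintf("GCT header declares %d probes but %d rows found.",
                  dims[1], nrow(body)))
  }
  body %>% dplyr::rename(probe_id = "Name", description = "Description")
}

#' @rdname read_gct
#' @param mat Tibble with `probe_id`, optional `description`, and one
#'   numeric column per condition.
#' @export
write_gct <- function(mat, path) {
  mat <- tibble::as_tibble(mat)
  stopifnot("probe_id" %in% names(mat))
  if (!"description" %in% names(mat)) mat$description <- "na"
  value_cols <- setdiff(names(mat), c("probe_id", "description"))
  out <- mat %>% dplyr::select("probe_id", "description",
                               dplyr::all_of(value_cols))
  names(out)[1:2] <- c("Name", "Description")
  readr::write_lines(c("#1.2", paste(nrow(out), length(value_cols), sep = "\t")),
                     path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read or write a present/absent calls table
#'
#' Tab-delimited: `probe_id` plus one `P`/`A` flag column per condition.
#'
#' @param path File path.
#' @return `read_calls()`: tibble with `probe_id` and one logical column
#'   per condition (`TRUE` = present).
#' @export
read_calls <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_character()
  ))
  tbl %>% dplyr::mutate(dplyr::across(-"probe_id", ~ .x == "P"))
}

#' @rdname read_calls
#' @param calls Tibble with `probe_id` and logical columns.
#' @export
write_calls <- function(calls, path) {
  calls %>%
    dplyr::mutate(dplyr::across(-"probe_id", ~ ifelse(.x, "P", "A"))) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read or write GMT gene-set files
#'
#' One gene set per line: name, description, then member genes,
#' tab-separated. Reading delegates to `fgsea::gmtPathways()` when
#' available.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readr::read_lines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(!is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read or write GRP-style tag lists
#'
#' A signature is stored as two GRP files (one probe id per line): an up
#' list and a down list.
#'
#' @param up_path,down_path File paths for the up and down tag lists.
#' @return `read_signature()`: a `query_signature` list.
#' @export
read_signature <- function(up_path, down_path) {
  structure(
    list(up_tags = readr::read_lines(up_path),
         down_tags = readr::read_lines(down_path),
         n_filtered = NA_integer_),
    class = "query_signature"
  )
}

#' @rdname read_signature
#' @param signature A `query_signature`.
#' @export
write_signature <- function(signature, up_path, down_path) {
  readr::write_lines(signature$up_tags, up_path)
  readr::write_lines(signature$down_tags, down_path)
  invisible(c(up_path, down_path))
}
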