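#' Read a mixed-type table from CSV/TSV
#'
#' Reads every cell as text (typing happens downstream in
#' [preprocess()]), with the first row as header and, by default, the
#' first column as the sample-identifier index. The delimiter is inferred
#' from the file extension (`.tsv`/`.tab` means tab, otherwise comma)
#' unless given explicitly.
#'
#' @param path Path to the file.
#' @param delimiter Optional single-character delimiter.
#' @param id_col Column (name or position) holding sample identifiers;
#'   `NULL` for none. Default: the first column.
#' @return A tibble of character columns; the identifier column name is
#'   recorded in the `"id_col"` attribute.
#' @export
read_mixed_table <- function(path, delimiter = NULL, id_col = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t"
                 else ","
  }
  tab <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    name_repair = "minimal")
  if (anyDuplicated(names(tab))) {
    stop("duplicated header names: ",
         paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  }
  id_name <- NULL
  if (!is.null(id_col)) {
    id_name <- if (is.numeric(id_col)) names(tab)[id_col] else id_col
    if (!id_name %in% names(tab)) stop("id column '", id_name, "' not found")
    if (anyDuplicated(tab[[id_name]])) {
      stop("duplicated row identifiers in column '", id_name, "'")
    }
  }
  attr(tab, "id_col") <- id_name
  tab
}

# format numerics to at most 12 significant digits without scientific
# notation for integral values
format_cells <- function(col) {
  if (!is.numeric(col)) return(col)
  out <- vapply(col, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == round(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    format(v, digits = 12, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write the outputs of an imputation run
#'
#' Writes `imputed_clean.csv` (categories as original text, excluded
#' columns verbatim), `imputed_encoded.csv`, a JSON `manifest.json`
#' sufficient to reproduce the run (configuration echo, master seed,
#' column profiles and per-column records), and `run.log`.
#'
#' @param fit A `boostfill` object.
#' @param out_dir Output directory (created if needed).
#' @param input Optional path of the original input, echoed into the
#'   manifest.
#' @return Invisibly, the paths written.
#' @export
write_imputation <- function(fit, out_dir, input = NULL) {
  stopifnot(inherits(fit, "boostfill"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  add_id <- function(tab) {
    if (is.null(fit$ids)) return(tab)
    dplyr::bind_cols(stats::setNames(tibble::tibble(fit$ids), fit$id_col), tab)
  }
  clean <- add_id(tibble::as_tibble(purrr::map(fit$imputed_clean, format_cells)))
  encoded <- add_id(tibble::as_tibble(purrr::map(fit$imputed_encoded, format_cells)))

  paths <- file.path(out_dir, c("imputed_clean.csv", "imputed_encoded.csv",
                                "manifest.json", "run.log"))
  readr::write_csv(clean, paths[1], na = "")
  readr::write_csv(encoded, paths[2], na = "")

  manifest <- list(
    package = "boostfill",
    version = as.character(utils::packageVersion("boostfill")),
    input = input,
    config = unclass(fit$config),
    master_seed = fit$config$master_seed,
    factorization = fit$factorization,
    gate = if (is.null(fit$gate)) NULL else as.list(fit$gate[1, ]),
    profiles = fit$profiles |>
      dplyr::mutate(n_categories = purrr::map_int(
        .data$categories, ~ length(.x %||% character()))) |>
      dplyr::select(-"categories"),
    records = fit$records,
    excluded_columns = fit$excluded_columns,
    per_iteration_change = fit$per_iteration_change)
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(c(
    paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " run complete"),
    paste0("rows=", nrow(fit$imputed_clean),
           " cols=", ncol(fit$imputed_clean),
           " imputed_cells=", sum(fit$profiles$n_missing),
           " seed=", fit$config$master_seed)), paths[4])
  invisible(paths)
}
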