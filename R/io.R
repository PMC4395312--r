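# Trace-file dialect: one CSV per animal (per-section records) plus a JSON
# metadata sidecar. UTF-8, comma separators, "." decimal, header required.

.trace_cols <- c("section_index", "z_um", "record_type", "x", "y",
                 "pool_label", "order_index")
.record_types <- c("neuron", "lateral_edge", "central_canal", "optical_ref",
                   "axis")
.meta_cols <- c("animal_id", "genotype", "housing", "age_weeks")

sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0(".meta.json")
}

#' Write a serial-section trace series to disk
#'
#' Writes the canonical trace CSV (columns `section_index`, `z_um`,
#' `record_type`, `x`, `y`, `pool_label`, `order_index`) and a JSON metadata
#' sidecar (`<stem>.meta.json`) holding `animal_id`, `genotype`, `housing`,
#' `age_weeks` and the package version. Ground-truth columns produced by
#' [sim_series()] are not written unless `keep_truth = TRUE`.
#'
#' @param series A trace tibble.
#' @param path Output CSV path.
#' @param keep_truth Also write `neuron_id`, `x_true`, `y_true` columns.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, keep_truth = FALSE) {
  stopifnot(is.data.frame(series))
  cols <- .trace_cols
  if (keep_truth) {
    cols <- c(cols, intersect(c("neuron_id", "x_true", "y_true"), names(series)))
  }
  miss <- setdiff(.trace_cols, names(series))
  if (length(miss)) {
    stop_format(paste0("series is missing column(s): ", paste(miss, collapse = ", ")))
  }
  out <- series[, cols]
  # fixed 12-significant-digit decimals: re-reading and re-writing a trace
  # file reproduces it byte for byte
  for (cc in intersect(c("z_um", "x", "y", "x_true", "y_true"), cols)) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), NA_character_,
                        sprintf("%.12g", out[[cc]]))
  }
  readr::write_csv(out, path)
  meta <- lapply(intersect(.meta_cols, names(series)),
                 function(cc) series[[cc]][1])
  names(meta) <- intersect(.meta_cols, names(series))
  meta$package_version <- as.character(utils::packageVersion("motorpool"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_trace <- function(df, path = "<trace>") {
  # line numbers: header is line 1, data row i is line i + 1
  line_of <- function(rows) paste(rows + 1L, collapse = ", ")

  bad_type <- !(df$record_type %in% .record_types)
  if (any(bad_type)) {
    stop_format(sprintf(
      "%s: unknown record_type %s (line %s).", path,
      paste(unique(df$record_type[bad_type]), collapse = ", "),
      line_of(which(bad_type))))
  }
  for (col in c("section_index", "z_um", "x", "y")) {
    bad <- !is.finite(df[[col]])
    if (any(bad)) {
      stop_format(sprintf("%s: non-finite `%s` (line %s).", path, col,
                          line_of(which(bad))))
    }
  }
  counts <- df |>
    dplyr::count(.data$section_index, .data$record_type) |>
    tidyr::pivot_wider(names_from = "record_type", values_from = "n",
                       values_fill = 0L)
  for (spec in list(c("lateral_edge", 5), c("optical_ref", 4),
                    c("central_canal", 1), c("axis", 1))) {
    rt <- spec[1]; want <- as.integer(spec[2])
    got <- if (rt %in% names(counts)) counts[[rt]] else rep(0L, nrow(counts))
    bad <- which(got != want)
    if (length(bad)) {
      stop_format(sprintf(
        "%s: section %s has %d `%s` record(s), expected %d.",
        path, counts$section_index[bad[1]], got[bad[1]], rt, want))
    }
  }
  sec <- unique(df$section_index)
  if (is.unsorted(sec, strictly = TRUE)) {
    stop_format(sprintf("%s: section_index must be strictly increasing.", path))
  }
  invisible(df)
}

#' Read a serial-section trace series
#'
#' Reads a trace CSV in the documented dialect, merges the JSON metadata
#' sidecar if present, and validates the result: exactly 5 `lateral_edge`
#' and 4 `optical_ref` records plus one `central_canal` and one `axis`
#' record per section, finite coordinates, known record types, strictly
#' increasing section order. Violations are reported with their line
#' numbers. Unknown extra columns are kept with a warning (forward
#' compatibility).
#'
#' @param path Path to the trace CSV.
#' @return A validated trace tibble (with metadata columns when a sidecar
#'   exists).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such trace file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.trace_cols, names(df))
  if (length(miss)) {
    stop_format(sprintf("%s: missing column(s): %s", path,
                        paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(.trace_cols, "neuron_id", "x_true", "y_true"))
  if (length(extra)) {
    warn(sprintf("%s: unknown column(s) kept as-is: %s", path,
                 paste(extra, collapse = ", ")))
  }
  df$section_index <- as.integer(df$section_index)
  if ("order_index" %in% names(df)) df$order_index <- as.integer(df$order_index)
  validate_trace(df, path)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    for (cc in intersect(.meta_cols, names(meta))) {
      df[[cc]] <- if (cc == "age_weeks") as.integer(meta[[cc]]) else meta[[cc]]
    }
    df <- dplyr::relocate(df, dplyr::any_of(.meta_cols))
  }
  df
}
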