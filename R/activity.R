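ACTIVITY_COLS <- c("city_id", "province_id", "year", "category", "subclass",
                   "stock_head", "slaughtered_head", "source_flag")

#' Read and write activity panels
#'
#' An activity panel is a long table with one row per
#' (city, year, category, subclass): head counts of the stock population
#' (animals alive at year end) and the slaughtered population (animals
#' raised and killed within the year), plus a `source_flag` marking rows
#' as `observed` or `gapfilled`. Missing records are rows whose head
#' counts are `NA`. CSV is the native format; a single-sheet XLSX of
#' identical layout is accepted when the readxl package is installed.
#'
#' @param path CSV (or XLSX) file with columns `city_id`, `province_id`,
#'   `year`, `category`, `subclass`, `stock_head`, `slaughtered_head`,
#'   `source_flag`.
#' @return `read_activity_panel()`: a `data.table`;
#'   `write_activity_panel()`: `path`, invisibly.
#' @export
read_activity_panel <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package", call. = FALSE)
    dt <- as.data.table(readxl::read_excel(path, sheet = 1))
  } else {
    dt <- fread(path, colClasses = list(character = c(
      "city_id", "province_id", "category", "subclass", "source_flag")))
  }
  missing_cols <- setdiff(ACTIVITY_COLS, names(dt))
  if (length(missing_cols))
    stop("activity panel missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt[, year := as.integer(year)]
  dt[, stock_head := as.numeric(stock_head)]
  dt[, slaughtered_head := as.numeric(slaughtered_head)]
  dt[]
}

#' @rdname read_activity_panel
#' @param panel Activity panel `data.table`.
#' @export
write_activity_panel <- function(panel, path) {
  fwrite(panel[, ACTIVITY_COLS, with = FALSE], path)
  invisible(path)
}

#' Validate an activity panel
#'
#' Report-only structural check of a panel: duplicate
#' (city, year, category, subclass) keys, negative or non-finite head
#' counts, missing (city, year) cells relative to a declared city list and
#' year range, and the fraction of gap-filled records. A (city, year) cell
#' counts as present when at least one of its rows carries non-`NA` head
#' counts. The input is never modified.
#'
#' @param panel Activity panel `data.table`.
#' @param cities Declared city list; default: cities present in the panel.
#' @param years Declared year range; default: years present in the panel.
#' @return A list of class `ch4_panel_report`: `n_records`,
#'   `n_city_year_cells` (present cells), `n_missing_city_years`,
#'   `missing_city_years` (table), `duplicates` (table),
#'   `n_negative_counts`, `gapfilled_fraction`, `valid` (no duplicates and
#'   no negative counts).
#' @export
validate_activity_panel <- function(panel, cities = NULL, years = NULL) {
  panel <- as.data.table(panel)
  if (nrow(panel)) assert_category(panel$category)
  if (is.null(cities)) cities <- sort(unique(panel$city_id))
  if (is.null(years)) years <- sort(unique(panel$year))

  dup <- if (nrow(panel)) {
    panel[, .N, by = .(city_id, year, category, subclass)][N > 1L]
  } else data.table(city_id = character(), year = integer(),
                    category = character(), subclass = character(),
                    N = integer())

  n_neg <- if (nrow(panel)) {
    panel[, sum((!is.na(stock_head) & (stock_head < 0 | !is.finite(stock_head))) |
                (!is.na(slaughtered_head) &
                 (slaughtered_head < 0 | !is.finite(slaughtered_head))))]
  } else 0L

  declared <- CJ(city_id = cities, year = years)
  present <- if (nrow(panel)) {
    unique(panel[!is.na(stock_head) | !is.na(slaughtered_head),
                 .(city_id, year)])
  } else data.table(city_id = character(), year = integer())
  missing_cells <- declared[!present, on = c("city_id", "year")]

  gap_frac <- if (nrow(panel)) mean(panel$source_flag == "gapfilled") else NA_real_

  rep <- list(
    n_records = nrow(panel),
    n_city_year_cells = nrow(present),
    n_missing_city_years = nrow(missing_cells),
    missing_city_years = missing_cells,
    duplicates = dup,
    n_negative_counts = as.integer(n_neg),
    gapfilled_fraction = gap_frac,
    valid = nrow(dup) == 0L && n_neg == 0L
  )
  class(rep) <- "ch4_panel_report"
  rep
}

#' @export
print.ch4_panel_report <- function(x, ...) {
  cat("<activity panel report>\n")
  cat("  records:            ", x$n_records, "\n")
  cat("  (city, year) cells: ", x$n_city_year_cells, "present,",
      x$n_missing_city_years, "missing\n")
  cat("  duplicate keys:     ", nrow(x$duplicates), "\n")
  cat("  negative counts:    ", x$n_negative_counts, "\n")
  cat("  gapfilled fraction: ",
      if (is.na(x$gapfilled_fraction)) "NA"
      else sprintf("%.3f", x$gapfilled_fraction), "\n")
  invisible(x)
}
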