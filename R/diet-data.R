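#' Long-format stomach-content datasets
#'
#' A diet dataset is a long-format data frame with one row per prey item;
#' an individual (stomach) whose flushing yielded no prey is encoded by a
#' single row whose prey columns are all `NA`.  This keeps per-item linear
#' dimensions, which the volumetric composition (%V) needs, while remaining
#' a plain rectangular table that round-trips through CSV/TSV.
#'
#' Required columns (fixed names, documented here once and used everywhere):
#' `sample_id`, `species`, `sex` (`male`/`female`/`unknown`), `svl_mm`,
#' `hl_mm`, `mw_mm`, `bm_g`, `microhabitat`, `prey_order`, `prey_category`,
#' `prey_length_mm`, `prey_width_mm`.  A derived `prey_volume_mm3` column
#' (prolate-spheroid volume) is added on construction.
#'
#' @param df a data frame holding the columns above (`prey_volume_mm3`
#'   optional; it is recomputed).
#' @return an object of class `diet_dataset` (a data frame).
#' @seealso [read_diet_table()], [validate_diet()], [prolate_spheroid_volume()]
#' @export
#' @examples
#' d <- diet_dataset(data.frame(
#'   sample_id = "f1", species = "Microhyla heymonsi", sex = "male",
#'   svl_mm = 23.1, hl_mm = 6.9, mw_mm = 6.0, bm_g = 1.8, microhabitat = NA,
#'   prey_order = "Isoptera", prey_category = "Termitidae",
#'   prey_length_mm = 2.0, prey_width_mm = 1.0))
#' d$prey_volume_mm3
diet_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(diet_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("diet table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, union(diet_columns(), names(df)), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$sex <- as.character(df$sex)
  df$microhabitat <- as.character(df$microhabitat)
  df$prey_order <- blank_to_na(as.character(df$prey_order))
  df$prey_category <- blank_to_na(as.character(df$prey_category))
  for (col in c("svl_mm", "hl_mm", "mw_mm", "bm_g",
                "prey_length_mm", "prey_width_mm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  vol <- rep(NA_real_, nrow(df))
  ok <- !is.na(df$prey_length_mm) & !is.na(df$prey_width_mm) &
    df$prey_length_mm > 0 & df$prey_width_mm > 0
  if (any(ok)) {
    vol[ok] <- prolate_spheroid_volume(df$prey_length_mm[ok],
                                       df$prey_width_mm[ok])
  }
  df$prey_volume_mm3 <- vol
  rownames(df) <- NULL
  class(df) <- c("diet_dataset", "data.frame")
  df
}

diet_columns <- function() {
  c("sample_id", "species", "sex", "svl_mm", "hl_mm", "mw_mm", "bm_g",
    "microhabitat", "prey_order", "prey_category",
    "prey_length_mm", "prey_width_mm")
}

blank_to_na <- function(x) {
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' @export
print.diet_dataset <- function(x, ...) {
  cnt <- diet_counts(x)
  cat("Stomach-content diet dataset\n")
  cat(sprintf("  %d stomachs, %d prey items, %d species\n",
              sum(cnt$n_stomachs), sum(cnt$n_items), nrow(cnt)))
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  - %s: %d stomachs (%d empty), %d items\n",
                cnt$species[i], cnt$n_stomachs[i], cnt$n_empty[i],
                cnt$n_items[i]))
  }
  invisible(x)
}

# TRUE for rows that are empty-stomach markers rather than prey items
is_marker_row <- function(x) {
  is.na(x$prey_category) & is.na(x$prey_order)
}

#' Per-species stomach and prey-item counts
#'
#' @param x a [diet_dataset()].
#' @return data frame with columns `species`, `n_stomachs`, `n_empty`,
#'   `n_items`.
#' @export
diet_counts <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  sp <- sort(unique(x$species))
  out <- data.frame(species = sp, n_stomachs = 0L, n_empty = 0L,
                    n_items = 0L, stringsAsFactors = FALSE)
  marker <- is_marker_row(x)
  for (i in seq_along(sp)) {
    rows <- x$species == sp[i]
    ids <- unique(x$sample_id[rows])
    item_ids <- unique(x$sample_id[rows & !marker])
    out$n_stomachs[i] <- length(ids)
    out$n_empty[i] <- length(setdiff(ids, item_ids))
    out$n_items[i] <- sum(rows & !marker)
  }
  out
}

#' Read a long-format stomach-content table
#'
#' Reads CSV or TSV with a header row; lines starting with `#` are treated
#' as provenance comments and skipped.  Schema problems raise an error that
#' names the missing column; a non-numeric measurement raises an error that
#' names the column and the offending file line.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"tsv"`.
#' @return a [diet_dataset()].
#' @export
read_diet_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", quote = "\"",
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           check.names = FALSE, fill = FALSE,
                           encoding = "UTF-8")
  missing_cols <- setdiff(diet_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("diet table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("svl_mm", "hl_mm", "mw_mm", "bm_g",
                "prey_length_mm", "prey_width_mm")
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    v[v == "" | v == "NA"] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric value '%s' in column '%s' (data row %d of %s)",
        v[bad[1]], col, bad[1], path), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  diet_dataset(raw)
}

#' Write a diet dataset as CSV/TSV
#'
#' The written file is re-readable by [read_diet_table()] with no
#' information loss; numeric formatting is fixed (up to 15 significant
#' digits) so that a write/read/write cycle is byte-stable.
#'
#' @param x a [diet_dataset()].
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param header_comments optional character vector written as leading
#'   `#` comment lines (provenance).
#' @export
write_diet_table <- function(x, path, dialect = c("csv", "tsv"),
                             header_comments = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "diet_dataset"))
  sep <- if (dialect == "csv") "," else "\t"
  out <- as.data.frame(x)[, diet_columns(), drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments) > 0L) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(out, con, sep = sep, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "NA")
  invisible(path)
}

#' Validate a diet dataset
#'
#' Checks are non-mutating; findings are the return value, never a condition.
#' Errors: non-positive morphometric or prey measurements, a `sample_id`
#' used with conflicting species/morphometrics, an empty-stomach marker row
#' coexisting with item rows for the same stomach, a prey category mapped to
#' more than one order.  Warnings: empty stomachs, items wider than long
#' (recorded as measured, but flagged), unknown sex, items with missing
#' dimensions (counted in N and F but contributing no volume).
#'
#' @param x a [diet_dataset()].
#' @return data frame of findings with columns `level` (`"error"`/
#'   `"warning"`), `rule`, and `message`; zero rows when clean.
#' @export
validate_diet <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  findings <- list()
  add <- function(level, rule, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(level = level, rule = rule, message = message,
                 stringsAsFactors = FALSE)
  }
  marker <- is_marker_row(x)

  for (col in c("svl_mm", "hl_mm", "mw_mm", "bm_g")) {
    bad <- which(!is.na(x[[col]]) & x[[col]] <= 0)
    for (i in bad) add("error", "nonpositive_measurement",
                       sprintf("%s is %g for sample %s", col, x[[col]][i],
                               x$sample_id[i]))
  }
  for (col in c("prey_length_mm", "prey_width_mm")) {
    bad <- which(!marker & !is.na(x[[col]]) & x[[col]] <= 0)
    for (i in bad) add("error", "nonpositive_measurement",
                       sprintf("%s is %g (sample %s)", col, x[[col]][i],
                               x$sample_id[i]))
  }

  # a sample_id must describe one individual: constant species + morphometrics
  for (id in unique(x$sample_id)) {
    rows <- x[x$sample_id == id, , drop = FALSE]
    key <- unique(rows[, c("species", "sex", "svl_mm", "hl_mm", "mw_mm",
                           "bm_g")])
    if (nrow(key) > 1L) {
      add("error", "conflicting_duplicate_id",
          sprintf("sample_id %s has conflicting individual records", id))
    }
    m <- is_marker_row(rows)
    if (any(m) && any(!m)) {
      add("error", "marker_with_items",
          sprintf("sample_id %s mixes an empty-stomach row with prey rows",
                  id))
    }
    if (all(m)) add("warning", "empty_stomach",
                    sprintf("stomach %s contained no prey", id))
  }

  cat_order <- unique(x[!marker, c("prey_category", "prey_order")])
  dup <- cat_order$prey_category[duplicated(cat_order$prey_category)]
  for (ct in unique(dup)) {
    add("error", "category_order_conflict",
        sprintf("prey category '%s' is assigned to multiple orders", ct))
  }

  wl <- which(!marker & !is.na(x$prey_width_mm) & !is.na(x$prey_length_mm) &
                x$prey_width_mm > x$prey_length_mm)
  for (i in wl) add("warning", "width_exceeds_length",
                    sprintf("item in sample %s has W=%g > L=%g",
                            x$sample_id[i], x$prey_width_mm[i],
                            x$prey_length_mm[i]))
  unk <- unique(x$sample_id[is.na(x$sex) | !(x$sex %in% c("male", "female"))])
  for (id in unk) add("warning", "unknown_sex",
                      sprintf("sample %s has unknown sex", id))
  nodim <- which(!marker & (is.na(x$prey_length_mm) | is.na(x$prey_width_mm)))
  for (i in nodim) add("warning", "missing_dimensions",
                       sprintf("item in sample %s lacks dimensions; no volume",
                               x$sample_id[i]))

  if (length(findings) == 0L) {
    return(data.frame(level = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
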