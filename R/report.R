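# Pipeline runners behind the command-line interface.  Every output file
# carries a provenance comment header (tool version, seed, serialized run
# config), and deterministic commands are byte-identical on re-run.

provenance_lines <- function(seed, config_string) {
  c(sprintf("dietniche %s",
            as.character(utils::packageVersion("dietniche"))),
    sprintf("seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("config=%s", config_string))
}

write_csv_prov <- function(df, path, prov, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
  }
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", prov), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "NA")
  invisible(path)
}

#' Validate a diet table on disk
#'
#' Reads the table, runs [validate_diet()] and fails (an R error, hence a
#' non-zero CLI exit) if any error-level finding is present; warnings are
#' messaged.
#'
#' @param input path to a diet CSV/TSV.
#' @param dialect `"csv"` or `"tsv"`.
#' @return the findings data frame, invisibly.
#' @export
run_validate <- function(input, dialect = "csv") {
  d <- read_diet_table(input, dialect)
  f <- validate_diet(d)
  for (i in which(f$level == "warning")) {
    message("warning [", f$rule[i], "]: ", f$message[i])
  }
  if (any(f$level == "error")) {
    stop("validation failed: ",
         paste(f$message[f$level == "error"], collapse = "; "),
         call. = FALSE)
  }
  invisible(f)
}

#' Summarize a diet dataset into table-style reports
#'
#' Writes, per species, the dietary composition table (percentage columns
#' rounded to `digits`, a raw-precision JSON alongside) and the stomach
#' summary, plus one diversity/breadth table and the Pianka overlap matrix
#' for the whole assemblage.
#'
#' @param input path to a diet CSV/TSV (ignored when `dataset` is given).
#' @param outdir output directory, created if needed.
#' @param dataset an in-memory [diet_dataset()] (optional alternative to
#'   `input`).
#' @param level taxon resolution, `"category"` or `"order"`.
#' @param digits rounding for the CSV reports (raw JSON is unrounded).
#' @param dialect input dialect.
#' @return character vector of files written, invisibly.
#' @export
run_summarize <- function(input = NULL, outdir, dataset = NULL,
                          level = "category", digits = 2, dialect = "csv") {
  d <- if (!is.null(dataset)) dataset else read_diet_table(input, dialect)
  stopifnot(inherits(d, "diet_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sprintf("summarize level=%s digits=%d", level, digits)
  prov <- provenance_lines(NULL, cfg)
  files <- character()
  sp <- sort(unique(d$species))
  slug <- function(s) gsub("[^A-Za-z0-9]+", "_", s)

  raw <- list(config = cfg, species = list())
  for (s in sp) {
    tab <- category_table(d, s, level)
    f1 <- file.path(outdir, sprintf("composition_%s_%s.csv", slug(s), level))
    write_csv_prov(as.data.frame(tab), f1, prov, digits)
    ss <- stomach_summary(d, s)
    f2 <- file.path(outdir, sprintf("stomach_summary_%s.csv", slug(s)))
    ssd <- cbind(variable = rownames(ss), as.data.frame(ss))
    write_csv_prov(ssd, f2, prov, digits)
    files <- c(files, f1, f2)
    raw$species[[s]] <- list(composition = as.data.frame(tab),
                             stomach_summary = ssd,
                             n_stomachs = attr(ss, "n_stomachs"),
                             n_empty = attr(ss, "n_empty"))
  }
  div <- diversity_summary(d, level)
  f3 <- file.path(outdir, sprintf("diversity_breadth_%s.csv", level))
  write_csv_prov(div, f3, prov, digits)
  files <- c(files, f3)
  raw$diversity <- div

  if (length(sp) >= 2) {
    profs <- lapply(sp, function(s) diet_profile(d, s, level))
    O <- overlap_matrix(profs)
  } else {
    O <- matrix(1, 1, 1, dimnames = list(sp, sp))
  }
  f4 <- file.path(outdir, sprintf("overlap_matrix_%s.csv", level))
  write_csv_prov(cbind(species = rownames(O), as.data.frame(O)), f4, prov,
                 digits)
  files <- c(files, f4)
  raw$overlap <- O

  f5 <- file.path(outdir, sprintf("summary_%s.json", level))
  jsonlite::write_json(raw, f5, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f5)
  invisible(files)
}

#' Compare species diets: ANOSIM and NMDS
#'
#' Builds per-stomach matrices on both bases (abundance and volume), runs
#' the global ANOSIM and every pairwise ANOSIM, and the two-dimensional
#' NMDS ordination for each basis.  Results (r, p, permutation count,
#' seed, stress) go to a JSON file; NMDS coordinates to CSVs.
#'
#' @inheritParams run_summarize
#' @param n_permutations permutations for each ANOSIM (default 999).
#' @param seed integer seed; recorded in every output.
#' @return list with the ANOSIM and NMDS results, invisibly.
#' @export
run_compare <- function(input = NULL, outdir, dataset = NULL,
                        level = "category", n_permutations = 999,
                        seed = 1, dialect = "csv") {
  d <- if (!is.null(dataset)) dataset else read_diet_table(input, dialect)
  stopifnot(inherits(d, "diet_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sprintf("compare level=%s n_permutations=%d seed=%d", level,
                 n_permutations, seed)
  prov <- provenance_lines(seed, cfg)
  res <- list(config = cfg, seed = seed, n_permutations = n_permutations)

  for (basis in c("abundance", "volume")) {
    m <- build_taxon_matrix(d, basis, level)
    dd <- bray_curtis(m)
    groups <- attr(dd, "groups")
    global <- anosim_test(dd, groups, n_permutations, seed)
    pairs <- list()
    sp <- sort(unique(groups))
    if (length(sp) >= 2) {
      for (i in seq_len(length(sp) - 1)) for (j in seq(i + 1, length(sp))) {
        keep <- groups %in% c(sp[i], sp[j])
        sub <- unclass(dd)[keep, keep]
        attr(sub, "groups") <- groups[keep]
        a <- anosim_test(sub, groups[keep], n_permutations, seed)
        pairs[[paste(sp[i], "vs", sp[j])]] <-
          list(r = a$r, p = a$p)
      }
    }
    nm <- nmds_ordination(dd, dims = 2, seed = seed)
    coords <- data.frame(sample_id = rownames(nm$points),
                         species = groups, nm$points,
                         stringsAsFactors = FALSE)
    fc <- file.path(outdir, sprintf("nmds_%s_%s.csv", basis, level))
    write_csv_prov(coords, fc, prov)
    res[[basis]] <- list(
      anosim = list(r = global$r, p = global$p,
                    n_permutations = global$n_permutations,
                    seed = global$seed),
      anosim_pairwise = pairs,
      nmds = list(stress = nm$stress, converged = nm$converged,
                  dims = nm$dims, seed = nm$seed,
                  n_restarts = nm$n_restarts))
  }
  fj <- file.path(outdir, sprintf("comparison_%s.json", level))
  jsonlite::write_json(res, fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Simulate a stomach-content dataset and write it to disk
#'
#' @param output path of the CSV to write.
#' @param config a [generator_config()]; when `NULL` and
#'   `study_defaults = TRUE`, [default_study_config()] is used.
#' @param study_defaults use the packaged study-shaped configuration.
#' @param seed integer seed for the generator.
#' @param n_stomachs optional per-spec override (recycled across specs);
#'   must be >= 1.
#' @return the output path, invisibly.
#' @export
run_simulate <- function(output, config = NULL, study_defaults = is.null(config),
                         seed = 1, n_stomachs = NULL) {
  if (is.null(config)) {
    if (!study_defaults) stop("need a config or study_defaults = TRUE",
                              call. = FALSE)
    config <- default_study_config(seed)
  } else {
    config$seed <- as.integer(seed)
  }
  if (!is.null(n_stomachs)) {
    if (any(n_stomachs < 1)) stop("n_stomachs must be >= 1", call. = FALSE)
    n_stomachs <- rep_len(n_stomachs, length(config$specs))
    for (i in seq_along(config$specs)) {
      config$specs[[i]]$n_stomachs <- as.integer(n_stomachs[i])
    }
  }
  d <- generate_diet_data(config)
  cfg <- sprintf("simulate seed=%d specs=%s", config$seed,
                 paste(sprintf("%s:%d",
                               vapply(config$specs, `[[`, "", "species"),
                               vapply(config$specs, `[[`, 1L, "n_stomachs")),
                       collapse = ";"))
  write_diet_table(d, output,
                   header_comments = provenance_lines(config$seed, cfg))
  invisible(output)
}
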