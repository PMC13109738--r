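#' Correlation between predator morphometrics and diet quantities
#'
#' Thin wrappers around [stats::cor.test()] returning a uniform result
#' record.  `method = "pearson"` gives the product-moment r with a
#' two-sided t-test on n - 2 degrees of freedom; `method = "kendall_tau_b"`
#' gives Kendall's tau-b, (C - D) / sqrt((n0 - n1)(n0 - n2)) with tie
#' corrections, and a two-sided normal-approximation p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"kendall_tau_b"`.
#' @return object of class `cor_result`: `statistic`, `p`, `n`, `method`.
#' @export
#' @examples
#' morpho_correlation(1:10, 2 * (1:10) + 1)                 # r = 1
#' morpho_correlation(c(1, 2, 2, 3), c(1, 2, 3, 3), "kendall_tau_b")
morpho_correlation <- function(x, y, method = c("pearson", "kendall_tau_b")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  if (method == "pearson") {
    ht <- stats::cor.test(x, y, method = "pearson")
  } else {
    # exact = FALSE: normal approximation (with tie correction) throughout
    ht <- suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = FALSE))
  }
  structure(list(statistic = unname(ht$estimate), p = ht$p.value, n = n,
                 method = method),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  lab <- if (x$method == "pearson") "Pearson r" else "Kendall tau-b"
  cat(sprintf("%s = %.4f, p = %.4g (n = %d)\n", lab, x$statistic, x$p, x$n))
  invisible(x)
}

#' Per-individual morphometrics and stomach-content totals
#'
#' One row per flushed individual: species, sex, the four morphometrics,
#' the total prolate-spheroid volume of its stomach contents, and the item
#' count.  This is the tidy table behind the size-vs-diet correlation
#' analyses, and is exported as-is so any regression package can model it.
#'
#' @param x a [diet_dataset()].
#' @return data frame with columns `sample_id`, `species`, `sex`, `svl_mm`,
#'   `hl_mm`, `mw_mm`, `bm_g`, `total_volume_mm3`, `n_items`.
#' @export
individual_table <- function(x) {
  stopifnot(inherits(x, "diet_dataset"))
  marker <- is_marker_row(x)
  ids <- unique(x$sample_id)
  first <- x[match(ids, x$sample_id), , drop = FALSE]
  vol <- x$prey_volume_mm3
  vol[is.na(vol) | marker] <- 0
  total_v <- vapply(ids, function(id) sum(vol[x$sample_id == id]), numeric(1))
  n_items <- vapply(ids, function(id) sum(x$sample_id == id & !marker),
                    integer(1))
  data.frame(sample_id = ids, species = first$species, sex = first$sex,
             svl_mm = first$svl_mm, hl_mm = first$hl_mm,
             mw_mm = first$mw_mm, bm_g = first$bm_g,
             total_volume_mm3 = unname(total_v),
             n_items = unname(n_items),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kendall tau-b between SVL and total stomach-content volume, per species
#'
#' @param x a [diet_dataset()].
#' @return data frame with one row per species: `species`, `tau`, `p`, `n`.
#' @export
svl_volume_kendall <- function(x) {
  ind <- individual_table(x)
  sp <- sort(unique(ind$species))
  rows <- lapply(sp, function(s) {
    sub <- ind[ind$species == s & ind$n_items > 0, , drop = FALSE]
    ct <- morpho_correlation(sub$svl_mm, sub$total_volume_mm3,
                             "kendall_tau_b")
    data.frame(species = s, tau = ct$statistic, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
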