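#' Prolate-spheroid prey volume
#'
#' Prey items flushed from stomachs are approximated as prolate spheroids
#' with the measured maximum length as the long axis and the maximum width
#' as the two short axes: V = 4*pi/3 * (L/2) * (W/2)^2, in cubic millimetres
#' when L and W are in millimetres.
#'
#' @param length_mm maximum prey length (mm), strictly positive.
#' @param width_mm maximum prey width (mm), strictly positive.
#' @return volume in mm^3; vectorized over both arguments.
#' @export
#' @examples
#' prolate_spheroid_volume(2, 1)   # pi/3
#' prolate_spheroid_volume(5, 2)   # 10.47 mm^3
prolate_spheroid_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("prey dimensions must be finite and strictly positive",
         call. = FALSE)
  }
  4 * pi / 3 * (length_mm / 2) * (width_mm / 2)^2
}

#' Dietary composition table for one species
#'
#' Builds the per-prey-taxon composition table: occurrence count `F_count`
#' (number of stomachs containing the taxon), item count `N_count`, summed
#' volume `V_sum`, the percentage columns `pctF`, `pctN`, `pctV`, and the
#' index of relative importance `IRI = (pctF + pctN + pctV) / 3`.
#'
#' `pctF` is normalized over the total number of occurrence records, so the
#' column sums to 100 across taxa (the convention of the composition-table
#' layout this package reproduces).  The conventional per-stomach occurrence
#' percentage, `F_count / (number of non-empty stomachs) * 100`, is kept as
#' the secondary column `occ_pct`.  Empty stomachs are excluded from the F
#' denominator and contribute nothing to N or V, but remain counted in the
#' `n_stomachs` attribute.
#'
#' Items with missing linear dimensions count toward `F` and `N` but add no
#' volume; [validate_diet()] flags them.
#'
#' @param x a [diet_dataset()].
#' @param species species label present in `x`.
#' @param level `"category"` (finest identified taxon: family, larval bin or
#'   residual bin) or `"order"`.
#' @return a data frame of class `category_table` with one row per taxon,
#'   ordered by decreasing IRI, and attributes `species`, `level`,
#'   `n_stomachs`, `n_empty`.
#' @export
category_table <- function(x, species, level = c("category", "order")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "diet_dataset"))
  if (!species %in% x$species) {
    stop("species not present in dataset: ", species, call. = FALSE)
  }
  sub <- x[x$species == species, , drop = FALSE]
  marker <- is_marker_row(sub)
  items <- sub[!marker, , drop = FALSE]
  if (nrow(items) == 0L) {
    stop("no prey items recorded for species ", species, call. = FALSE)
  }
  lab <- if (level == "category") items$prey_category else items$prey_order
  lab[is.na(lab)] <- "Unidentified"
  vol <- items$prey_volume_mm3
  vol[is.na(vol)] <- 0

  taxa <- sort(unique(lab))
  F_count <- vapply(taxa, function(t)
    length(unique(items$sample_id[lab == t])), integer(1))
  N_count <- vapply(taxa, function(t) sum(lab == t), integer(1))
  V_sum <- vapply(taxa, function(t) sum(vol[lab == t]), numeric(1))

  pctF <- F_count / sum(F_count) * 100
  pctN <- N_count / sum(N_count) * 100
  pctV <- if (sum(V_sum) > 0) V_sum / sum(V_sum) * 100 else rep(0, length(taxa))
  IRI <- (pctF + pctN + pctV) / 3
  occ_pct <- F_count / length(unique(items$sample_id)) * 100

  ord <- items$prey_order[match(taxa, lab)]
  out <- data.frame(taxon = taxa, prey_order = ord,
                    F_count = F_count, N_count = N_count, V_sum = V_sum,
                    pctF = pctF, pctN = pctN, pctV = pctV, IRI = IRI,
                    occ_pct = occ_pct,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$IRI, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species") <- species
  attr(out, "level") <- level
  attr(out, "n_stomachs") <- length(unique(sub$sample_id))
  attr(out, "n_empty") <- length(unique(sub$sample_id)) -
    length(unique(items$sample_id))
  class(out) <- c("category_table", "data.frame")
  out
}

#' Index of relative importance from its percentage components
#'
#' IRI is the arithmetic mean of the three composition percentages, so each
#' taxon's importance reflects how often it occurs, how many items it
#' contributes and how much volume it contributes, on equal footing.
#'
#' @param pctF,pctN,pctV percentage components, each in \[0, 100\].
#' @return IRI on the percentage scale; vectorized.
#' @export
iri <- function(pctF, pctN, pctV) {
  stopifnot(all(pctF >= 0 & pctF <= 100), all(pctN >= 0 & pctN <= 100),
            all(pctV >= 0 & pctV <= 100))
  (pctF + pctN + pctV) / 3
}

#' Per-species stomach and prey-size summary
#'
#' Mean/SD/range of the per-stomach item count (empty stomachs count as
#' zero, so mean count times the number of stomachs equals the total item
#' count), and of prey width, length and volume pooled over items.
#'
#' @param x a [diet_dataset()].
#' @param species species label present in `x`.
#' @return data frame of class `stomach_summary` with rows `N`, `W`, `L`,
#'   `V` and columns `mean`, `sd`, `min`, `max`; attributes `species`,
#'   `n_stomachs`, `n_empty`, `n_items`.
#' @export
stomach_summary <- function(x, species) {
  stopifnot(inherits(x, "diet_dataset"))
  if (!species %in% x$species) {
    stop("species not present in dataset: ", species, call. = FALSE)
  }
  sub <- x[x$species == species, , drop = FALSE]
  marker <- is_marker_row(sub)
  items <- sub[!marker, , drop = FALSE]
  ids <- unique(sub$sample_id)
  counts <- vapply(ids, function(id) sum(items$sample_id == id), integer(1))
  stat <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  }
  out <- as.data.frame(rbind(
    N = stat(counts),
    W = stat(items$prey_width_mm),
    L = stat(items$prey_length_mm),
    V = stat(items$prey_volume_mm3)))
  attr(out, "species") <- species
  attr(out, "n_stomachs") <- length(ids)
  attr(out, "n_empty") <- sum(counts == 0L)
  attr(out, "n_items") <- nrow(items)
  class(out) <- c("stomach_summary", "data.frame")
  out
}

#' @export
print.category_table <- function(x, digits = 2, ...) {
  cat(sprintf("Dietary composition: %s (%s level, %d stomachs, %d empty)\n",
              attr(x, "species"), attr(x, "level"), attr(x, "n_stomachs"),
              attr(x, "n_empty")))
  y <- as.data.frame(x)
  for (col in c("V_sum", "pctF", "pctN", "pctV", "IRI", "occ_pct")) {
    y[[col]] <- round(y[[col]], digits)
  }
  print(y, ...)
  invisible(x)
}

#' @export
print.stomach_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Stomach summary: %s (%d stomachs, %d empty, %d items)\n",
              attr(x, "species"), attr(x, "n_stomachs"), attr(x, "n_empty"),
              attr(x, "n_items")))
  print(round(as.data.frame(x), digits), ...)
  invisible(x)
}
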