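#' Niche profiles: a species' proportion vector over prey taxa
#'
#' The resource axis is the set of prey taxa registered in a species' diet
#' (taxa with at least one item).  Proportions are numeric proportions
#' (shares of the item count), matching the definition of the p_i that
#' enter niche breadth and niche overlap.
#'
#' @param labels taxon labels.
#' @param counts non-negative integer item counts (optional when
#'   `proportions` given).
#' @param proportions proportions summing to 1 (derived from `counts` when
#'   omitted).
#' @param species species label carried along for reporting.
#' @param level resolution of the labels (`"category"` or `"order"`).
#' @return an object of class `niche_profile`.
#' @export
niche_profile <- function(labels, counts = NULL, proportions = NULL,
                          species = "", level = "category") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate taxon labels", call. = FALSE)
  if (is.null(proportions)) {
    if (is.null(counts)) stop("need counts or proportions", call. = FALSE)
    if (any(counts < 0) || sum(counts) <= 0) {
      stop("counts must be non-negative with positive sum", call. = FALSE)
    }
    proportions <- counts / sum(counts)
  } else {
    if (any(proportions < 0)) stop("negative proportion", call. = FALSE)
    s <- sum(proportions)
    if (abs(s - 1) > 1e-6) {
      # accept percentage-scale input (printed columns sum to 100 +/- a
      # rounding residue); anything else is a user error
      if (abs(s - 100) < 0.5) proportions <- proportions / 100
      else stop("proportions must sum to 1 (or 100 on the % scale)",
                call. = FALSE)
    }
    proportions <- proportions / sum(proportions)
  }
  # only taxa actually registered in the diet stay on the resource axis
  keep <- proportions > 0
  structure(list(species = species, level = level,
                 labels = labels[keep],
                 counts = if (!is.null(counts)) counts[keep] else NULL,
                 proportions = proportions[keep]),
            class = "niche_profile")
}

#' Build a niche profile from a diet dataset
#'
#' @param x a [diet_dataset()].
#' @param species species label present in `x`.
#' @inheritParams category_table
#' @return a [niche_profile()] over the taxa registered for that species.
#' @export
diet_profile <- function(x, species, level = c("category", "order")) {
  level <- match.arg(level)
  tab <- category_table(x, species, level)
  niche_profile(tab$taxon, counts = tab$N_count, species = species,
                level = level)
}

#' @export
print.niche_profile <- function(x, ...) {
  cat(sprintf("Niche profile: %s (%s level, %d taxa)\n", x$species, x$level,
              length(x$labels)))
  v <- round(x$proportions, 4)
  names(v) <- x$labels
  print(v, ...)
  invisible(x)
}

#' Simpson heterogeneity index (finite-sample form)
#'
#' D = sum(n_i (n_i - 1)) / (N (N - 1)) is the probability that two prey
#' items drawn without replacement belong to the same taxon; 1 - D is the
#' dietary heterogeneity reported per species.
#'
#' @param counts non-negative integer item counts per taxon, total >= 2.
#' @return list with `D` and `one_minus_D`.
#' @export
simpson_index <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- sum(counts)
  if (N < 2) stop("need at least two items in total", call. = FALSE)
  D <- sum(counts * (counts - 1)) / (N * (N - 1))
  list(D = D, one_minus_D = 1 - D)
}

#' Shannon diversity H'
#'
#' H' = -sum(p_i log p_i), natural logarithm; zero-proportion taxa are
#' skipped.
#'
#' @param proportions proportion vector summing to 1 (counts are accepted
#'   and normalized).
#' @return H' (>= 0).
#' @export
shannon_index <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(p < 0)) stop("negative proportion", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("empty profile", call. = FALSE)
  if (abs(s - 1) > 1e-6 && all(p == floor(p))) p <- p / s
  else if (abs(s - 1) > 1e-6) stop("proportions must sum to 1", call. = FALSE)
  else p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon evenness J'
#'
#' J' = H' / ln S, the observed diversity relative to its maximum over S
#' taxa.  S is passed explicitly because the choice of S (taxa registered
#' for the species vs. a pooled taxon list) changes J' and must be visible.
#'
#' @param H Shannon diversity.
#' @param S number of taxa, >= 2.
#' @return J' in \[0, 1\].
#' @export
evenness <- function(H, S) {
  if (S < 2) stop("evenness needs S >= 2 taxa", call. = FALSE)
  if (H < 0) stop("negative H", call. = FALSE)
  H / log(S)
}

#' Levins standardized trophic niche breadth
#'
#' B = 1 / sum(p_i^2) over the n resource taxa registered in the diet, and
#' B_sta = (B - 1) / (n - 1) rescales it to \[0, 1\]: values near 0 mark a
#' specialist, values near 1 a generalist spreading its diet evenly.
#'
#' @param proportions diet proportion vector (p_i) over the registered
#'   taxa; must sum to 1 (a percentage-scale vector summing to 100 is
#'   accepted).  Taxa with p_i = 0 are not registered and are dropped
#'   before n is counted.
#' @return list with `B`, `n`, `B_sta`.
#' @export
#' @examples
#' levins_breadth(rep(1 / 4, 4))  # uniform: B = n, B_sta = 1
levins_breadth <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(p < 0)) stop("negative proportion", call. = FALSE)
  s <- sum(p)
  if (abs(s - 100) < 0.5) p <- p / 100
  else if (abs(s - 1) > 1e-6) stop("proportions must sum to 1 or 100",
                                   call. = FALSE)
  p <- p / sum(p)
  p <- p[p > 0]
  n <- length(p)
  if (n < 2) stop("niche breadth needs at least two registered taxa",
                  call. = FALSE)
  B <- 1 / sum(p^2)
  list(B = B, n = n, B_sta = (B - 1) / (n - 1))
}

#' Pianka pairwise niche overlap
#'
#' O_jk = sum(P_ij P_ik) / sqrt(sum(P_ij^2) sum(P_ik^2)) over the union of
#' the two species' prey taxa (taxa absent from one diet enter with
#' proportion zero).  The index is the cosine of the angle between the two
#' proportion vectors, hence bounded in \[0, 1\]: 0 for disjoint diets, 1
#' for proportionally identical ones.
#'
#' @param profile_j,profile_k [niche_profile()] objects at the same level.
#' @return overlap in \[0, 1\].
#' @export
pianka_overlap <- function(profile_j, profile_k) {
  stopifnot(inherits(profile_j, "niche_profile"),
            inherits(profile_k, "niche_profile"))
  u <- union(profile_j$labels, profile_k$labels)
  pj <- profile_j$proportions[match(u, profile_j$labels)]
  pk <- profile_k$proportions[match(u, profile_k$labels)]
  pj[is.na(pj)] <- 0
  pk[is.na(pk)] <- 0
  nj <- sum(pj^2)
  nk <- sum(pk^2)
  if (nj == 0 || nk == 0) stop("zero-norm niche profile", call. = FALSE)
  sum(pj * pk) / sqrt(nj * nk)
}

#' Pairwise niche-overlap matrix
#'
#' @param profiles list of two or more [niche_profile()] objects.
#' @return symmetric matrix of Pianka overlaps with unit diagonal, rows and
#'   columns named by species.
#' @export
overlap_matrix <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  sp <- vapply(profiles, function(p) p$species, character(1))
  k <- length(profiles)
  O <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      O[i, j] <- O[j, i] <- pianka_overlap(profiles[[i]], profiles[[j]])
    }
  }
  dimnames(O) <- list(sp, sp)
  O
}

#' Diversity, evenness and niche-breadth table for all species
#'
#' Convenience wrapper producing one row per species: finite-sample Simpson
#' heterogeneity (1 - D), Shannon H', the taxon count S used for evenness
#' (the number of taxa registered for that species at the chosen level),
#' J' = H'/ln S, Levins B and B_sta.
#'
#' @param x a [diet_dataset()].
#' @inheritParams category_table
#' @return data frame with one row per species.
#' @export
diversity_summary <- function(x, level = c("category", "order")) {
  level <- match.arg(level)
  stopifnot(inherits(x, "diet_dataset"))
  sp <- sort(unique(x$species))
  rows <- lapply(sp, function(s) {
    pr <- diet_profile(x, s, level)
    si <- simpson_index(pr$counts)
    H <- shannon_index(pr$proportions)
    S <- length(pr$labels)
    lv <- if (S >= 2) levins_breadth(pr$proportions) else
      list(B = NA_real_, n = S, B_sta = NA_real_)
    data.frame(species = s, one_minus_D = si$one_minus_D, H = H, S = S,
               J = if (S >= 2) evenness(H, S) else NA_real_,
               B = lv$B, B_sta = lv$B_sta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
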