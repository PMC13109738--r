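#' Per-stomach sample-by-taxon matrix
#'
#' One row per non-empty stomach, one column per prey taxon at the chosen
#' resolution; cells hold item counts (`value = "abundance"`) or summed
#' prolate-spheroid volumes in mm^3 (`value = "volume"`).  Empty stomachs
#' cannot enter a Bray-Curtis analysis (zero row sum) and are dropped with
#' a message.
#'
#' @param x a [diet_dataset()].
#' @param value `"abundance"` or `"volume"`.
#' @inheritParams category_table
#' @return a numeric matrix with `sample_id` rownames, taxon colnames, and
#'   attribute `groups` (the species of each row); class `taxon_matrix`.
#' @export
build_taxon_matrix <- function(x, value = c("abundance", "volume"),
                               level = c("category", "order")) {
  value <- match.arg(value)
  level <- match.arg(level)
  stopifnot(inherits(x, "diet_dataset"))
  marker <- is_marker_row(x)
  items <- x[!marker, , drop = FALSE]
  if (nrow(items) == 0L) stop("no non-empty stomachs", call. = FALSE)
  n_empty <- length(setdiff(unique(x$sample_id), unique(items$sample_id)))
  if (n_empty > 0L) {
    message(n_empty, " empty stomach(s) dropped from the sample-by-taxon matrix")
  }
  lab <- if (level == "category") items$prey_category else items$prey_order
  lab[is.na(lab)] <- "Unidentified"
  cell <- if (value == "abundance") rep(1, nrow(items)) else {
    v <- items$prey_volume_mm3
    v[is.na(v)] <- 0
    v
  }
  ids <- unique(items$sample_id)
  taxa <- sort(unique(lab))
  m <- matrix(0, nrow = length(ids), ncol = length(taxa),
              dimnames = list(ids, taxa))
  ri <- match(items$sample_id, ids)
  ci <- match(lab, taxa)
  for (k in seq_along(ri)) m[ri[k], ci[k]] <- m[ri[k], ci[k]] + cell[k]
  attr(m, "groups") <- items$species[match(ids, items$sample_id)]
  attr(m, "value") <- value
  attr(m, "level") <- level
  class(m) <- c("taxon_matrix", class(m))
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' d_jk = sum|x_ij - x_ik| / sum(x_ij + x_ik) over taxa i, for every pair
#' of stomachs; 0 for identical compositions, 1 for disjoint ones.
#'
#' @param m a [build_taxon_matrix()] result or any non-negative numeric
#'   matrix with samples in rows.
#' @return symmetric matrix of class `dissim_matrix` with zero diagonal and
#'   entries in \[0, 1\]; the `groups` attribute of `m` is carried over.
#' @export
bray_curtis <- function(m) {
  v <- unclass(m)
  attr(v, "groups") <- NULL
  if (any(v < 0)) stop("negative abundance/volume entry", call. = FALSE)
  rs <- rowSums(v)
  if (any(rs == 0)) {
    stop("all-zero row(s): ",
         paste(rownames(v)[rs == 0], collapse = ", "), call. = FALSE)
  }
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    xi <- v[i, ]
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(abs(xi - v[j, ])) / (rs[i] + rs[j])
    }
  }
  attr(d, "groups") <- attr(m, "groups")
  class(d) <- c("dissim_matrix", class(d))
  d
}

lower_pairs <- function(n) {
  # index pairs (i, j), i < j, in the order lower.tri() vectorizes
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  cbind(i = i, j = j)
}

#' ANOSIM: analysis of similarity
#'
#' Rank-based permutation test of whether dissimilarities between groups
#' exceed those within groups.  All pairwise dissimilarities are ranked
#' (mid-ranks for ties) and
#' r = (mean between-group rank - mean within-group rank) / (M / 2),
#' with M = n(n-1)/2 pairs, so r lies in \[-1, 1\]; r near 1 means groups
#' hold distinct compositions, r near 0 means none.  The p-value comes from
#' random relabelings of the samples with the +1 correction,
#' p = (1 + #\{r* >= r\}) / (1 + n_permutations), so it is never zero.
#'
#' @param d a [bray_curtis()] matrix (or any symmetric dissimilarity
#'   matrix).
#' @param groups group label per sample; defaults to the `groups` attribute
#'   of `d`.
#' @param n_permutations number of random relabelings (default 999).
#' @param seed integer seed controlling the permutations; recorded in the
#'   result.
#' @return object of class `diet_anosim`: `r`, `p`, `n_permutations`,
#'   `seed`, `n`, `groups_n`.
#' @export
anosim_test <- function(d, groups = attr(d, "groups"),
                        n_permutations = 999, seed = NULL) {
  v <- unclass(d)
  n <- nrow(v)
  if (is.null(groups) || length(groups) != n) {
    stop("need one group label per sample", call. = FALSE)
  }
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("ANOSIM needs >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)

  dv <- v[lower.tri(v)]
  rk <- rank(dv)                       # mid-ranks for ties
  idx <- lower_pairs(n)
  M <- length(dv)
  r_stat <- function(g) {
    within <- g[idx[, 1]] == g[idx[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  r_obs <- r_stat(groups)

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  perm_r <- local_seed(seed, {
    vapply(seq_len(n_permutations),
           function(k) r_stat(sample(groups)), numeric(1))
  })
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_permutations)
  structure(list(r = r_obs, p = p, n_permutations = n_permutations,
                 seed = seed, n = n, groups_n = as.integer(tab),
                 group_labels = names(tab)),
            class = "diet_anosim")
}

#' @export
print.diet_anosim <- function(x, ...) {
  cat("ANOSIM (Bray-Curtis ranks)\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", x$group_labels, x$groups_n),
                    collapse = ", ")))
  cat(sprintf("  r = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$r, x$p, x$n_permutations, x$seed))
  invisible(x)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `dims` dimensions so that configuration
#' distances preserve the rank order of the input dissimilarities.  The
#' loss is Kruskal stress-1,
#' sqrt(sum((dhat - d)^2) / sum(d^2)), where dhat is the isotonic
#' (pool-adjacent-violators) regression of configuration distances on the
#' dissimilarity ranks (mid-rank ties, primary tie treatment: tied
#' dissimilarities are free to order themselves by current distance).
#' Minimization is gradient descent with a backtracking step, so stress is
#' non-increasing across iterations by construction.  The first start is
#' the classical-scaling (principal-coordinate) configuration; the
#' remaining `n_restarts - 1` starts are seeded random configurations, and
#' the lowest-stress run is returned.
#'
#' @param d dissimilarity matrix (e.g. [bray_curtis()]).
#' @param dims embedding dimension (default 2).
#' @param seed integer seed for the random restarts; recorded.
#' @param n_restarts total number of starts (>= 1; default 4).
#' @param max_iter maximum gradient iterations per start.
#' @param tol relative stress-improvement threshold declaring convergence.
#' @return object of class `diet_nmds`: `points` (samples x dims),
#'   `stress`, `stress_trace` (per-iteration stress of the best start),
#'   `converged`, `dims`, `seed`, `n_restarts`; `groups` carried from `d`.
#' @export
nmds_ordination <- function(d, dims = 2, seed = NULL, n_restarts = 4,
                            max_iter = 200, tol = 1e-7) {
  v <- unclass(d)
  n <- nrow(v)
  stopifnot(dims >= 1, n_restarts >= 1)
  if (n < dims + 1) stop("too few samples for the requested dims",
                         call. = FALSE)
  delta <- v[lower.tri(v)]
  idx <- lower_pairs(n)
  denom_pairs <- length(delta)

  config_dist <- function(X) {
    dx <- X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE]
    sqrt(rowSums(dx^2))
  }
  # stress and the fitted disparities for a configuration
  stress_fit <- function(dc) {
    o <- order(delta, dc)               # primary treatment of ties
    fit <- stats::isoreg(dc[o])$yf
    dhat <- numeric(length(dc))
    dhat[o] <- fit
    ss <- sum((dc - dhat)^2)
    tt <- sum(dc^2)
    list(stress = sqrt(ss / tt), dhat = dhat, ss = ss, tt = tt)
  }
  run <- function(X0) {
    X <- X0
    dc <- config_dist(X)
    if (all(dc == 0)) dc <- dc + 1e-12
    sf <- stress_fit(dc)
    trace <- sf$stress
    step <- 0.1
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (sf$stress < 1e-12) { converged <- TRUE; break }
      # gradient of stress-1 w.r.t. configuration, disparities held fixed
      w <- ((dc - sf$dhat) / sf$ss - dc / sf$tt) * sf$stress / pmax(dc, 1e-12)
      G <- matrix(0, n, dims)
      diffs <- X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE]
      gw <- diffs * w
      for (k in seq_len(dims)) {
        G[, k] <- G[, k] +
          tapply_sum(gw[, k], idx[, 1], n) - tapply_sum(gw[, k], idx[, 2], n)
      }
      scale_g <- sqrt(sum(G^2))
      if (scale_g < 1e-15) { converged <- TRUE; break }
      improved <- FALSE
      for (h in seq_len(30)) {
        Xn <- X - step * sqrt(sum(X^2)) * G / scale_g
        dcn <- config_dist(Xn)
        if (any(dcn == 0)) dcn <- dcn + 1e-12
        sfn <- stress_fit(dcn)
        if (sfn$stress <= sf$stress) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      rel <- (sf$stress - sfn$stress) / max(sf$stress, 1e-15)
      X <- Xn; dc <- dcn; sf <- sfn
      trace <- c(trace, sf$stress)
      step <- min(step * 1.5, 1)
      if (rel < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = sf$stress, trace = trace, converged = converged)
  }

  # deterministic principal-coordinate start, then seeded random starts
  X0 <- suppressWarnings(stats::cmdscale(stats::as.dist(v), k = dims))
  if (ncol(X0) < dims) {
    X0 <- cbind(X0, matrix(0, n, dims - ncol(X0)))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  starts <- local_seed(seed, {
    c(list(X0),
      lapply(seq_len(n_restarts - 1), function(k)
        matrix(stats::runif(n * dims, -1, 1), n, dims)))
  })
  runs <- lapply(starts, run)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  pts <- best$X
  rownames(pts) <- rownames(v)
  colnames(pts) <- paste0("NMDS", seq_len(dims))
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 dims = dims, seed = seed, n_restarts = n_restarts,
                 groups = attr(d, "groups")),
            class = "diet_nmds")
}

tapply_sum <- function(x, f, n) {
  out <- numeric(n)
  s <- tapply(x, f, sum)
  out[as.integer(names(s))] <- s
  out
}

#' @export
print.diet_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimension(s)\n",
              nrow(x$points), x$dims))
  cat(sprintf("  stress = %.4f (%s, %d starts, seed %d)\n", x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_restarts, x$seed))
  invisible(x)
}

#' @param x a `diet_nmds` object.
#' @param ... passed to [graphics::plot()].
#' @rdname nmds_ordination
#' @export
plot.diet_nmds <- function(x, ...) {
  g <- x$groups
  col <- if (is.null(g)) 1 else as.integer(factor(g))
  graphics::plot(x$points[, 1], x$points[, 2],
                 col = col, pch = 19,
                 xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  if (!is.null(g)) {
    graphics::legend("topright", legend = levels(factor(g)),
                     col = seq_along(levels(factor(g))), pch = 19, cex = 0.8)
  }
  invisible(x)
}

# evaluate expr under a seed without disturbing the caller's RNG state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
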