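#' Specification of one species' synthetic diet
#'
#' Bundles everything needed to simulate flushed stomachs for one predator
#' species: the prey-category multinomial, an over-dispersed per-stomach
#' item-count model (negative binomial parameterized by mean and SD,
#' optionally truncated to a printed range), log-normal prey width/length
#' models moment-matched to published means/SDs and truncated at published
#' ranges, and a Gaussian-copula morphometric model with target pairwise
#' Pearson correlations.
#'
#' @param species species label.
#' @param category_probs named probability vector over prey categories
#'   (must sum to 1; a percentage vector summing to 100 is rescaled).
#' @param category_orders named character vector mapping each category to
#'   its prey order.
#' @param n_stomachs number of individuals to simulate.
#' @param count_mean,count_sd mean and SD of the untruncated per-stomach
#'   item count; SD > sqrt(mean) selects a negative binomial, otherwise a
#'   Poisson is used.
#' @param count_range integer `c(min, max)` truncation, or `NULL`.
#' @param width_mean,width_sd,width_range log-normal prey width model (mm).
#' @param length_mean,length_sd,length_range log-normal prey length model
#'   (mm).  Widths exceeding lengths are swapped after drawing, mirroring
#'   how a measured item's longer axis defines its length.
#' @param morpho_mean,morpho_sd named vectors over `svl_mm`, `hl_mm`,
#'   `mw_mm`, `bm_g`.
#' @param morpho_cor 4x4 positive-definite correlation matrix in the same
#'   order (see [morpho_cor_matrix()]).
#' @param sex_ratio probability that an individual is male.
#' @return object of class `species_diet_spec`.
#' @export
species_diet_spec <- function(species, category_probs, category_orders,
                              n_stomachs,
                              count_mean, count_sd, count_range = NULL,
                              width_mean, width_sd, width_range,
                              length_mean, length_sd, length_range,
                              morpho_mean, morpho_sd, morpho_cor,
                              sex_ratio = 0.5) {
  s <- sum(category_probs)
  if (abs(s - 100) < 0.5) category_probs <- category_probs / 100
  else if (abs(s - 1) > 1e-6) {
    stop("category_probs must sum to 1 (or 100)", call. = FALSE)
  }
  category_probs <- category_probs / sum(category_probs)
  if (is.null(names(category_probs)) || any(!nzchar(names(category_probs)))) {
    stop("category_probs must be a named vector", call. = FALSE)
  }
  if (any(category_probs < 0)) stop("negative category probability",
                                    call. = FALSE)
  missing_map <- setdiff(names(category_probs), names(category_orders))
  if (length(missing_map) > 0L) {
    stop("no prey order mapped for: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_stomachs >= 1, count_mean > 0, count_sd > 0,
            width_mean > 0, length_mean > 0,
            all(morpho_mean > 0), all(morpho_sd > 0),
            sex_ratio >= 0, sex_ratio <= 1)
  vars <- c("svl_mm", "hl_mm", "mw_mm", "bm_g")
  morpho_mean <- morpho_mean[vars]
  morpho_sd <- morpho_sd[vars]
  if (any(is.na(morpho_mean)) || any(is.na(morpho_sd))) {
    stop("morpho_mean/morpho_sd must name svl_mm, hl_mm, mw_mm, bm_g",
         call. = FALSE)
  }
  structure(list(species = species, category_probs = category_probs,
                 category_orders = category_orders,
                 n_stomachs = as.integer(n_stomachs),
                 count_mean = count_mean, count_sd = count_sd,
                 count_range = count_range,
                 width_mean = width_mean, width_sd = width_sd,
                 width_range = width_range,
                 length_mean = length_mean, length_sd = length_sd,
                 length_range = length_range,
                 morpho_mean = morpho_mean, morpho_sd = morpho_sd,
                 morpho_cor = morpho_cor, sex_ratio = sex_ratio),
            class = "species_diet_spec")
}

#' Morphometric correlation matrix from published pairwise values
#'
#' Only the SVL-MW, SVL-BM and MW-BM Pearson correlations are published.
#' Head length correlations are filled with a single-factor rule,
#' r(HL, x) = r_svl_hl * r(SVL, x), which keeps the matrix close to
#' rank-one and hence positive definite; if numerical rounding still
#' pushes an eigenvalue below zero the spectrum is clipped at 1e-6 and the
#' matrix rescaled to unit diagonal.
#'
#' @param r_svl_mw,r_svl_bm,r_mw_bm published pairwise correlations.
#' @param r_svl_hl assumed SVL-HL correlation (default 0.9, in line with
#'   the published head-body correlations).
#' @return 4x4 correlation matrix over `svl_mm`, `hl_mm`, `mw_mm`, `bm_g`.
#' @export
morpho_cor_matrix <- function(r_svl_mw, r_svl_bm, r_mw_bm,
                              r_svl_hl = 0.9) {
  vars <- c("svl_mm", "hl_mm", "mw_mm", "bm_g")
  R <- diag(4)
  dimnames(R) <- list(vars, vars)
  R["svl_mm", "hl_mm"] <- R["hl_mm", "svl_mm"] <- r_svl_hl
  R["svl_mm", "mw_mm"] <- R["mw_mm", "svl_mm"] <- r_svl_mw
  R["svl_mm", "bm_g"] <- R["bm_g", "svl_mm"] <- r_svl_bm
  R["hl_mm", "mw_mm"] <- R["mw_mm", "hl_mm"] <- r_svl_hl * r_svl_mw
  R["hl_mm", "bm_g"] <- R["bm_g", "hl_mm"] <- r_svl_hl * r_svl_bm
  R["mw_mm", "bm_g"] <- R["bm_g", "mw_mm"] <- r_mw_bm
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    v <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    s <- sqrt(diag(R))
    R <- R / outer(s, s)
    dimnames(R) <- list(vars, vars)
  }
  R
}

#' Generator configuration for a whole assemblage
#'
#' @param specs list of [species_diet_spec()] objects.
#' @param seed integer seed recorded in the config and used for the whole
#'   draw.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(specs, seed) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  ok <- vapply(specs, inherits, logical(1), "species_diet_spec")
  if (!all(ok)) stop("specs must be species_diet_spec objects", call. = FALSE)
  structure(list(specs = specs, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default study-shaped generator configuration
#'
#' Three species specs whose parameters are the published summary tables:
#' category multinomials from the composition table's numeric proportions,
#' per-stomach count models and prey-size models from the published
#' means/SDs and ranges, and morphometric models from the published
#' moments and pairwise correlations.  Stomach counts are 26, 42 and 48
#' (116 individuals in total).
#'
#' @param seed integer seed stored in the config.
#' @return a [generator_config()] with three specs.
#' @export
default_study_config <- function(seed = 1) {
  comp <- study_composition()
  prey <- study_prey_summary()
  morpho <- study_morphometrics()
  short <- c("Microhyla heymonsi" = "heymonsi",
             "Microhyla mukhlesuri" = "mukhlesuri",
             "Occidozyga lingnanica" = "lingnanica")
  specs <- lapply(names(short), function(sp) {
    key <- short[[sp]]
    pn <- comp[[paste0(key, "_pctN")]]
    keep <- !is.na(pn) & pn > 0
    probs <- stats::setNames(pn[keep] / sum(pn[keep]),
                             comp$prey_category[keep])
    orders <- stats::setNames(comp$prey_order[keep], comp$prey_category[keep])
    ps <- prey[prey$species == sp, ]
    row_of <- function(v) ps[ps$variable == v, ]
    mo <- morpho$moments[morpho$moments$species == sp, ]
    mv <- stats::setNames(mo$mean, mo$variable)
    msd <- stats::setNames(mo$sd, mo$variable)
    co <- morpho$correlations[morpho$correlations$species == sp, ]
    species_diet_spec(
      species = sp, category_probs = probs, category_orders = orders,
      n_stomachs = unique(ps$n_stomachs),
      count_mean = row_of("N")$mean, count_sd = row_of("N")$sd,
      count_range = c(row_of("N")$min, row_of("N")$max),
      width_mean = row_of("W")$mean, width_sd = row_of("W")$sd,
      width_range = c(row_of("W")$min, row_of("W")$max),
      length_mean = row_of("L")$mean, length_sd = row_of("L")$sd,
      length_range = c(row_of("L")$min, row_of("L")$max),
      morpho_mean = mv, morpho_sd = msd,
      morpho_cor = morpho_cor_matrix(co$r_svl_mw, co$r_svl_bm, co$r_mw_bm),
      sex_ratio = co$n_male / (co$n_male + co$n_female))
  })
  generator_config(specs, seed)
}

# truncated over-dispersed count draw; rejection with a clamped fallback
draw_counts <- function(n, mean, sd, range) {
  size <- if (sd^2 > mean) mean^2 / (sd^2 - mean) else Inf
  draw <- function(k) {
    if (is.finite(size)) stats::rnbinom(k, size = size, mu = mean)
    else stats::rpois(k, mean)
  }
  x <- draw(n)
  if (!is.null(range)) {
    for (tries in 1:50) {
      bad <- x < range[1] | x > range[2]
      if (!any(bad)) break
      x[bad] <- draw(sum(bad))
    }
    x <- pmin(pmax(x, range[1]), range[2])
  }
  x
}

# log-normal moment-matched to (mean, sd), truncated to range by rejection
draw_sizes <- function(n, mean, sd, range) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- stats::rlnorm(n, meanlog, sdlog)
  if (!is.null(range)) {
    for (tries in 1:50) {
      bad <- x < range[1] | x > range[2]
      if (!any(bad)) break
      x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    }
    x <- pmin(pmax(x, range[1]), range[2])
  }
  round(x, 1)   # measurements are recorded to the nearest 0.1 mm
}

draw_morpho <- function(n, mean, sd, R) {
  L <- chol(R)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  x <- sweep(sweep(z, 2, sd, "*"), 2, mean, "+")
  # morphometrics are strictly positive; redraw the rare negative row
  for (tries in 1:50) {
    bad <- which(apply(x, 1, function(r) any(r <= 0)))
    if (length(bad) == 0L) break
    z <- matrix(stats::rnorm(length(bad) * 4), length(bad), 4) %*% L
    x[bad, ] <- sweep(sweep(z, 2, sd, "*"), 2, mean, "+")
  }
  colnames(x) <- names(mean)
  round(x, 2)
}

#' Generate a synthetic stomach-content dataset
#'
#' Deterministic given the config seed.  For each individual: morphometrics
#' from the Gaussian copula, sex from the sex ratio, an item count from the
#' count model, categories i.i.d. from the category multinomial, and prey
#' length/width from the size models (swapped if a width exceeds its
#' length).  Prey sizes are shared across categories, as only pooled size
#' statistics are published.
#'
#' @param config a [generator_config()].
#' @return a [diet_dataset()].
#' @export
#' @examples
#' d <- generate_diet_data(default_study_config(seed = 42))
#' diet_counts(d)
generate_diet_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    chunks <- lapply(seq_along(config$specs), function(si) {
      sp <- config$specs[[si]]
      n <- sp$n_stomachs
      morpho <- draw_morpho(n, sp$morpho_mean, sp$morpho_sd, sp$morpho_cor)
      sex <- ifelse(stats::runif(n) < sp$sex_ratio, "male", "female")
      counts <- draw_counts(n, sp$count_mean, sp$count_sd, sp$count_range)
      ids <- sprintf("S%d_%03d", si, seq_len(n))
      per <- lapply(seq_len(n), function(i) {
        k <- counts[i]
        base <- data.frame(
          sample_id = ids[i], species = sp$species, sex = sex[i],
          svl_mm = morpho[i, "svl_mm"], hl_mm = morpho[i, "hl_mm"],
          mw_mm = morpho[i, "mw_mm"], bm_g = morpho[i, "bm_g"],
          microhabitat = NA_character_, stringsAsFactors = FALSE)
        if (k == 0L) {
          base$prey_order <- NA_character_
          base$prey_category <- NA_character_
          base$prey_length_mm <- NA_real_
          base$prey_width_mm <- NA_real_
          return(base)
        }
        cats <- sample(names(sp$category_probs), k, replace = TRUE,
                       prob = sp$category_probs)
        len <- draw_sizes(k, sp$length_mean, sp$length_sd, sp$length_range)
        wid <- draw_sizes(k, sp$width_mean, sp$width_sd, sp$width_range)
        swap <- wid > len
        tmp <- len[swap]
        len[swap] <- wid[swap]
        wid[swap] <- tmp
        out <- base[rep(1, k), , drop = FALSE]
        out$prey_order <- unname(sp$category_orders[cats])
        out$prey_category <- cats
        out$prey_length_mm <- len
        out$prey_width_mm <- wid
        out
      })
      do.call(rbind, per)
    })
    diet_dataset(do.call(rbind, chunks))
  })
}
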