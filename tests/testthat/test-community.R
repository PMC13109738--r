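test_that("sample-by-taxon matrix accumulates counts and volumes", {
  d <- diet_dataset(rbind(diet_row("a"), diet_row("a")))
  m <- build_taxon_matrix(d, "abundance")
  expect_equal(unname(unclass(m)[1, 1]), 2)
  mv <- build_taxon_matrix(d, "volume")
  expect_equal(unname(unclass(mv)[1, 1]), 2 * pi / 3)  # two 2x1 mm items

  withe <- diet_dataset(rbind(diet_row("a"), empty_stomach_row("b")))
  expect_message(m2 <- build_taxon_matrix(withe, "abundance"),
                 "empty stomach")
  expect_equal(nrow(m2), 1L)
})

test_that("study-shaped synthetic data yields one matrix row per stomach", {
  d <- generate_diet_data(default_study_config(seed = 31))
  m <- build_taxon_matrix(d, "abundance")
  expect_equal(nrow(m), 116L)  # count-model minimum of 1 leaves none empty
  expect_equal(length(attr(m, "groups")), 116L)
})

test_that("Bray-Curtis matches hand values and vegan on random data", {
  m <- rbind(a = c(2, 1, 0), b = c(0, 1, 2), c = c(2, 1, 0))
  dd <- bray_curtis(m)
  expect_equal(unclass(dd)["a", "b"], 2 / 3)
  expect_equal(unclass(dd)["a", "c"], 0)
  disj <- rbind(x = c(3, 0), y = c(0, 5))
  expect_equal(unclass(bray_curtis(disj))["x", "y"], 1)
  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "b")

  skip_if_not_installed("vegan")
  set.seed(8)
  r <- matrix(rpois(15 * 6, 3) + 1, 15, 6,
              dimnames = list(paste0("s", 1:15), NULL))
  expect_equal(max(abs(unclass(bray_curtis(r)) -
                         as.matrix(vegan::vegdist(r, "bray")))), 0)
})

test_that("Bray-Curtis is invariant under common rescaling of a pair", {
  m <- rbind(a = c(2, 1, 4), b = c(1, 3, 0))
  expect_equal(unclass(bray_curtis(m * 7))["a", "b"],
               unclass(bray_curtis(m))["a", "b"])
})

test_that("ANOSIM separates separated groups and floors its p-value", {
  # two tight clusters far apart: every between-pair exceeds every
  # within-pair, so r = 1 and no permuted labelling can match it (the
  # groups are large enough that the true partition is essentially never
  # redrawn, leaving p at the +1-corrected permutation floor)
  m <- rbind(matrix(c(10:17, rep(0, 8)), 8, 2),
             matrix(c(rep(0, 8), 10:17), 8, 2))
  rownames(m) <- c(paste0("a", 1:8), paste0("b", 1:8))
  dd <- bray_curtis(m)
  res <- anosim_test(dd, rep(c("a", "b"), each = 8), n_permutations = 999,
                     seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 1000)
  expect_equal(res$n_permutations, 999L)
  expect_equal(res$seed, 1)
})

test_that("ANOSIM r equals the rank-formula enumeration on 4 points", {
  # direct enumeration oracle for n = 4, groups aa/bb
  m <- rbind(a1 = c(5, 1, 0), a2 = c(4, 2, 0), b1 = c(0, 2, 5),
             b2 = c(1, 1, 6))
  dd <- unclass(bray_curtis(m))
  g <- c("a", "a", "b", "b")
  pairs <- t(combn(4, 2))
  dv <- dd[pairs]
  rk <- rank(dv)
  within <- g[pairs[, 1]] == g[pairs[, 2]]
  r_oracle <- (mean(rk[!within]) - mean(rk[within])) / (6 / 2)
  res <- anosim_test(bray_curtis(m), g, n_permutations = 9, seed = 2)
  expect_equal(res$r, r_oracle)
})

test_that("ANOSIM agrees with vegan and is rank-invariant", {
  skip_if_not_installed("vegan")
  set.seed(23)
  m <- matrix(rpois(24 * 5, 4) + 1, 24, 5,
              dimnames = list(paste0("s", 1:24), NULL))
  g <- rep(c("a", "b", "c"), each = 8)
  dd <- bray_curtis(m)
  mine <- anosim_test(dd, g, n_permutations = 99, seed = 4)
  veg <- vegan::anosim(vegan::vegdist(m, "bray"), g, permutations = 99)
  expect_equal(mine$r, unname(veg$statistic))
  # any strictly monotone transform of the dissimilarities leaves r alone
  dd2 <- unclass(dd)^3 + 0.1 * (unclass(dd) > 0)
  diag(dd2) <- 0
  mine2 <- anosim_test(dd2, g, n_permutations = 99, seed = 4)
  expect_equal(mine2$r, mine$r)
})

test_that("ANOSIM r is near zero for shuffled homogeneous data", {
  set.seed(55)
  m <- matrix(rpois(30 * 6, 5) + 1, 30, 6,
              dimnames = list(paste0("s", 1:30), NULL))
  g <- sample(rep(c("a", "b"), each = 15))
  res <- anosim_test(bray_curtis(m), g, n_permutations = 199, seed = 6)
  expect_lt(abs(res$r), 0.25)
  expect_gt(res$p, 0.01)
})

test_that("ANOSIM rejects degenerate groupings", {
  m <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 1))
  expect_error(anosim_test(bray_curtis(m), c("x", "x", "x")), ">= 2 groups")
  expect_error(anosim_test(bray_curtis(m), c("x", "x", "y")), ">= 2")
})

test_that("NMDS recovers exact Euclidean geometry and degenerate cases", {
  set.seed(77)
  X <- matrix(rnorm(10), 5, 2)
  de <- as.matrix(dist(X))
  rownames(de) <- colnames(de) <- paste0("p", 1:5)
  nm <- nmds_ordination(de, dims = 2, seed = 3, n_restarts = 2)
  expect_lt(nm$stress, 0.01)
  # two points in one dimension are always perfectly representable
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  nm2 <- nmds_ordination(d2, dims = 1, seed = 1, n_restarts = 1)
  expect_equal(nm2$stress, 0, tolerance = 1e-8)
})

test_that("NMDS stress is non-increasing within a run", {
  d <- generate_diet_data(default_study_config(seed = 41))
  dd <- bray_curtis(build_taxon_matrix(d, "abundance"))
  nm <- nmds_ordination(dd, dims = 2, seed = 11, n_restarts = 2,
                        max_iter = 120)
  expect_true(all(diff(nm$stress_trace) <= 1e-12))
  expect_equal(nm$stress, min(nm$stress_trace))
  expect_equal(nrow(nm$points), nrow(dd))
})

test_that("NMDS stress is competitive with vegan monoMDS", {
  skip_if_not_installed("vegan")
  set.seed(91)
  m <- matrix(rpois(20 * 6, 4) + 1, 20, 6,
              dimnames = list(paste0("s", 1:20), NULL))
  dd <- bray_curtis(m)
  nm <- nmds_ordination(dd, dims = 2, seed = 2, n_restarts = 4,
                        max_iter = 300)
  veg <- vegan::metaMDS(vegan::vegdist(m, "bray"), k = 2, trace = 0)
  expect_lt(nm$stress, veg$stress + 0.01)
})
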