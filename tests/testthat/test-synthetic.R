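test_that("the default study configuration mirrors the published tables", {
  cfg <- default_study_config(seed = 1)
  expect_length(cfg$specs, 3L)
  sp <- vapply(cfg$specs, `[[`, "", "species")
  n <- vapply(cfg$specs, `[[`, 1L, "n_stomachs")
  expect_equal(stats::setNames(n, sp),
               c("Microhyla heymonsi" = 26L, "Microhyla mukhlesuri" = 42L,
                 "Occidozyga lingnanica" = 48L))
  ncat <- vapply(cfg$specs, function(s) length(s$category_probs), 1L)
  expect_equal(unname(ncat), c(8L, 11L, 28L))
  for (s in cfg$specs) {
    expect_equal(sum(s$category_probs), 1, tolerance = 1e-9)
    expect_true(all(names(s$category_probs) %in% names(s$category_orders)))
    ev <- eigen(s$morpho_cor, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("generation is deterministic given the seed and leaves RNG alone", {
  cfg <- default_study_config(seed = 99)
  set.seed(1234)
  before <- .Random.seed
  d1 <- generate_diet_data(cfg)
  expect_identical(.Random.seed, before)
  d2 <- generate_diet_data(cfg)
  expect_identical(d1, d2)
  d3 <- generate_diet_data(default_study_config(seed = 100))
  expect_false(identical(d1, d3))
  cnt <- diet_counts(d1)
  expect_equal(sum(cnt$n_stomachs), 116L)
})

test_that("generated measurements respect the configured ranges", {
  d <- generate_diet_data(default_study_config(seed = 3))
  prey <- study_prey_summary()
  for (sp in unique(prey$species)) {
    items <- d[d$species == sp & !is.na(d$prey_category), ]
    rng <- function(v) prey[prey$species == sp & prey$variable == v, ]
    expect_true(all(items$prey_width_mm >= rng("W")$min - 1e-9))
    # lengths live in the printed range up to the W<->L swap with a
    # width drawn from its own (narrower) range
    expect_true(all(items$prey_length_mm <= rng("L")$max + 1e-9))
    expect_true(all(items$prey_length_mm >= items$prey_width_mm))
    ids <- unique(items$sample_id)
    counts <- table(items$sample_id)
    expect_true(all(counts >= rng("N")$min & counts <= rng("N")$max))
  }
  expect_true(all(d$svl_mm > 0 & d$bm_g > 0))
  expect_true(all(d$sex %in% c("male", "female")))
})

test_that("large-sample composition recovers the category multinomial", {
  cfg <- default_study_config(seed = 17)
  big <- cfg$specs[[2]]          # the termite-dominated Microhyla
  big$n_stomachs <- 4200L
  d <- generate_diet_data(generator_config(list(big), seed = 17))
  tab <- category_table(d, big$species)
  termite <- tab$pctN[tab$taxon == "Termitidae"]
  expect_equal(termite, 75.85, tolerance = 2 / 75.85)  # within 2 points
  # every generating probability is recovered within 2 percentage points
  got <- stats::setNames(tab$pctN, tab$taxon)[names(big$category_probs)]
  got[is.na(got)] <- 0
  expect_true(all(abs(got - 100 * big$category_probs) < 2))
})

test_that("the untruncated count model recovers its mean", {
  cfg <- default_study_config(seed = 29)
  sp <- cfg$specs[[3]]
  sp$count_range <- NULL          # recovery is about the core model
  sp$n_stomachs <- 3000L
  d <- generate_diet_data(generator_config(list(sp), seed = 29))
  counts <- table(factor(d$sample_id[!is.na(d$prey_category)],
                         levels = unique(d$sample_id)))
  se <- sp$count_sd / sqrt(sp$n_stomachs)
  expect_lt(abs(mean(counts) - sp$count_mean), 4 * se)
})

test_that("size models reproduce the pooled moments before truncation bias", {
  cfg <- default_study_config(seed = 37)
  sp <- cfg$specs[[1]]
  sp$n_stomachs <- 1000L
  d <- generate_diet_data(generator_config(list(sp), seed = 37))
  items <- d[!is.na(d$prey_category), ]
  # swap + truncation shift moments mildly; demand the right scale
  expect_equal(mean(items$prey_width_mm), sp$width_mean, tolerance = 0.15)
  expect_equal(mean(items$prey_length_mm), sp$length_mean, tolerance = 0.15)
})

test_that("invalid configurations are rejected", {
  cfg <- default_study_config(seed = 1)
  sp <- cfg$specs[[1]]
  expect_error(species_diet_spec(
    "x", c(a = 0.5, b = 0.2), c(a = "A", b = "B"), 5,
    10, 5, NULL, 1, 0.2, c(0.5, 2), 2, 1, c(0.5, 5),
    sp$morpho_mean, sp$morpho_sd, sp$morpho_cor), "sum to 1")
  expect_error(species_diet_spec(
    "x", c(0.5, 0.5), c(a = "A", b = "B"), 5,
    10, 5, NULL, 1, 0.2, c(0.5, 2), 2, 1, c(0.5, 5),
    sp$morpho_mean, sp$morpho_sd, sp$morpho_cor), "named")
  expect_error(generator_config(list(1), seed = 1), "species_diet_spec")
})

test_that("end-to-end pipeline recovers the analytic Pianka overlap", {
  cfg <- default_study_config(seed = 53)
  # enough stomachs that every species contributes ~5000 items
  specs <- lapply(cfg$specs, function(s) {
    s$n_stomachs <- as.integer(ceiling(5000 / s$count_mean))
    s
  })
  d <- generate_diet_data(generator_config(specs, seed = 53))
  sp <- vapply(specs, `[[`, "", "species")
  profs <- lapply(sp, function(s) diet_profile(d, s, "category"))
  O_hat <- overlap_matrix(profs)
  analytic <- lapply(specs, function(s)
    niche_profile(names(s$category_probs),
                  proportions = s$category_probs, species = s$species))
  O_true <- overlap_matrix(analytic)
  expect_true(all(abs(O_hat - O_true) < 0.02))
})
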