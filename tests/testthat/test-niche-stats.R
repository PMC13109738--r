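# independent high-precision oracles, kept deliberately naive
oracle_shannon <- function(counts) {
  p <- counts / sum(counts)
  acc <- 0
  for (pi in p) if (pi > 0) acc <- acc - pi * log(pi)
  acc
}
oracle_simpson_D <- function(counts) {
  # pair enumeration: probability two distinct items share a taxon
  N <- sum(counts)
  same <- 0
  for (ni in counts) same <- same + ni * (ni - 1)
  same / (N * (N - 1))
}
oracle_levins <- function(p) {
  p <- p[p > 0] / sum(p)
  B <- 1 / sum(p * p)
  list(B = B, B_sta = (B - 1) / (length(p) - 1))
}

test_that("finite-sample Simpson matches pair enumeration", {
  expect_equal(simpson_index(c(2, 2))$D, 1 / 3)
  expect_equal(simpson_index(c(10))$D, 1)
  expect_equal(simpson_index(c(10))$one_minus_D, 0)
  for (n in c(2, 5, 17)) expect_equal(simpson_index(n)$D, 1)
  set.seed(42)
  for (rep in 1:20) {
    counts <- rpois(sample(2:8, 1), 5) + 1
    expect_equal(simpson_index(counts)$D, oracle_simpson_D(counts))
  }
  expect_error(simpson_index(c(1)), "two items")
  expect_error(simpson_index(c(1.5, 2)), "integers")
})

test_that("reconstructed study counts reproduce the published 1 - D", {
  recon <- function(key, N) round(study_pctN(key) / 100 * N)
  expect_equal(round(simpson_index(recon("heymonsi", 501))$one_minus_D, 2),
               0.15)
  expect_equal(round(simpson_index(recon("mukhlesuri", 878))$one_minus_D, 2),
               0.39)
  expect_equal(round(simpson_index(recon("lingnanica", 280))$one_minus_D, 2),
               0.91)
})

test_that("Shannon index and evenness behave at the closed-form anchors", {
  expect_equal(shannon_index(rep(1 / 4, 4)), log(4))
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(evenness(log(7), 7), 1)
  expect_equal(evenness(0, 5), 0)
  expect_error(evenness(1, 1), "S >= 2")
  expect_error(shannon_index(c(0.5, 0.2)), "sum to 1")
})

test_that("shannon/evenness/levins agree with naive summation to 1e-12", {
  counts <- c(666, 174, 13, 12, 7, 1, 1, 1, 1, 1, 1)  # reconstructed diet
  H <- shannon_index(counts)
  expect_equal(H, oracle_shannon(counts), tolerance = 1e-12)
  expect_equal(round(H, 4), 0.7363)
  expect_equal(evenness(H, 11), H / log(11), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:25) {
    p <- runif(sample(2:12, 1))
    p <- p / sum(p)
    expect_equal(shannon_index(p), oracle_shannon(p), tolerance = 1e-12)
    lv <- levins_breadth(p)
    orc <- oracle_levins(p)
    expect_equal(lv$B, orc$B, tolerance = 1e-12)
    expect_equal(lv$B_sta, orc$B_sta, tolerance = 1e-12)
  }
})

test_that("Levins breadth reproduces the published breadth ranking", {
  expect_equal(round(levins_breadth(study_pctN("heymonsi"))$B_sta, 2), 0.02)
  expect_equal(round(levins_breadth(study_pctN("mukhlesuri"))$B_sta, 2), 0.06)
  # printed 0.33; proportions rounded to 2 decimals move it to 0.34
  expect_equal(round(levins_breadth(study_pctN("lingnanica"))$B_sta, 2), 0.34)
  expect_equal(levins_breadth(study_pctN("heymonsi"))$n, 8L)
  expect_equal(levins_breadth(study_pctN("mukhlesuri"))$n, 11L)
})

test_that("breadth hits the generalist limit and respects transfers", {
  for (n in c(2, 6, 11)) {
    lv <- levins_breadth(rep(1 / n, n))
    expect_equal(lv$B, n)
    expect_equal(lv$B_sta, 1)
  }
  # relabeling invariance and a mass-equalizing transfer increases B_sta
  p <- c(0.6, 0.25, 0.1, 0.05)
  expect_equal(levins_breadth(sample(p))$B_sta, levins_breadth(p)$B_sta)
  q <- c(0.55, 0.3, 0.1, 0.05)  # moved 0.05 from the largest to the second
  expect_gt(levins_breadth(q)$B_sta, levins_breadth(p)$B_sta)
})

test_that("Pianka overlap is a bounded symmetric cosine of diet vectors", {
  a <- niche_profile(c("x", "y"), proportions = c(0.7, 0.3), species = "A")
  b <- niche_profile(c("x", "y"), proportions = c(0.7, 0.3), species = "B")
  expect_equal(pianka_overlap(a, b), 1)
  dis <- niche_profile(c("z", "w"), proportions = c(0.5, 0.5), species = "C")
  expect_equal(pianka_overlap(a, dis), 0)
  set.seed(19)
  for (rep in 1:25) {
    labs <- letters[1:6]
    p1 <- runif(6); p2 <- runif(6)
    pr1 <- niche_profile(labs, proportions = p1 / sum(p1))
    pr2 <- niche_profile(labs, proportions = p2 / sum(p2))
    o <- pianka_overlap(pr1, pr2)
    expect_gte(o, 0)
    expect_lte(o, 1 + 1e-12)
    expect_equal(pianka_overlap(pr2, pr1), o)
  }
})

test_that("moving mass off shared taxa lowers the overlap", {
  base <- niche_profile(c("x", "y"), proportions = c(0.5, 0.5))
  other <- niche_profile(c("x", "z"), proportions = c(0.5, 0.5))
  shifted <- niche_profile(c("x", "z"), proportions = c(0.3, 0.7))
  expect_gt(pianka_overlap(base, other), pianka_overlap(base, shifted))
})

test_that("study niche profiles give the published overlap pattern", {
  profs <- lapply(c(mukhlesuri = "mukhlesuri", heymonsi = "heymonsi",
                    lingnanica = "lingnanica"), function(k) {
    p <- study_pctN(k)
    niche_profile(names(p), proportions = p / sum(p), species = k)
  })
  O <- overlap_matrix(profs)
  expect_equal(diag(O), c(mukhlesuri = 1, heymonsi = 1, lingnanica = 1))
  expect_equal(O, t(O))
  expect_equal(round(O["heymonsi", "lingnanica"], 2), 0.49)
  # printed 97% and 47%; reconstruction from rounded proportions
  expect_equal(O["mukhlesuri", "heymonsi"], 0.98, tolerance = 0.01)
  expect_equal(O["mukhlesuri", "lingnanica"], 0.52, tolerance = 0.01)
})

test_that("overlap matrix handles identical and disjoint profiles", {
  a <- niche_profile(c("x"), proportions = 1, species = "A")
  b <- niche_profile(c("x"), proportions = 1, species = "B")
  expect_equal(unname(overlap_matrix(list(a, b))),
               matrix(1, 2, 2))
  d1 <- niche_profile("x", proportions = 1, species = "1")
  d2 <- niche_profile("y", proportions = 1, species = "2")
  d3 <- niche_profile("z", proportions = 1, species = "3")
  expect_equal(unname(overlap_matrix(list(d1, d2, d3))), diag(3))
})

test_that("diet_profile draws proportions from item counts", {
  d <- tiny_diet()
  pr <- diet_profile(d, "sp1", "category")
  expect_equal(sort(pr$labels), c("Formicidae", "Termitidae"))
  expect_equal(sum(pr$proportions), 1)
  expect_equal(pr$proportions[pr$labels == "Termitidae"], 2 / 3)
})
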