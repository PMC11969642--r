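test_that("bray_curtis matches the formula and its limits", {
  m <- toy_matrix(rbind(c(4, 1, 0), c(1, 1, 3)))
  expect_equal(bray_curtis(m)[1, 2], 60)

  ident <- toy_matrix(rbind(c(2, 3), c(2, 3)))
  expect_equal(bray_curtis(ident)[1, 2], 0)

  disjoint <- toy_matrix(rbind(c(2, 0), c(0, 3)))
  expect_equal(bray_curtis(disjoint)[1, 2], 100)

  bad <- peak_matrix(rbind(c(0, 0), c(1, 2)), c(1000.5, 1100.5),
                     data.frame(sample_id = c("zed", "ok")))
  expect_error(bray_curtis(bad), "zed")
})

test_that("anosim reproduces hand-ranked examples", {
  r <- anosim(separable_dist(), c("A", "A", "B", "B"), n_permutations = 0)
  expect_equal(r$R, 1)
  expect_equal(r$c, 3)

  # within ranks {3,5}, between {1,2,4,6}: R = (3.25 - 4)/3
  d <- dist_from_pairs(4, list(c(1, 2, 3), c(3, 4, 5), c(1, 3, 1),
                               c(1, 4, 2), c(2, 3, 4), c(2, 4, 6)))
  r2 <- anosim(d, c("A", "A", "B", "B"), n_permutations = 0)
  expect_equal(r2$R, -0.25)

  expect_error(anosim(separable_dist(), c("A", "A", "A", "B"),
                      n_permutations = 0), "single sample")
  flat <- as_pmf_dist(matrix(5, 4, 4) - diag(5, 4))
  expect_warning(r3 <- anosim(flat, c("A", "A", "B", "B"),
                              n_permutations = 0), "equal")
  expect_equal(r3$R, 0)
})

test_that("significance follows the (n_ge + 1)/(n_perm + 1) convention", {
  expect_equal(significance_percent(44, 999), 4.5)
  expect_equal(significance_percent(0, 999), 0.1)
  # a reported result carries the same arithmetic
  set.seed(2)
  m <- random_grouped_matrix(c(4, 4), 12, seed = 2)
  r <- anosim(bray_curtis(m), m$labels$family, n_permutations = 99, seed = 5)
  expect_equal(r$sig_percent,
               100 * (r$n_ge_observed + 1) / (r$n_permutations + 1))
  # permutation stream reproducible from seed
  r2 <- anosim(bray_curtis(m), m$labels$family, n_permutations = 99, seed = 5)
  expect_identical(r$n_ge_observed, r2$n_ge_observed)
})

test_that("anosim R is rank-based: invariant under monotone transforms", {
  for (seed in 1:5) {
    m <- random_grouped_matrix(c(3, 3, 3), 10, seed = seed)
    d <- bray_curtis(m)
    r0 <- anosim(d, m$labels$family, n_permutations = 0)$R
    for (f in list(function(x) x^2, function(x) sqrt(x),
                   function(x) 5 * x + 1)) {
      dt <- as_pmf_dist(ifelse(diag(nrow(d)) == 1, 0, f(unclass(d))) /
                          max(f(unclass(d))) * 100)
      expect_equal(anosim(dt, m$labels$family, n_permutations = 0)$R, r0,
                   tolerance = 1e-12)
    }
  }
})

test_that("anosim matches the brute-force oracle on random instances", {
  for (seed in 1:10) {
    m <- random_grouped_matrix(c(3, 3, 2), 8, seed = seed + 100)
    m$labels$family <- sample(m$labels$family)
    d <- bray_curtis(m)
    expect_equal(anosim(d, m$labels$family, n_permutations = 0)$R,
                 brute_anosim_R(d, m$labels$family), tolerance = 1e-12)
  }
})

test_that("mean R over random labels is near zero", {
  set.seed(19)
  Rs <- replicate(200, {
    d <- matrix(stats::runif(100, 1, 99), 10, 10)
    d <- (d + t(d)) / 2; diag(d) <- 0
    anosim(as_pmf_dist(d), sample(rep(c("A", "B"), 5)), n_permutations = 0)$R
  })
  se <- stats::sd(Rs) / sqrt(length(Rs))
  expect_lt(abs(mean(Rs)), 3 * se)
})

test_that("pairwise_anosim covers all pairs and counts arrangements", {
  m <- random_grouped_matrix(c(2, 2, 2), 10, seed = 31)
  pw <- pairwise_anosim(bray_curtis(m), m$labels$family,
                        n_permutations = 19, seed = 1)
  expect_length(pw, 3L)
  expect_equal(pw[["A vs B"]]$possible_perms, 6)

  # large groups overflow to the sentinel
  m2 <- random_grouped_matrix(c(25, 25), 10, seed = 32)
  pw2 <- pairwise_anosim(bray_curtis(m2), m2$labels$family,
                         n_permutations = 9, seed = 1)
  expect_equal(pw2[[1]]$possible_perms, "very large")

  # two groups of clones: degenerate ties give R = 0
  clones <- toy_matrix(matrix(rep(c(1, 2, 3), 6), 6, 3, byrow = TRUE),
                       family = rep(c("A", "B"), each = 3))
  pwc <- suppressWarnings(pairwise_anosim(bray_curtis(clones),
                                          clones$labels$family,
                                          n_permutations = 19, seed = 1))
  expect_equal(pwc[[1]]$R, 0)
})

test_that("simper decompositions reproduce hand-computed contributions", {
  g <- toy_matrix(rbind(c(4, 0), c(2, 2)), family = c("G", "G"))
  sw <- simper_within(g)[["G"]]
  expect_equal(sw$average_score, 50)
  expect_equal(sw$table$contribution[order(sw$table$mz)], c(50, 0))

  h <- toy_matrix(rbind(c(4, 0), c(2, 2)), family = c("G", "H"))
  sb <- simper_between(h)[[1]]
  expect_equal(sb$average_score, 50)
  expect_equal(sb$table$contribution, c(25, 25))

  idg <- toy_matrix(rbind(c(1, 2), c(1, 2)), family = c("G", "G"))
  expect_equal(simper_within(idg)[["G"]]$average_score, 100)

  dis <- toy_matrix(rbind(c(1, 0), c(0, 2)), family = c("G", "H"))
  expect_equal(simper_between(dis)[[1]]$average_score, 100)
})

test_that("simper contributions sum to Bray-Curtis group means", {
  m <- random_grouped_matrix(c(4, 4, 4), 15, seed = 77)
  d <- bray_curtis(m)
  labels <- m$labels$family
  sw <- simper_within(m)
  for (g in names(sw)) {
    idx <- which(labels == g)
    sims <- 100 - d[idx, idx][lower.tri(d[idx, idx])]
    expect_equal(sw[[g]]$average_score, mean(sims), tolerance = 1e-9)
    expect_equal(sum(sw[[g]]$table$contribution), mean(sims),
                 tolerance = 1e-9)
    expect_true(all(diff(sw[[g]]$table$cumulative_pct) >= -1e-9))
    expect_equal(sw[[g]]$table$cumulative_pct[nrow(sw[[g]]$table)], 100,
                 tolerance = 1e-9)
  }
  sb <- simper_between(m)
  for (r in sb) {
    ia <- which(labels == r$scope[1]); ib <- which(labels == r$scope[2])
    expect_equal(r$average_score, mean(d[ia, ib]), tolerance = 1e-9)
    expect_equal(sum(r$table$contribution), mean(d[ia, ib]),
                 tolerance = 1e-9)
  }
})

test_that("top_contributors returns the minimal covering prefix", {
  fake <- structure(list(
    scope = "G", type = "similarity", average_score = 100, n_pairs = 1,
    table = data.frame(mz = c(1000.5, 1200.5, 1400.5),
                       contribution = c(50, 30, 20),
                       contribution_pct = c(50, 30, 20),
                       cumulative_pct = c(50, 80, 100),
                       sd_ratio = Inf)), class = "simper_result")
  expect_equal(nrow(top_contributors(fake, 70)), 2L)
  expect_equal(nrow(top_contributors(fake, 100)), 3L)

  # tie on contribution: lower m/z first, minimal prefix of two
  g <- toy_matrix(rbind(c(2, 2, 1), c(2, 2, 1)), family = c("G", "G"))
  sw <- simper_within(g)[["G"]]
  tc <- top_contributors(sw, 50)
  expect_equal(nrow(tc), 2L)
  expect_equal(tc$mz, sort(tc$mz))
})

test_that("nmds embeds ranks with reproducible stress", {
  # three mutually equidistant points embed exactly in the plane
  d3 <- as_pmf_dist(matrix(50, 3, 3) - diag(50, 3))
  nd <- nmds(d3, k = 2, n_restarts = 5, seed = 2)
  expect_lt(nd$stress, 1e-4)

  m <- random_grouped_matrix(c(3, 3, 3), 12, seed = 41)
  d <- bray_curtis(m)
  a <- nmds(d, k = 2, n_restarts = 10, seed = 7)
  b <- nmds(d, k = 2, n_restarts = 10, seed = 7)
  expect_identical(a$coordinates, b$coordinates)
  expect_equal(unname(colMeans(a$coordinates)), c(0, 0), tolerance = 1e-9)

  # rank invariance: doubling all dissimilarities leaves stress unchanged
  d2 <- unclass(d) * 2
  d2 <- as_pmf_dist(d2 / max(d2) * 100)
  c2 <- nmds(d2, k = 2, n_restarts = 10, seed = 7)
  expect_equal(c2$stress, a$stress, tolerance = 1e-4)

  dbad <- unclass(d); dbad[1, 2] <- dbad[2, 1] <- NA
  expect_error(nmds(structure(dbad, class = c("pmf_dist", "matrix")),
                    k = 2, n_restarts = 2, seed = 1), "non-finite")
})

test_that("bray_curtis and anosim agree with the vegan reference", {
  for (seed in 1:3) {
    m <- random_grouped_matrix(c(4, 4), 15, seed = 500 + seed)
    d <- bray_curtis(m)
    ref <- as.matrix(vegan::vegdist(m$values, method = "bray")) * 100
    expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(anosim(d, m$labels$family, n_permutations = 0)$R,
                 unname(vegan::anosim(stats::as.dist(ref), m$labels$family,
                                      permutations = 0)$statistic),
                 tolerance = 1e-12)
  }
})
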