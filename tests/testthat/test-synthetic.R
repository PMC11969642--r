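test_that("simulate_taxonomy is ultrametric, bounded and reproducible", {
  tree <- simulate_taxonomy(6, depth_mya = 200, seed = 4)
  expect_s3_class(tree, "phylo")
  expect_equal(length(tree$tip.label), 6)
  depths <- ape::node.depth.edgelength(tree)[1:6]
  expect_equal(depths, rep(200, 6), tolerance = 1e-9)

  ed <- pairwise_ed(tree)
  expect_equal(ed, t(ed))
  expect_true(all(ed[upper.tri(ed)] <= 200 + 1e-9))

  tree2 <- simulate_taxonomy(6, depth_mya = 200, seed = 4)
  expect_equal(tree, tree2)
  expect_error(simulate_taxonomy(1, seed = 1), ">= 2")

  # n = 2: a single split at the stated depth
  t2 <- simulate_taxonomy(2, depth_mya = 120, seed = 9)
  expect_equal(pairwise_ed(t2)[1, 2], 120, tolerance = 1e-9)
})

test_that("zero divergence leaves all leaves with the root fingerprint", {
  cfg <- simulation_config(seed = 3, divergence_scale = 0,
                           n_marker_peaks = 0)
  ev <- evolve_peptides(simulate_taxonomy(4, 100, 3), cfg)
  ref <- ev$peptide_sets[[1]]$mz
  for (p in ev$peptide_sets) expect_equal(p$mz, ref)
  expect_true(all(ev$ground_truth$substitution_counts == 0))
})

test_that("substitution counts grow linearly with ED at the stated rates", {
  # two-taxon trees: expected pairwise count = sum(rates) * scale * ED
  eds <- c(25, 50, 100, 200)
  reps <- 40
  means <- vapply(eds, function(ed) {
    tot <- vapply(seq_len(reps), function(r) {
      tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", ed, ed))
      cfg <- simulation_config(seed = 7000 + r * 13 + as.integer(ed),
                               n_marker_peaks = 0)
      ev <- evolve_peptides(tree, cfg)
      ev$ground_truth$substitution_counts["A", "B"]
    }, numeric(1))
    mean(tot)
  }, numeric(1))
  expected <- (0.7 + 0.9 + 1.0) * eds
  expect_equal(means, expected, tolerance = 0.1)

  # the fish-specific alpha 3 chain accrues ~1.0/0.7 the changes of alpha 1
  tree <- ape::read.tree(text = "(A:150,B:150);")
  per_chain <- rowMeans(vapply(1:60, function(r) {
    cfg <- simulation_config(seed = 9000 + r, n_marker_peaks = 0)
    gt <- evolve_peptides(tree, cfg)$ground_truth
    vapply(gt$substitution_counts_chain, function(mm) mm["A", "B"],
           numeric(1))
  }, numeric(3)))
  expect_equal(per_chain[["COL1A3"]] / per_chain[["COL1A1"]], 1 / 0.7,
               tolerance = 0.15)
})

test_that("generate_spectra is reproducible and honours the noise limits", {
  tree <- simulate_taxonomy(3, 100, 5)
  cfg <- simulation_config(seed = 5)
  ev <- evolve_peptides(tree, cfg)
  s1 <- generate_spectra(ev$peptide_sets, cfg)
  s2 <- generate_spectra(ev$peptide_sets, cfg)
  expect_identical(s1, s2)

  # noiseless limit: all individuals of a leaf are identical
  cfg0 <- simulation_config(seed = 5, detection_prob = 1, intensity_cv = 0,
                            n_noise_peaks = 0, n_individuals = 3)
  ev0 <- evolve_peptides(tree, cfg0)
  s0 <- generate_spectra(ev0$peptide_sets, cfg0)
  fam <- vapply(s0, `[[`, character(1), "family")
  for (leaf in unique(fam)) {
    grp <- s0[fam == leaf]
    for (s in grp[-1]) {
      expect_equal(s$mz, grp[[1]]$mz)
      expect_equal(s$intensity, grp[[1]]$intensity)
    }
  }
})

test_that("the planted matrix peak is removed downstream by the defect rule", {
  cfg <- simulation_config(seed = 12, n_individuals = 3)
  st <- simulate_pmf_study(3, 100, cfg)
  m <- align_peaks(normalize_spectra(st$spectra), 0.3)
  expect_true(any(abs(m$mz - 1060.1) <= 0.3))
  f <- suppressWarnings(filter_nonbiological(m))
  expect_false(any(abs(f$mz - 1060.1) <= 0.3))
  report <- attr(f, "removal_report")
  hit <- report[abs(report$mz - 1060.1) <= 0.3, ]
  expect_equal(unique(hit$rule), "mass_defect")
})

test_that("companion alignments preserve the collagen motif and event counts", {
  tree <- simulate_taxonomy(4, 150, 21)
  cfg <- simulation_config(seed = 21)
  aln <- generate_alignments(tree, cfg)
  expect_named(aln, c("COL1A1", "COL1A2", "COL1A3"))
  for (ch in names(aln)) for (s in aln[[ch]]) {
    res <- strsplit(s, "")[[1]]
    expect_true(all(res[seq(1, length(res), by = 3)] == "G"))
  }

  # zero divergence: all pairs identical
  cfg0 <- simulation_config(seed = 21, divergence_scale = 0)
  aln0 <- generate_alignments(tree, cfg0)
  expect_equal(length(unique(aln0$COL1A1)), 1L)

  # summed per-chain count differences track ground-truth event counts
  # (equality up to repeat hits on the same site)
  gt <- evolve_peptides(tree, cfg)$ground_truth
  tips <- tree$tip.label
  for (pair in list(c(1, 2), c(1, 4), c(2, 3))) {
    cd <- sum(vapply(names(aln), function(ch)
      identity_metrics(aln[[ch]][[tips[pair[1]]]],
                       aln[[ch]][[tips[pair[2]]]])$count_difference,
      numeric(1)))
    truth <- gt$substitution_counts[tips[pair[1]], tips[pair[2]]]
    expect_lte(cd, truth)
    expect_gte(cd, 0.9 * truth - 3)  # few multiple hits at this depth
  }
})

test_that("ground-truth markers align to exactly one taxon's spectra", {
  cfg <- simulation_config(seed = 31, detection_prob = 1,
                           n_individuals = 3)
  st <- simulate_pmf_study(4, 150, cfg)
  m <- align_peaks(normalize_spectra(st$spectra), 0.3)
  fams <- m$labels$family
  for (fam in names(st$ground_truth$marker_peaks)) {
    for (mk in st$ground_truth$marker_peaks[[fam]]) {
      feat <- which(abs(m$mz - mk) <= 0.3)
      expect_length(feat, 1L)
      present <- m$values[, feat] > 0
      expect_true(all(fams[present] == fam))
    }
  }
})

test_that("lower detection probability reduces within-group similarity", {
  sims <- vapply(c(0.9, 0.6, 0.4), function(dp) {
    cfg <- simulation_config(seed = 17, detection_prob = dp)
    st <- simulate_pmf_study(3, 100, cfg)
    m <- pipeline_matrix(st$spectra)
    mean(vapply(simper_within(m), `[[`, numeric(1), "average_score"))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})
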