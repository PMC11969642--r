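# monoisotopic residue masses (Da) of the 20 proteinogenic amino acids
.aa_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

#' Configuration for the synthetic collagen-PMF generator
#'
#' Describes the simulated world: a taxonomy with branch lengths in Mya,
#' per-leaf sample sizes, the peptide complement shared across taxa, the
#' divergence process that shifts peptide masses along branches at the
#' relative per-chain rates 0.7/0.9/1.0 (COL1A1/A2/A3), planted
#' taxon-unique marker peaks, detection and intensity noise, and matrix /
#' chemical-noise contamination.
#'
#' @param n_individuals Samples per leaf taxon (default 10, typical of
#'   the per-family sample sizes in published ZooMS datasets).
#' @param n_peptides Peptides in the root fingerprint (default 45, split
#'   across the three chains).
#' @param divergence_scale Global multiplier on the per-chain substitution
#'   rates (default 1; the expected substitution count between two taxa on
#'   chain c is `rate_c * divergence_scale * ED`).
#' @param detection_prob Probability a peptide of a taxon appears in an
#'   individual's spectrum (default 0.6).
#' @param intensity_cv Coefficient of variation of the log-normal intensity
#'   noise around each peptide's base intensity (default 1).
#' @param n_noise_peaks Random chemical-noise peaks per spectrum
#'   (default 30). The default noise triple (0.6, 1, 30) is calibrated so
#'   simulated within-group Bray-Curtis similarity falls in the 20-42
#'   range real collagen fingerprint datasets exhibit.
#' @param n_marker_peaks Taxon-unique peptide masses planted per leaf
#'   (default 3).
#' @param matrix_peak_mz m/z of ever-present matrix contaminant peaks
#'   (default 1060.1, decimal near 0.1 as matrix clusters show).
#' @param mz_range Peptide mass range in Da (default 900-3500).
#' @param chain_length Residues per collagen chain for the companion
#'   sequences (default 1014 = 338 Gly-Xaa-Yaa triplets).
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 10L, n_peptides = 45L,
                              divergence_scale = 1, detection_prob = 0.6,
                              intensity_cv = 1, n_noise_peaks = 30L,
                              n_marker_peaks = 3L, matrix_peak_mz = 1060.1,
                              mz_range = c(900, 3500), chain_length = 1014L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must lie in (0, 1]")
  if (n_peptides < 1L) stop("n_peptides must be >= 1")
  if (intensity_cv < 0) stop("intensity_cv must be >= 0")
  if (chain_length %% 3L != 0L) stop("chain_length must be a multiple of 3")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_peptides = as.integer(n_peptides),
                 divergence_scale = divergence_scale,
                 detection_prob = detection_prob,
                 intensity_cv = intensity_cv,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 n_marker_peaks = as.integer(n_marker_peaks),
                 matrix_peak_mz = matrix_peak_mz,
                 mz_range = mz_range,
                 chain_length = as.integer(chain_length),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Preset simulation configurations
#'
#' `"fish"` uses divergence_scale 2 and detection_prob 0.7 (disparate,
#' noisier fingerprints); `"mammal"` uses 1 and 0.9 (tight, well-detected
#' fingerprints) — chosen to reproduce the direction of the fish-vs-mammal
#' within-group-similarity contrast, not any printed magnitude.
#'
#' @param preset `"fish"` or `"mammal"`.
#' @param seed Mandatory integer seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
preset_config <- function(preset = c("fish", "mammal"), seed, ...) {
  preset <- match.arg(preset)
  if (preset == "fish")
    simulation_config(divergence_scale = 2, detection_prob = 0.7,
                      seed = seed, ...)
  else
    simulation_config(divergence_scale = 1, detection_prob = 0.9,
                      seed = seed, ...)
}

#' Simulate an ultrametric taxonomy
#'
#' Random bifurcating coalescent-shaped tree whose leaves all sit at depth
#' `depth_mya`, so leaf-pair divergence times span (0, depth_mya\].
#'
#' @param n_families Number of leaf taxa (>= 2).
#' @param depth_mya Tree depth in Mya (default 150).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with tip labels `Fam01, Fam02, ...`.
#' @export
simulate_taxonomy <- function(n_families, depth_mya = 150, seed = 1L) {
  if (n_families < 2L) stop("n_families must be >= 2")
  set.seed(seed)
  tree <- ape::rcoal(n_families,
                     tip.label = sprintf("Fam%02d", seq_len(n_families)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth_mya / depth
  tree
}

#' Pairwise evolutionary distances from an ultrametric tree
#'
#' @param tree An `ape::phylo` tree with branch lengths in Mya.
#' @return Symmetric matrix of divergence times (half the patristic
#'   distance), zero diagonal, in Mya.
#' @export
pairwise_ed <- function(tree) {
  stats::cophenetic(tree) / 2
}

# core evolutionary simulation shared by evolve_peptides() and
# generate_alignments(): deterministic given config$seed
.evolve <- function(tree, config) {
  set.seed(config$seed)
  chains <- names(.chain_rates)
  n_pep <- config$n_peptides
  pep_chain <- chains[(seq_len(n_pep) - 1L) %% 3L + 1L]

  # root peptide masses with peptide-like mass defect
  nominal <- sort(sample(seq(ceiling(config$mz_range[1L]),
                             floor(config$mz_range[2L])), n_pep))
  root_mz <- nominal + (4.95e-4 * nominal + stats::rnorm(n_pep, 0, 0.03)) %% 1

  # each observable peptide covers a residue span on its chain (about
  # 110 Da per residue); substitutions outside every span change the
  # sequence but are invisible in the fingerprint, as in real PMFs where
  # tryptic coverage of the chain is partial
  pep_len <- pmax(5L, round(root_mz / 110))
  span_hi <- lapply(chains, function(ch) cumsum(pep_len[pep_chain == ch]))
  names(span_hi) <- chains
  for (ch in chains)
    if (max(span_hi[[ch]]) > config$chain_length)
      stop("chain_length too short for the peptide complement")

  # root Gly-Xaa-Yaa sequences per chain
  aa_pool <- setdiff(names(.aa_masses), "G")
  n_res <- config$chain_length
  root_seq <- lapply(chains, function(ch) {
    s <- sample(aa_pool, n_res, replace = TRUE)
    s[seq(1L, n_res, by = 3L)] <- "G"
    s
  })
  names(root_seq) <- chains
  mutable_pos <- setdiff(seq_len(n_res), seq(1L, n_res, by = 3L))

  # preorder traversal accumulating states at every node
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  masses <- vector("list", n_node); seqs <- vector("list", n_node)
  events <- integer(n_node)           # substitution events from root
  events_ch <- base::matrix(0L, n_node, length(chains),
                            dimnames = list(NULL, chains))
  masses[[root]] <- root_mz; seqs[[root]] <- root_seq; events[root] <- 0L
  # process edges parent-before-child: preorder by reordering cladewise
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    len <- tr$edge.length[e]
    mz <- masses[[parent]]; sq <- seqs[[parent]]
    n_ev <- 0L
    events_ch[child, ] <- events_ch[parent, ]
    for (ch in chains) {
      lambda <- 0.5 * .chain_rates[[ch]] * config$divergence_scale * len
      n_sub <- stats::rpois(1L, lambda)
      if (n_sub == 0L) next
      n_ev <- n_ev + n_sub
      events_ch[child, ch] <- events_ch[child, ch] + n_sub
      for (k in seq_len(n_sub)) {
        pos <- sample(mutable_pos, 1L)
        old <- sq[[ch]][pos]
        repeat {
          new <- sample(aa_pool, 1L)
          delta <- .aa_masses[[new]] - .aa_masses[[old]]
          if (new != old && abs(delta) >= 0.02) break
        }
        sq[[ch]][pos] <- new
        slot <- findInterval(pos - 1L, span_hi[[ch]]) + 1L
        if (slot <= length(span_hi[[ch]])) {  # inside an observable peptide
          pep <- which(pep_chain == ch)[slot]
          mz[pep] <- mz[pep] + delta
        }
      }
    }
    masses[[child]] <- mz; seqs[[child]] <- sq
    events[child] <- events[parent] + n_ev
  }

  # planted taxon-unique marker peaks per leaf
  marker_mz <- vector("list", n_tip)
  if (config$n_marker_peaks > 0L) {
    # keep planted masses > 1 Da from every evolved leaf mass so each
    # marker aligns into a feature of exactly one taxon
    occupied <- unique(round(unlist(masses[seq_len(n_tip)])))
    pool <- setdiff(seq(ceiling(config$mz_range[1L]),
                        floor(config$mz_range[2L])),
                    c(occupied - 1L, occupied, occupied + 1L))
    picks <- sample(pool, n_tip * config$n_marker_peaks)
    for (i in seq_len(n_tip)) {
      nom <- picks[(i - 1L) * config$n_marker_peaks +
                     seq_len(config$n_marker_peaks)]
      marker_mz[[i]] <- sort(nom + (4.95e-4 * nom +
                                      stats::rnorm(length(nom), 0, 0.03)) %% 1)
    }
  } else {
    marker_mz <- replicate(n_tip, numeric(0), simplify = FALSE)
  }
  names(marker_mz) <- tree$tip.label

  # pairwise true substitution counts via root-path accumulation
  mrca <- ape::mrca(tree)
  subs <- base::matrix(0L, n_tip, n_tip,
                       dimnames = list(tree$tip.label, tree$tip.label))
  subs_ch <- lapply(chains, function(ch)
    base::matrix(0L, n_tip, n_tip,
                 dimnames = list(tree$tip.label, tree$tip.label)))
  names(subs_ch) <- chains
  for (i in seq_len(n_tip)) for (j in seq_len(n_tip)) if (i != j) {
    subs[i, j] <- events[i] + events[j] - 2L * events[mrca[i, j]]
    for (ch in chains)
      subs_ch[[ch]][i, j] <- events_ch[i, ch] + events_ch[j, ch] -
        2L * events_ch[mrca[i, j], ch]
  }

  peptide_sets <- lapply(seq_len(n_tip), function(i)
    data.frame(mz = c(masses[[i]], marker_mz[[i]]),
               chain = c(pep_chain, rep("marker", length(marker_mz[[i]]))),
               peptide = c(seq_len(n_pep),
                           n_pep + seq_along(marker_mz[[i]]))))
  names(peptide_sets) <- tree$tip.label
  leaf_seqs <- lapply(seq_len(n_tip), function(i)
    vapply(seqs[[i]], paste, character(1L), collapse = ""))
  names(leaf_seqs) <- tree$tip.label

  list(peptide_sets = peptide_sets,
       sequences = leaf_seqs,
       ground_truth = list(
         marker_peaks = marker_mz,
         substitution_counts = subs,
         substitution_counts_chain = subs_ch,
         ed_mya = pairwise_ed(tree),
         root_mz = root_mz,
         peptide_chain = pep_chain))
}

#' Evolve peptide mass sets along a taxonomy
#'
#' Starting from a root fingerprint of `n_peptides` masses with
#' peptide-like mass defects, substitution events accrue along each branch
#' as a Poisson process with rate `0.5 * chain_rate * divergence_scale` per
#' Mya per chain, so the expected substitution count separating two taxa on
#' chain c equals `rate_c * divergence_scale * ED`. Each event shifts one
#' peptide's mass by a residue-substitution mass difference (near-isobaric
#' Leu/Ile exchanges, invisible at PMF precision, are excluded) and changes
#' the corresponding chain sequence at a non-Gly position, coupling mass
#' and sequence divergence. Each leaf additionally carries
#' `n_marker_peaks` planted taxon-unique masses.
#'
#' @param tree An ultrametric `ape::phylo` (branch lengths in Mya), e.g.
#'   from [simulate_taxonomy()].
#' @param config A [simulation_config()].
#' @return List with `peptide_sets` (per leaf: data frame mz/chain/peptide)
#'   and `ground_truth` (planted marker peaks per leaf, pairwise true
#'   substitution counts, pairwise ED in Mya).
#' @export
evolve_peptides <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  ev <- .evolve(tree, config)
  ev[c("peptide_sets", "ground_truth")]
}

#' Companion aligned collagen-like sequences
#'
#' Returns the per-leaf chain sequences produced by the same substitution
#' events as [evolve_peptides()] under the same config (gap-free, so they
#' are trivially aligned). Every third residue is glycine, preserving the
#' Gly-Xaa-Yaa collagen motif.
#'
#' @inheritParams evolve_peptides
#' @return Named list, one element per chain (`COL1A1`, `COL1A2`,
#'   `COL1A3`), each a named character vector of leaf sequences.
#' @export
generate_alignments <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  seqs <- .evolve(tree, config)$sequences
  chains <- names(.chain_rates)
  out <- lapply(chains, function(ch)
    vapply(seqs, `[[`, character(1L), ch))
  names(out) <- chains
  out
}

#' Generate individual spectra from per-taxon peptide sets
#'
#' Each individual of a leaf observes each of the leaf's peptides with
#' probability `detection_prob`, at a log-normal intensity with coefficient
#' of variation `intensity_cv` around the peptide's base intensity;
#' `n_noise_peaks` chemical-noise peaks (random m/z and mass defect, low
#' intensity) and the ever-present matrix peak(s) at `matrix_peak_mz`
#' (mass defect near 0.1) are added. Byte-reproducible from the config
#' seed.
#'
#' @param peptide_sets Per-leaf peptide tables from [evolve_peptides()].
#' @param config A [simulation_config()].
#' @return List of [pmf_spectrum] objects (`<leaf>_<i>`), family label set
#'   to the leaf taxon, dataset `"synthetic"`.
#' @export
generate_spectra <- function(peptide_sets, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  sdlog <- if (config$intensity_cv > 0)
    sqrt(log(1 + config$intensity_cv^2)) else 0
  n_pep_total <- max(vapply(peptide_sets, nrow, integer(1L)))
  base_int <- stats::rlnorm(n_pep_total, meanlog = log(50), sdlog = 0.6)
  matrix_base <- 30
  spectra <- list()
  for (leaf in names(peptide_sets)) {
    pep <- peptide_sets[[leaf]]
    for (i in seq_len(config$n_individuals)) {
      detected <- stats::runif(nrow(pep)) <= config$detection_prob
      mz <- pep$mz[detected]
      intensity <- base_int[pep$peptide[detected]] *
        (if (sdlog > 0)
          stats::rlnorm(sum(detected), -sdlog^2 / 2, sdlog) else 1)
      if (config$n_noise_peaks > 0L) {
        nmz <- stats::runif(config$n_noise_peaks,
                            config$mz_range[1L], config$mz_range[2L])
        mz <- c(mz, nmz)
        intensity <- c(intensity,
                       stats::rlnorm(config$n_noise_peaks,
                                     meanlog = log(5), sdlog = 0.6))
      }
      if (length(config$matrix_peak_mz)) {
        mz <- c(mz, config$matrix_peak_mz)
        intensity <- c(intensity,
                       matrix_base * (if (sdlog > 0)
                         stats::rlnorm(length(config$matrix_peak_mz),
                                       -sdlog^2 / 2, sdlog) else 1))
      }
      ord <- order(mz)
      spectra[[paste0(leaf, "_", i)]] <-
        pmf_spectrum(paste0(leaf, "_", i), mz[ord], intensity[ord],
                     family = leaf, dataset = "synthetic")
    }
  }
  spectra
}

#' One-call synthetic PMF study
#'
#' Convenience wrapper: simulates a taxonomy, evolves peptides and
#' generates spectra, returning everything needed to exercise the full
#' pipeline.
#'
#' @param n_families Leaf taxa (default 5).
#' @param depth_mya Tree depth in Mya (default 150).
#' @param config A [simulation_config()]; its seed also seeds the taxonomy.
#' @return List with `tree`, `spectra`, `peptide_sets`, `ground_truth`,
#'   `config`.
#' @export
simulate_pmf_study <- function(n_families = 5L, depth_mya = 150, config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_taxonomy(n_families, depth_mya, seed = config$seed)
  ev <- evolve_peptides(tree, config)
  spectra <- generate_spectra(ev$peptide_sets, config)
  list(tree = tree, spectra = spectra, peptide_sets = ev$peptide_sets,
       ground_truth = ev$ground_truth, config = config)
}
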