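# Microdiversity screening: NTD, pairwise identity (vs an independent Gotoh
# DP oracle), beta-nearest similarity, clade reports, rarefaction and the
# depth-vs-NTD diagnostic.

test_that("NTD matches hand values and the row-minimum oracle", {
  tr <- worked_tree()
  expect_equal(ntd(tr), c(A = 2, B = 2, C = 4))
  cherry <- read_newick(text = "(A:0.01,B:0.01);")
  expect_equal(ntd(cherry), c(A = 0.02, B = 0.02))

  set.seed(51)
  tree <- random_tree(100)
  d <- patristic_matrix(tree)
  expected <- vapply(seq_len(100), function(i) min(d[i, -i]), numeric(1))
  expect_equal(unname(ntd(tree)), expected)
  # NTD <= distance to every other tip, and rerooting leaves it unchanged
  nt <- ntd(tree)
  expect_true(all(nt <= apply(d + diag(Inf, 100), 1, min) + 1e-12))
  expect_equal(ntd(midpoint_root(tree))[names(nt)], nt, tolerance = 1e-9)
})

test_that("pairwise identity: trivial cases and score agreement with a Gotoh oracle", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("acgt", "ACGA"), 75)  # case-insensitive

  # symmetry
  set.seed(52)
  a <- random_seq(120); b <- random_seq(110)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))

  # alignment scores equal an independent affine-gap DP on random pairs
  skip_if_not_installed("Biostrings")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  for (rep in 1:5) {
    x <- random_seq(60)
    y <- x
    # mutate and indel
    pos <- sample(60, 6)
    chars <- strsplit(y, "")[[1]]
    chars[pos] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    y <- paste(chars[-sample(60, 2)], collapse = "")
    aln <- Biostrings::pairwiseAlignment(x, y, type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 2, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracle_nw_score(x, y),
                 tolerance = 1e-9)
  }
})

test_that("beta-nearest similarity: forced nearest, exclusions, abundance-blindness", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  seqs <- c(A = "ACGTACGTAC", B = "ACGTACGTCC", C = "TTTTACGTAC")
  comm <- matrix(c(1, 0, 1, 1, 1, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  # A exclusive to s1; in s2 its nearest is B (d = 2)
  res <- beta_nearest_similarity(comm, d, seqs)
  a_row <- res$per_asv[res$per_asv$asv == "A", ]
  expect_equal(a_row$median_similarity, pairwise_identity(seqs["A"],
                                                          seqs["B"]))
  # B and C are present everywhere: excluded with a log entry
  expect_setequal(attr(res, "skipped_everywhere_present"), c("B", "C"))
  expect_false(any(res$per_asv$asv %in% c("B", "C")))

  # abundance rescaling changes nothing (presence/absence only)
  comm2 <- comm * matrix(runif(6, 0.5, 20), 3)
  res2 <- beta_nearest_similarity(comm2, d, seqs)
  expect_equal(res$replacements$similarity, res2$replacements$similarity)
})

test_that("two exclusive ASVs report their mutual identity", {
  cherry <- read_newick(text = "(A:0.01,B:0.01);")
  d <- patristic_matrix(cherry)
  seqs <- c(A = "ACGTACGTACGTACGTACGT", B = "ACGTACGTACGTACGTACGA")
  comm <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  res <- beta_nearest_similarity(comm, d, seqs)
  expect_equal(res$per_asv$median_similarity,
               rep(pairwise_identity(seqs["A"], seqs["B"]), 2))
})

test_that("planted microdiverse clade separates from background in the report", {
  set.seed(53)
  tree <- random_tree(90)
  clade <- pick_clade(tree, 20)
  tree <- compress_clade(tree, clade, 0.02)
  seqs <- evolve_sequences(tree, length = 250)
  sim <- plant_hos_clade(tree, clade, n_samples = 12)
  d <- patristic_matrix(tree)
  rep <- clade_microdiversity_report(clade, setdiff(tree$tip.label, clade),
                                     comm = sim$comm, seqs = seqs, d = d)
  expect_lt(median(rep$ntd_clade), median(rep$ntd_background))
  expect_gt(rep$frac_over_97[["clade"]], rep$frac_over_97[["background"]])
  expect_lt(rep$p_ntd, 0.01)
  expect_lt(rep$p_similarity, 0.01)
  expect_false(rep$underpowered)
})

test_that("self-comparison report is null and single-tip clades are flagged", {
  set.seed(54)
  tree <- random_tree(30)
  seqs <- evolve_sequences(tree, length = 100)
  sim <- plant_hos_clade(tree, character(0), n_samples = 6,
                         background_occupancy = 0.5)
  d <- patristic_matrix(tree)
  tips <- tree$tip.label
  rep <- clade_microdiversity_report(tips, tips, comm = sim$comm,
                                     seqs = seqs, d = d)
  expect_gt(rep$p_ntd, 0.9)
  expect_equal(rep$frac_over_97[["clade"]], rep$frac_over_97[["background"]])

  rep1 <- clade_microdiversity_report(tips[1], tips[-1], comm = sim$comm,
                                      seqs = seqs, d = d)
  expect_true(rep1$underpowered)
})

test_that("clade rarefaction: exact boundary depths and the hypergeometric expectation", {
  counts <- matrix(c(10, 10, 10, 10), 4, 1,
                   dimnames = list(paste0("a", 1:4), "s1"))
  full <- clade_rarefaction(counts, paste0("a", 1:4), depths = 40, reps = 10)
  expect_equal(full$mean_richness, 4)
  expect_equal(full$sd_richness, 0)
  one <- clade_rarefaction(counts, paste0("a", 1:4), depths = 1, reps = 20)
  expect_equal(one$mean_richness, 1)

  set.seed(55)
  curve <- clade_rarefaction(counts, paste0("a", 1:4), depths = c(5, 15),
                             reps = 600)
  for (i in seq_len(nrow(curve))) {
    exp_rich <- oracle_expected_richness(rep(10, 4), curve$depth[i])
    se <- curve$sd_richness[i] / sqrt(600)
    expect_lt(abs(curve$mean_richness[i] - exp_rich), 4 * se + 1e-9)
  }
  expect_warning(clade_rarefaction(counts, paste0("a", 1:4), depths = 100),
                 "truncated")
})

test_that("depth_vs_ntd: degenerate flat trees flagged, caterpillar case matches hand enumeration", {
  # perfectly balanced ultrametric tree: NTD constant
  bal <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  out <- depth_vs_ntd(bal)
  expect_true(is.na(out$rho))
  expect_equal(out$flag, "zero_variance")

  # 4-tip caterpillar, hand-enumerated depths and NTDs
  cat4 <- read_newick(text = "(((A:1,B:2):1,C:4):1,D:8);")
  out2 <- depth_vs_ntd(cat4)
  hand_depth <- c(A = 3, B = 4, C = 5, D = 8)
  hand_ntd <- c(A = 3, B = 3, C = 6, D = 11)
  expect_equal(out2$data$depth, unname(hand_depth[out2$data$unit]))
  expect_equal(out2$data$ntd, unname(hand_ntd[out2$data$unit]))
  ref <- suppressWarnings(cor.test(hand_depth, hand_ntd,
                                   method = "spearman"))
  expect_equal(out2$rho, unname(ref$estimate))
})
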