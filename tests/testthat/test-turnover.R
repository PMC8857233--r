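# Community-level turnover statistics against hand computations, a
# double-loop oracle, and picante/vegan cross-checks.

test_that("bmntd matches hand computation and flags identical membership", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  comm <- matrix(c(1, 0, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(bmntd("s1", "s2", comm, d, weighting = "presence"), 4)

  same <- matrix(c(1, 2, 1, 3, 0, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  out <- bmntd("s1", "s2", same, d)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "identical_membership"))
})

test_that("bmntd equals the double-loop oracle and is symmetric", {
  set.seed(21)
  for (rep in 1:3) {
    ds <- random_dataset(30, 4)
    smp <- colnames(ds$comm)
    for (w in c("abundance", "presence")) {
      v1 <- bmntd(smp[1], smp[2], ds$comm, ds$d, weighting = w)
      expect_equal(as.numeric(v1),
                   oracle_bmntd(smp[1], smp[2], ds$comm, ds$d, w),
                   tolerance = 1e-12)
      expect_equal(as.numeric(v1),
                   as.numeric(bmntd(smp[2], smp[1], ds$comm, ds$d,
                                    weighting = w)),
                   tolerance = 1e-12)
    }
  }
})

test_that("bmntd agrees with picante::comdistnt on disjoint samples", {
  skip_if_not_installed("picante")
  set.seed(22)
  tree <- random_tree(20)
  ids <- tree$tip.label
  comm <- matrix(0, 20, 2, dimnames = list(ids, c("s1", "s2")))
  comm[1:8, 1] <- rlnorm(8)
  comm[9:20, 2] <- rlnorm(12)
  d <- patristic_matrix(tree)
  ours <- bmntd("s1", "s2", comm, d, weighting = "abundance")
  pic <- picante::comdistnt(t(comm), d, abundance.weighted = TRUE)
  expect_equal(as.numeric(ours), as.numeric(pic), tolerance = 1e-10)
  ours_p <- bmntd("s1", "s2", comm, d, weighting = "presence")
  pic_p <- picante::comdistnt(t(comm), d, abundance.weighted = FALSE)
  expect_equal(as.numeric(ours_p), as.numeric(pic_p), tolerance = 1e-10)
})

test_that("bnti: identical rich samples give strong homogeneous-selection signal", {
  set.seed(23)
  tree <- random_tree(60)
  ids <- tree$tip.label
  comm <- matrix(0, 60, 2, dimnames = list(ids, c("s1", "s2")))
  present <- sample(ids, 25)
  comm[present, 1] <- comm[present, 2] <- rlnorm(25)
  d <- patristic_matrix(tree)
  set.seed(1)
  z <- bnti("s1", "s2", comm, d, n_reps = 199)
  expect_lt(z, -2)
})

test_that("bnti is symmetric in the pair and z = 0 for a constant matching null", {
  set.seed(24)
  ds <- random_dataset(20, 3)
  set.seed(5)
  z12 <- bnti("s01", "s02", ds$comm, ds$d, n_reps = 99)
  set.seed(5)
  z21 <- bnti("s02", "s01", ds$comm, ds$d, n_reps = 99)
  expect_equal(as.numeric(z12), as.numeric(z21))

  # equidistant star-like distances: every permutation gives the same bMNTD
  ids <- paste0("t", 1:6)
  d <- matrix(1, 6, 6, dimnames = list(ids, ids)); diag(d) <- 0
  comm <- matrix(0, 6, 2, dimnames = list(ids, c("a", "b")))
  comm[1:3, "a"] <- 1; comm[3:6, "b"] <- 1
  expect_equal(as.numeric(bnti("a", "b", comm, d, n_reps = 50)), 0)
})

test_that("bray_curtis matches hand values and vegan", {
  comm <- matrix(c(0.5, 0.25, 0.5, 0.25, 0, 0.5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("x", "y")))
  expect_equal(bray_curtis("x", "y", comm), 0.5)
  same <- cbind(comm[, 1, drop = FALSE], x2 = comm[, 1])
  colnames(same) <- c("x", "x2")
  expect_equal(bray_curtis("x", "x2", same), 0)
  disj <- matrix(c(1, 0, 0, 2), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis("x", "y", disj), 1)

  skip_if_not_installed("vegan")
  set.seed(25)
  ds <- random_dataset(15, 2)
  rel <- sweep(ds$comm, 2, colSums(ds$comm), "/")
  expect_equal(bray_curtis("s01", "s02", ds$comm),
               as.numeric(vegan::vegdist(t(rel), method = "bray")),
               tolerance = 1e-10)
})

test_that("Raup-Crick scoring formula and identical-sample behavior", {
  rc <- phyloscore:::.rc_from_null
  expect_equal(rc(0.5, rep(0.5, 99)), 0)    # all ties
  expect_equal(rc(0.9, rep(0.1, 99)), 1)    # obs above every draw
  expect_equal(rc(0.1, rep(0.9, 99)), -1)

  set.seed(26)
  ds <- random_dataset(40, 6, occupancy = 0.5)
  counts <- round(ds$comm * 50) + (ds$comm > 0)  # integer counts
  comm <- counts
  comm[, 2] <- comm[, 1]  # make sample 2 identical to sample 1
  set.seed(3)
  v <- rc_bray("s01", "s02", comm, n_reps = 199)
  expect_lte(v, -0.95)

  single <- matrix(c(3, 4), 1, 2, dimnames = list("A", c("x", "y")))
  out <- rc_bray("x", "y", single, n_reps = 10)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "degenerate_pool")
})

test_that("process assignment follows the strict threshold bands", {
  expect_equal(assign_process(-3.1), "homogeneous_selection")
  expect_equal(assign_process(2.5), "variable_selection")
  expect_equal(assign_process(0.5, 0.97), "dispersal_limitation")
  expect_equal(assign_process(0.5, -0.97), "homogenizing_dispersal")
  expect_equal(assign_process(0.5, 0.2), "undominated")
  # boundaries fall through to the next stage
  expect_equal(assign_process(-2, -0.99), "homogenizing_dispersal")
  expect_equal(assign_process(2, 0.99), "dispersal_limitation")
  expect_equal(assign_process(0, 0.95), "undominated")
  expect_equal(assign_process(0, -0.95), "undominated")
  expect_equal(assign_process(NA_real_), "undefined")
})

test_that("assign_processes covers all pairs and fractions sum to one", {
  set.seed(27)
  ds <- random_dataset(25, 4, occupancy = 0.5)
  groups <- setNames(c("g1", "g1", "g2", "g2"), colnames(ds$comm))
  set.seed(2)
  pt <- assign_processes(ds$comm, ds$d, n_reps = 59, groups = groups)
  expect_equal(nrow(pt), choose(4, 2))
  s <- attr(pt, "summary")
  expect_equal(sum(s$overall$fraction), 1)
  expect_setequal(unique(pt$stratum), c("within", "between"))
  expect_true(all(is.na(pt$rc_bray[abs(pt$bnti) > 2])))
})
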