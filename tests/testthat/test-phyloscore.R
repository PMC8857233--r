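# The per-ASV phyloscore z and its null machinery, checked against hand
# enumeration and a literal subset-enumeration oracle.

three_taxon_comm <- function() {
  matrix(c(1, 0, 0, 1, 0, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("j", "k")))
}

test_that("nearest beta distance is the hand-computed minimum", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  comm <- matrix(c(1, 0, 0, 1, 0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("j", "k")))
  expect_equal(nearest_beta_distance("A", "k", comm, d), 2)  # to B
  comm2 <- three_taxon_comm(); comm2["C", "k"] <- 1; comm2["B", "k"] <- 0
  expect_equal(nearest_beta_distance("A", "k", comm2, d), 4)  # to C

  set.seed(5)
  ds <- random_dataset(40, 4)
  pres <- ds$comm > 0
  for (s in colnames(ds$comm)) {
    absent <- rownames(ds$comm)[!pres[, s]]
    for (a in head(absent, 5)) {
      full_scan <- min(vapply(rownames(ds$comm)[pres[, s]],
                              function(x) ds$d[a, x], numeric(1)))
      expect_equal(nearest_beta_distance(a, s, ds$comm, ds$d), full_scan)
    }
  }
})

test_that("null nearest distances follow the exact two-outcome law on the worked tree", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  comm <- three_taxon_comm()  # k contains only B: N_k = 1, pool {B, C}
  # N_k = pool size: every draw is the whole pool
  comm_full <- comm; comm_full[c("B", "C"), "k"] <- 1
  vals <- null_nearest_distances("A", "k", comm_full, d, M = 20)
  expect_true(all(vals == 2))  # min over {B, C} always

  set.seed(2)
  draws <- null_nearest_distances("A", "k", comm, d, M = 10000,
                                  sampling = "simple")
  expect_setequal(unique(draws), c(2, 4))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 3), 3 * se)

  set.seed(9)
  v1 <- null_nearest_distances("A", "k", comm, d, M = 50)
  set.seed(9)
  v2 <- null_nearest_distances("A", "k", comm, d, M = 50)
  expect_identical(v1, v2)
})

test_that("exhaustive null: closed form equals literal subset enumeration", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  comm <- three_taxon_comm()
  ex <- exhaustive_null("A", "k", comm, d)
  expect_equal(ex$mean_log, (log(2) + log(4)) / 2)
  expect_equal(ex$sd_log, (log(4) - log(2)) / 2)

  # N_k = pool size leaves a single subset: sd 0
  comm_full <- comm; comm_full[c("B", "C"), "k"] <- 1
  expect_equal(exhaustive_null("A", "k", comm_full, d)$sd_log, 0)

  # random fixtures: closed form vs combn enumeration
  set.seed(31)
  for (rep in 1:3) {
    ds <- random_dataset(9, 3)
    pres <- ds$comm > 0
    for (s in colnames(ds$comm)) {
      absent <- rownames(ds$comm)[!pres[, s]]
      for (a in head(absent, 3)) {
        cf <- exhaustive_null(a, s, ds$comm, ds$d, method = "closed_form")
        en <- exhaustive_null(a, s, ds$comm, ds$d, method = "enumerate")
        expect_equal(cf$mean_log, en$mean_log, tolerance = 1e-10)
        expect_equal(cf$sd_log, en$sd_log, tolerance = 1e-10)
        expect_equal(cf$mu3, en$mu3, tolerance = 1e-10)
        expect_equal(cf$mu4, en$mu4, tolerance = 1e-10)
      }
    }
  }
})

test_that("worked-tree phyloscore is exactly -1 under the exhaustive null", {
  tr <- worked_tree()
  d <- patristic_matrix(tr)
  comm <- three_taxon_comm()
  rec <- phyloscore("A", "j", "k", comm, d, exact = TRUE)
  expect_equal(rec$z, -1)
  expect_equal(rec$d_obs, 2)

  set.seed(4)
  mc <- phyloscore("A", "j", "k", comm, d, M = 100)
  ex <- exhaustive_null("A", "k", comm, d)
  se <- phyloscore_mc_se(ex, -1, 100)
  expect_lt(abs(mc$z - (-1)), 3 * se)
})

test_that("z is zero when the observed distance equals the null geometric mean", {
  # four taxa, recipient k = {B}, N_k = 1: null outcomes are d(A,B), d(A,C),
  # d(A,D) with equal weight; d(A,B) = 4 is the geometric mean of {4, 2, 8}
  ids <- c("A", "B", "C", "D")
  d <- matrix(5, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 4
  d["A", "C"] <- d["C", "A"] <- 2
  d["A", "D"] <- d["D", "A"] <- 8
  comm <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), nrow = 4, byrow = TRUE,
                 dimnames = list(ids, c("j", "k")))
  rec <- phyloscore("A", "j", "k", comm, d, exact = TRUE)
  expect_lt(abs(rec$z), 1e-9)
})

test_that("record bookkeeping: never-unique ASVs contribute nothing, singletons twice", {
  set.seed(6)
  ds <- random_dataset(12, 3)
  comm <- ds$comm
  comm["t1", ] <- 1                      # present everywhere
  comm["t2", ] <- c(1, 0, 0)             # present in exactly one sample
  rec <- all_phyloscores(comm, ds$d, M = 20)
  expect_equal(sum(rec$asv == "t1"), 0L)
  expect_equal(sum(rec$asv == "t2"), 2L)
  # both directions present for each contributing pair
  expect_true(all(rec$donor != rec$recipient))
})

test_that("phyloscores are abundance-blind and bit-reproducible under a seed", {
  set.seed(8)
  ds <- random_dataset(25, 5)
  set.seed(123)
  r1 <- all_phyloscores(ds$comm, ds$d, M = 30)
  comm_scaled <- ds$comm * matrix(runif(length(ds$comm), 0.1, 10),
                                  nrow(ds$comm))
  set.seed(123)
  r2 <- all_phyloscores(comm_scaled, ds$d, M = 30)
  expect_identical(r1$z, r2$z)
  set.seed(123)
  r3 <- all_phyloscores(ds$comm, ds$d, M = 30)
  expect_identical(r1, r3)
})

test_that("Monte-Carlo z converges to the exhaustive z on a small fixture", {
  set.seed(14)
  ds <- random_dataset(10, 3)
  pres <- ds$comm > 0
  rec <- all_phyloscores(ds$comm, ds$d, M = 100)
  checked <- 0L
  for (i in head(seq_len(nrow(rec)), 30)) {
    ex <- exhaustive_null(rec$asv[i], rec$recipient[i], ds$comm, ds$d)
    if (ex$sd_log == 0) next
    z_ex <- (log(rec$d_obs[i]) - ex$mean_log) / ex$sd_log
    se <- phyloscore_mc_se(ex, z_ex, 100)
    expect_lt(abs(rec$z[i] - z_ex), 3 * pmax(se, 1e-12))
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})

test_that("aggregation arithmetic and flags", {
  rec <- data.frame(asv = c("x", "x", "x", "y"),
                    donor = "a", recipient = "b", d_obs = 1,
                    null_mean_log = 0, null_sd_log = 1,
                    z = c(-1, -2, 3, NA), flag = c("ok", "ok", "ok",
                                                   "sd_zero"))
  s <- aggregate_phyloscores(rec, asv_ids = c("x", "y", "z"))
  xs <- s[s$asv == "x", ]
  expect_equal(xs$total, 0)
  expect_equal(xs$mean, 0)
  expect_equal(xs$median, -1)
  expect_equal(xs$n_pairs, 3)
  ys <- s[s$asv == "y", ]
  expect_equal(ys$n_pairs, 0)
  expect_equal(ys$total, 0)
  expect_equal(ys$n_flagged, 1L)
  expect_true(is.na(ys$mean_over_sd))
  expect_equal(s[s$asv == "z", "flag"], "no_records")

  one <- rec[1, ]
  s1 <- aggregate_phyloscores(one)
  expect_true(is.na(s1$mean_over_sd))  # sd of a single value is undefined
})
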