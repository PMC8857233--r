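# Core per-ASV phyloscore machinery.
#
# For a focal ASV i absent from community k with richness N_k, the null model
# draws N_k taxa (uniformly, without replacement) from the regional pool minus
# i and records the nearest patristic distance from i to the draw. The minimum
# of a uniform random N-subset of the P pool distances is the r-th closest
# distance with probability
#     P(rank = r) = choose(P - r, N - 1) / choose(P, N),  r = 1..P-N+1,
# which this file exploits twice: exact ("exhaustive") null moments are a
# weighted sum over ranks, and Monte-Carlo draws are inverse-CDF samples of the
# rank distribution -- identical in law to drawing subsets, but O(P + M) per
# record instead of O(M * N_k).

# Floor a patristic matrix at half its smallest positive entry so that log()
# never sees a zero (identical placements / zero-length terminal branches).
.floor_distances <- function(d) {
  pos <- d[d > 0]
  if (!length(pos)) stop("distance matrix has no positive entries")
  eps <- min(pos) / 2
  n_floored <- (sum(d <= 0) - nrow(d)) / 2  # off-diagonal zeros, per pair
  out <- pmax(d, eps)
  diag(out) <- 0
  list(d = out, eps = eps, n_floored = n_floored)
}

# P(min of a uniform random N-subset of P sorted values is the r-th smallest),
# r = 1..P-N+1. Computed by the stable ratio recurrence
# w_{r+1}/w_r = (P-r-N+1)/(P-r), w_1 = N/P.
.min_rank_pmf <- function(P, N) {
  if (N < 1L || N > P) stop("need 1 <= N <= P")
  R <- P - N + 1L
  w <- numeric(R)
  w[1L] <- N / P
  if (R > 1L) {
    r <- seq_len(R - 1L)
    w[-1L] <- w[1L] * cumprod((P - r - N + 1) / (P - r))
  }
  w
}

# Internal dataset view shared by the vectorized scorers: floored distances,
# per-row sorted log-distances to all other taxa, presence matrix.
.phyloscore_env <- function(comm, d) {
  comm <- validate_community(comm)
  ids <- rownames(comm)
  if (!all(ids %in% rownames(d))) {
    stop("ASVs missing from the distance matrix: ",
         paste(utils::head(setdiff(ids, rownames(d)), 5L), collapse = ", "))
  }
  d <- d[ids, ids]
  fl <- .floor_distances(d)
  S <- length(ids)
  sorted_log <- matrix(0, S, S - 1L)
  sorted_val <- matrix(0, S, S - 1L)
  for (i in seq_len(S)) {
    v <- sort(fl$d[i, -i])
    sorted_val[i, ] <- v
    sorted_log[i, ] <- log(v)
  }
  rownames(sorted_log) <- rownames(sorted_val) <- ids
  list(ids = ids, d = fl$d, eps = fl$eps, n_floored = fl$n_floored,
       pres = comm > 0, sorted_log = sorted_log, sorted_val = sorted_val)
}

# Inverse-CDF ranks for n records x M draws from one rank CDF. Stratified
# sampling places one uniform in each of the M probability strata per record
# (variance-reduced Monte Carlo); "simple" is plain iid sampling.
.draw_ranks <- function(cdf, M, n, sampling) {
  u <- stats::runif(M * n)
  if (sampling == "stratified") u <- (rep.int(seq_len(M), n) - u) / M
  r <- findInterval(u, cdf) + 1L
  pmin(r, length(cdf))
}

#' Nearest phylogenetic distance of an ASV to a community
#'
#' The observed quantity of the phyloscore: the minimum patristic distance
#' between focal ASV `asv` (absent from `sample`) and the ASVs present in
#' `sample`.
#'
#' @param asv Focal ASV id.
#' @param sample Sample id in which the focal ASV is absent.
#' @param comm Community matrix (ASV x sample).
#' @param d Patristic distance matrix covering the ASVs.
#' @return Nearest patristic distance (not floored, not logged).
#' @export
nearest_beta_distance <- function(asv, sample, comm, d) {
  comm <- validate_community(comm)
  present <- rownames(comm)[comm[, sample] > 0]
  if (!length(present)) stop("sample ", sample, " is empty")
  if (asv %in% present) stop(asv, " is present in ", sample)
  min(d[asv, present])
}

#' Null distribution of nearest distances for a focal ASV
#'
#' Draws `M` nearest-distance minima, each corresponding to a uniform random
#' draw of `N_k` taxa (the observed richness of `sample`) from the regional
#' pool excluding the focal ASV. Sampling is via the exact rank distribution
#' of the subset minimum; `sampling = "stratified"` (default) spreads the
#' uniforms across the M probability strata to reduce Monte-Carlo variance,
#' `"simple"` draws iid.
#'
#' @inheritParams nearest_beta_distance
#' @param M Number of null draws.
#' @param sampling `"stratified"` or `"simple"`.
#' @return Numeric vector of M nearest distances (floored at the dataset's
#'   epsilon, see Details in [phyloscore()]).
#' @export
null_nearest_distances <- function(asv, sample, comm, d, M = 100L,
                                   sampling = c("stratified", "simple")) {
  sampling <- match.arg(sampling)
  env <- .phyloscore_env(comm, d)
  i <- match(asv, env$ids)
  if (is.na(i)) stop("unknown ASV: ", asv)
  N <- sum(env$pres[, sample])
  P <- length(env$ids) - 1L
  if (N < 1L) stop("sample ", sample, " is empty")
  if (N > P) stop("pool (", P, ") smaller than richness (", N, ")")
  cdf <- cumsum(.min_rank_pmf(P, N))
  ranks <- .draw_ranks(cdf, M, 1L, sampling)
  env$sorted_val[i, ranks]
}

#' Exact null moments of the log nearest distance
#'
#' Mean and standard deviation (population form) of the log-transformed
#' nearest distance of `asv` under the uniform random-membership null for
#' `sample`, over *all* subsets of the pool. `method = "closed_form"` uses the
#' rank distribution of the subset minimum and is exact at any pool size;
#' `method = "enumerate"` literally enumerates subsets (an independent check,
#' capped by `cap` subsets).
#'
#' @inheritParams nearest_beta_distance
#' @param method `"closed_form"` or `"enumerate"`.
#' @param cap Maximum number of subsets to enumerate.
#' @return List with `mean_log`, `sd_log`, and central moments `mu2`..`mu4` of
#'   the log null distribution (used for Monte-Carlo standard errors).
#' @export
exhaustive_null <- function(asv, sample, comm, d,
                            method = c("closed_form", "enumerate"),
                            cap = 2e5) {
  method <- match.arg(method)
  env <- .phyloscore_env(comm, d)
  i <- match(asv, env$ids)
  if (is.na(i)) stop("unknown ASV: ", asv)
  N <- sum(env$pres[, sample])
  P <- length(env$ids) - 1L
  if (N < 1L) stop("sample ", sample, " is empty")
  if (N > P) stop("pool (", P, ") smaller than richness (", N, ")")
  if (method == "closed_form") {
    w <- .min_rank_pmf(P, N)
    L <- env$sorted_log[i, seq_along(w)]
  } else {
    if (choose(P, N) > cap) {
      stop("choose(", P, ", ", N, ") exceeds the enumeration cap (", cap,
           "); use method = 'closed_form' or Monte-Carlo")
    }
    pool <- setdiff(env$ids, asv)
    mins <- utils::combn(pool, N,
                         FUN = function(s) min(env$d[asv, s]))
    L <- log(mins)
    w <- rep(1 / length(L), length(L))
  }
  m <- sum(w * L)
  cm <- vapply(2:4, function(p) sum(w * (L - m)^p), numeric(1))
  list(mean_log = m, sd_log = sqrt(cm[1L]),
       mu2 = cm[1L], mu3 = cm[2L], mu4 = cm[3L])
}

#' Delta-method Monte-Carlo standard error of a phyloscore z
#'
#' Standard error of the iid Monte-Carlo z estimator at a given M, from the
#' exact central moments of the log null distribution (as returned by
#' [exhaustive_null()]).
#'
#' @param exh List with `mu2`, `mu3`, `mu4` (central moments of log null).
#' @param z The exhaustive z value.
#' @param M Number of Monte-Carlo draws.
#' @return Standard error of the Monte-Carlo z.
#' @export
phyloscore_mc_se <- function(exh, z, M) {
  v <- 1 + z^2 * (exh$mu4 / exh$mu2^2 - 1) / 4 + z * exh$mu3 / exh$mu2^1.5
  sqrt(pmax(v, 0) / M)
}

#' Phyloscore of a single (ASV, donor sample, recipient sample) triple
#'
#' The phyloscore z quantifies how much closer (negative z) or farther
#' (positive z) the nearest relative of ASV `asv` in recipient community
#' `recipient` is, compared to random communities of the same richness:
#' \deqn{z = (\log d_{obs} - \langle \log d^0 \rangle) / \sigma^0,}
#' with natural logs, where the null mean and standard deviation are those of
#' the log-transformed null nearest distances. Distances are floored at half
#' the smallest positive patristic distance in the dataset before logging.
#'
#' @param asv Focal ASV, present in `donor`, absent from `recipient`.
#' @param donor Sample id where the focal ASV is present.
#' @param recipient Sample id where it is absent.
#' @inheritParams null_nearest_distances
#' @param exact Use the exact null moments instead of Monte-Carlo sampling.
#' @return One-row data.frame: `asv`, `donor`, `recipient`, `d_obs`,
#'   `null_mean_log`, `null_sd_log`, `z`, `flag` (`"ok"` or `"sd_zero"`).
#' @export
phyloscore <- function(asv, donor, recipient, comm, d, M = 100L,
                       sampling = c("stratified", "simple"), exact = FALSE) {
  sampling <- match.arg(sampling)
  comm <- validate_community(comm)
  if (comm[asv, donor] <= 0) stop(asv, " is absent from donor ", donor)
  if (comm[asv, recipient] > 0) stop(asv, " is present in recipient ",
                                     recipient)
  env <- .phyloscore_env(comm, d)
  i <- match(asv, env$ids)
  kpres <- env$ids[env$pres[, recipient]]
  d_obs <- min(env$d[asv, kpres])
  if (exact) {
    ex <- exhaustive_null(asv, recipient, comm, d)
    m <- ex$mean_log; s <- ex$sd_log
  } else {
    nd <- log(null_nearest_distances(asv, recipient, comm, d, M, sampling))
    m <- mean(nd)
    s <- sqrt(mean(nd^2) - m^2)
  }
  flag <- if (s > 0) "ok" else "sd_zero"
  data.frame(asv = asv, donor = donor, recipient = recipient, d_obs = d_obs,
             null_mean_log = m, null_sd_log = s,
             z = if (s > 0) (log(d_obs) - m) / s else NA_real_,
             flag = flag, stringsAsFactors = FALSE)
}

#' Phyloscores for every ASV and sample pair
#'
#' For every unordered sample pair (j, k) and every ASV present in exactly one
#' of the two, computes the phyloscore record in both directions. The null
#' pool defaults to all ASVs in the dataset minus the focal ASV (`"regional"`);
#' `pool = "pair"` restricts it to the taxa of the two compared samples.
#' Deterministic given the RNG state: pairs are visited in column order, the
#' j-to-k direction before k-to-j, with one block of uniforms per direction.
#'
#' @inheritParams null_nearest_distances
#' @param pool `"regional"` or `"pair"` null pool.
#' @param groups Optional named vector mapping samples to group labels, used by
#'   `pair_filter`.
#' @param pair_filter `NULL` (all pairs), `"within"` or `"between"` group
#'   pairs.
#' @return A data.frame of class `phyloscore_table`, one row per
#'   (ASV, donor, recipient) record, with attributes `n_floored` (distances
#'   floored before logging) and `M`.
#' @export
all_phyloscores <- function(comm, d, M = 100L,
                            sampling = c("stratified", "simple"),
                            pool = c("regional", "pair"),
                            groups = NULL, pair_filter = NULL) {
  sampling <- match.arg(sampling)
  pool <- match.arg(pool)
  env <- .phyloscore_env(comm, d)
  samples <- colnames(env$pres)
  ns <- length(samples)
  if (ns < 2L) stop("need >= 2 samples")
  S <- length(env$ids)
  P <- S - 1L
  Nk <- colSums(env$pres)
  cdfs <- lapply(seq_len(ns), function(k) {
    if (Nk[k] >= 1L && Nk[k] <= P) cumsum(.min_rank_pmf(P, Nk[k])) else NULL
  })
  keep_pair <- function(a, b) {
    if (is.null(pair_filter)) return(TRUE)
    if (is.null(groups)) stop("pair_filter requires groups")
    same <- identical(groups[[a]], groups[[b]])
    if (pair_filter == "within") same else !same
  }
  out <- vector("list", ns * (ns - 1L))
  pos <- 0L
  for (jj in seq_len(ns - 1L)) {
    for (kk in seq((jj + 1L), ns)) {
      if (!keep_pair(samples[jj], samples[kk])) next
      for (dir in list(c(jj, kk), c(kk, jj))) {
        j <- dir[1L]; k <- dir[2L]
        uniq <- which(env$pres[, j] & !env$pres[, k])
        if (!length(uniq)) next
        kpres <- which(env$pres[, k])
        if (!length(kpres)) next
        dsub <- env$d[uniq, kpres, drop = FALSE]
        d_obs <- apply(dsub, 1L, min)
        n <- length(uniq)
        if (pool == "regional") {
          cdf <- cdfs[[k]]
          if (is.null(cdf)) next
          ranks <- .draw_ranks(cdf, M, n, sampling)
          vals <- matrix(env$sorted_log[cbind(rep(uniq, each = M), ranks)],
                         nrow = M)
        } else {
          pair_taxa <- which(env$pres[, j] | env$pres[, k])
          vals <- matrix(NA_real_, M, n)
          for (t in seq_len(n)) {
            pl <- setdiff(pair_taxa, uniq[t])
            if (Nk[k] > length(pl)) next
            sl <- sort(log(env$d[uniq[t], pl]))
            cdf_t <- cumsum(.min_rank_pmf(length(pl), Nk[k]))
            vals[, t] <- sl[.draw_ranks(cdf_t, M, 1L, sampling)]
          }
        }
        mlog <- colMeans(vals)
        slog <- sqrt(pmax(colMeans(vals^2) - mlog^2, 0))
        z <- (log(d_obs) - mlog) / slog
        flag <- ifelse(is.finite(z), "ok", "sd_zero")
        z[!is.finite(z)] <- NA_real_
        pos <- pos + 1L
        out[[pos]] <- data.frame(
          asv = env$ids[uniq], donor = samples[j], recipient = samples[k],
          d_obs = d_obs, null_mean_log = mlog, null_sd_log = slog,
          z = z, flag = flag, stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  res <- if (pos) do.call(rbind, out[seq_len(pos)]) else
    data.frame(asv = character(0), donor = character(0),
               recipient = character(0), d_obs = numeric(0),
               null_mean_log = numeric(0), null_sd_log = numeric(0),
               z = numeric(0), flag = character(0))
  attr(res, "n_floored") <- env$n_floored
  attr(res, "M") <- M
  class(res) <- c("phyloscore_table", "data.frame")
  res
}

#' Aggregate phyloscores per ASV
#'
#' Summarizes each ASV's phyloscore records across all community pairs: the
#' total (sum -- the default phylofactorization input), mean, median, number
#' of records and mean/sd quotient. Records flagged `sd_zero` are excluded and
#' counted. ASVs from `asv_ids` with no records are reported with total 0 and
#' `n_pairs` 0 (flagged `no_records`).
#'
#' @param records A `phyloscore_table` from [all_phyloscores()].
#' @param asv_ids Optional universe of ASV ids to report (e.g. all rows of the
#'   community matrix).
#' @return data.frame with one row per ASV: `asv`, `total`, `mean`, `median`,
#'   `n_pairs`, `mean_over_sd`, `n_flagged`, `flag`.
#' @export
aggregate_phyloscores <- function(records, asv_ids = NULL) {
  ok <- records[records$flag == "ok" & is.finite(records$z), , drop = FALSE]
  ids <- if (is.null(asv_ids)) sort(unique(records$asv)) else asv_ids
  zs <- split(ok$z, factor(ok$asv, levels = ids))
  n_flag <- vapply(split(records$flag != "ok",
                         factor(records$asv, levels = ids)),
                   sum, numeric(1))
  summ <- function(z) {
    n <- length(z)
    c(total = if (n) sum(z) else 0,
      mean = if (n) mean(z) else NA_real_,
      median = if (n) stats::median(z) else NA_real_,
      n_pairs = n,
      mean_over_sd = if (n >= 2L && stats::sd(z) > 0) mean(z) / stats::sd(z)
                     else NA_real_)
  }
  m <- t(vapply(zs, summ, numeric(5)))
  out <- data.frame(asv = ids, m, n_flagged = as.integer(n_flag),
                    flag = ifelse(m[, "n_pairs"] == 0, "no_records", "ok"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("phyloscore_summary", "data.frame")
  out
}
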