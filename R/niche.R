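# Phylogenetic niche conservatism: per-ASV niche optima from environmental
# data, standardized euclidean niche distances, and a Mantel correlogram of
# niche distance against phylogenetic distance. A positive Mantel r in the
# short phylogenetic distance classes is the prerequisite for nearest-taxon
# null models (closely related taxa must occupy similar niches).

#' Per-ASV niche optima
#'
#' The niche optimum of an ASV for an environmental variable is its
#' abundance-weighted mean across the samples where it occurs:
#' \eqn{o_{iE} = \sum_s a_{is} E_s / \sum_s a_{is}} (or the abundance-weighted
#' median with `statistic = "median"`). ASVs with zero total abundance are
#' excluded.
#'
#' @param comm Community matrix (ASV x sample).
#' @param env data.frame or matrix of environmental variables, samples in rows
#'   (row names = sample ids), one numeric column per variable.
#' @param statistic `"mean"` (default) or `"median"` (abundance-weighted).
#' @return List of class `niche_profile` with `optima` (ASV x variable, native
#'   units) and `standardized` (z-scored per variable; zero-variance variables
#'   dropped with a warning).
#' @export
niche_optima <- function(comm, env, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  comm <- validate_community(comm)
  miss <- setdiff(colnames(comm), rownames(env))
  if (length(miss)) stop("samples without environmental data: ",
                         paste(miss, collapse = ", "))
  E <- as.matrix(env[colnames(comm), , drop = FALSE])
  storage.mode(E) <- "double"
  if (any(!is.finite(E))) stop("non-finite environmental values")
  tot <- rowSums(comm)
  keep <- tot > 0
  if (!any(keep)) stop("no ASV with positive abundance")
  m <- comm[keep, , drop = FALSE]
  if (statistic == "mean") {
    opt <- (m %*% E) / rowSums(m)
  } else {
    wmed <- function(x, w) {
      o <- order(x); x <- x[o]; w <- w[o] / sum(w)
      x[which(cumsum(w) >= 0.5)[1L]]
    }
    opt <- t(apply(m, 1L, function(w)
      apply(E, 2L, function(e) wmed(e, w))))
    dimnames(opt) <- list(rownames(m), colnames(E))
  }
  sds <- apply(opt, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance variables dropped: ",
            paste(colnames(opt)[sds == 0], collapse = ", "))
  }
  std <- scale(opt[, sds > 0, drop = FALSE])
  structure(list(optima = opt, standardized = std), class = "niche_profile")
}

#' Euclidean niche distance matrix
#'
#' Euclidean distance between ASVs on their z-scored niche optima;
#' standardization makes the distances invariant to affine transforms of the
#' input variables.
#'
#' @param profile A `niche_profile` from [niche_optima()].
#' @return Symmetric ASV x ASV distance matrix.
#' @export
niche_distance <- function(profile) {
  if (!inherits(profile, "niche_profile")) stop("not a niche_profile")
  as.matrix(stats::dist(profile$standardized))
}

#' Mantel correlogram of niche distance on phylogenetic distance
#'
#' Partitions the phylogenetic distances into classes (equal-width, Sturges'
#' rule on the pair count by default) and computes, per class, the Mantel
#' correlation between the class-membership indicator and the niche distances,
#' signed so that positive r means within-class niche similarity. Permutation
#' p-values (matrix row/column permutation of the niche distances, shared
#' across classes, one-tailed toward the observed sign) are progressively
#' Holm-corrected across classes. Classes in the upper half of the distance
#' range that exclude some taxa entirely are not tested (standard correlogram
#' cutoff), and classes with fewer than 20 pairs are flagged low-power.
#'
#' @param phylo_dist,niche_dist Symmetric distance matrices over the same ids.
#' @param n_classes Number of distance classes (default: Sturges' rule).
#' @param permutations Number of permutations.
#' @param break_pts Optional explicit class break points (overrides
#'   `n_classes`).
#' @param cutoff Apply the upper-half class cutoff?
#' @return data.frame of class `mantel_correlogram`: `class_index`,
#'   `midpoint`, `lo`, `hi`, `n_pairs`, `r`, `p`, `p_corrected`, `low_power`.
#' @export
mantel_correlogram <- function(phylo_dist, niche_dist, n_classes = NULL,
                               permutations = 999L, break_pts = NULL,
                               cutoff = TRUE) {
  ids <- rownames(phylo_dist)
  if (is.null(ids) || !all(ids %in% rownames(niche_dist))) {
    stop("distance matrices must share ids")
  }
  nd <- as.matrix(niche_dist)[ids, ids]
  pd <- as.matrix(phylo_dist)
  n <- nrow(pd)
  lower <- lower.tri(pd)
  pv <- pd[lower]
  n_pairs_tot <- length(pv)
  if (is.null(break_pts)) {
    if (is.null(n_classes)) n_classes <- ceiling(1 + log2(n_pairs_tot))
    break_pts <- seq(min(pv), max(pv), length.out = n_classes + 1L)
  }
  n_classes <- length(break_pts) - 1L
  eps <- .Machine$double.eps
  brk <- break_pts
  brk[1L] <- brk[1L] - eps
  cls <- findInterval(pv, brk, rightmost.closed = TRUE)
  half <- n_classes %/% 2
  # indicator matrix over pairs, one column per class; standardize columns
  B <- matrix(0, n_pairs_tot, n_classes)
  ok <- cls >= 1L & cls <= n_classes
  B[cbind(which(ok), cls[ok])] <- 1
  n_pairs <- colSums(B)
  testable <- n_pairs > 0
  if (cutoff) {
    # a class is untestable if beyond half range and some taxon has no pair
    row_of <- row(pd)[lower]; col_of <- col(pd)[lower]
    for (k in which(testable)) {
      if (k > half) {
        members <- c(row_of[cls == k], col_of[cls == k])
        if (length(setdiff(seq_len(n), members))) testable[k] <- FALSE
      }
    }
  }
  Bc <- scale(B[, testable, drop = FALSE])
  r_of <- function(v) {
    vs <- (v - mean(v)) / stats::sd(v)
    -as.numeric(crossprod(Bc, vs)) / (n_pairs_tot - 1)
  }
  r_obs <- r_of(nd[lower])
  ge <- rep(1L, length(r_obs)); le <- rep(1L, length(r_obs))
  for (p in seq_len(permutations)) {
    idx <- sample.int(n)
    vp <- nd[idx, idx][lower]
    rp <- r_of(vp)
    ge <- ge + (rp >= r_obs)
    le <- le + (rp <= r_obs)
  }
  p_raw <- ifelse(r_obs >= 0, ge, le) / (permutations + 1)
  p_all <- rep(NA_real_, n_classes)
  p_all[testable] <- p_raw
  # progressive Holm: class j corrected within the first j testable classes
  p_corr <- rep(NA_real_, n_classes)
  ti <- which(testable)
  for (j in seq_along(ti)) {
    p_corr[ti[j]] <- stats::p.adjust(p_raw[seq_len(j)], "holm")[j]
  }
  r_all <- rep(NA_real_, n_classes)
  r_all[testable] <- r_obs
  out <- data.frame(
    class_index = seq_len(n_classes),
    midpoint = (break_pts[-1L] + break_pts[-(n_classes + 1L)]) / 2,
    lo = break_pts[-(n_classes + 1L)], hi = break_pts[-1L],
    n_pairs = as.integer(n_pairs), r = r_all, p = p_all,
    p_corrected = p_corr, low_power = n_pairs < 20L)
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
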