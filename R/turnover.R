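# Community-level null models of the Stegen-style assembly framework:
# beta-MNTD / beta-NTI (phylogenetic turnover vs a tip-shuffling null) and
# Raup-Crick on Bray-Curtis (compositional turnover vs a random-assembly
# null), plus the per-pair assignment of the dominant assembly process.

.bmntd_parts <- function(a, b, comm, d, weighting) {
  pres <- comm > 0
  if (!any(pres[, a]) || !any(pres[, b])) stop("empty sample in pair (",
                                               a, ", ", b, ")")
  only_a <- which(pres[, a] & !pres[, b])
  only_b <- which(pres[, b] & !pres[, a])
  if (!length(only_a) && !length(only_b)) return(NULL)
  in_a <- which(pres[, a]); in_b <- which(pres[, b])
  da <- if (length(only_a))
    apply(d[only_a, in_b, drop = FALSE], 1L, min) else numeric(0)
  db <- if (length(only_b))
    apply(d[only_b, in_a, drop = FALSE], 1L, min) else numeric(0)
  if (weighting == "abundance") {
    w <- c(comm[only_a, a] / sum(comm[, a]), comm[only_b, b] / sum(comm[, b]))
  } else {
    w <- rep(1, length(da) + length(db))
  }
  list(vals = c(da, db), w = w / sum(w))
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For each ASV present in exactly one sample of the pair, takes its minimum
#' patristic distance to the ASVs present in the other sample, and returns the
#' weighted mean of those distances. Weights are the focal ASV's relative
#' abundance within its own sample, renormalized over the contributing ASVs
#' (`weighting = "presence"` gives the simple mean). Identical membership
#' yields 0 with attribute `identical_membership = TRUE`.
#'
#' @param a,b Sample ids.
#' @param comm Community matrix (ASV x sample).
#' @param d Patristic distance matrix over the ASVs.
#' @param weighting `"abundance"` or `"presence"`.
#' @return Non-negative scalar.
#' @export
bmntd <- function(a, b, comm, d, weighting = c("abundance", "presence")) {
  weighting <- match.arg(weighting)
  comm <- validate_community(comm)
  d <- d[rownames(comm), rownames(comm)]
  parts <- .bmntd_parts(a, b, comm, d, weighting)
  if (is.null(parts)) {
    out <- 0
    attr(out, "identical_membership") <- TRUE
    return(out)
  }
  sum(parts$vals * parts$w)
}

#' Beta nearest taxon index (beta-NTI)
#'
#' z-score of the observed beta-MNTD against a tip-shuffling null: each
#' replicate reassigns the presences and abundances of the compared
#' communities to random tips of the phylogeny, preserving the distribution
#' of phylogenetic distances. By default (`null_model = "independent"`) the
#' two communities are relabeled independently, so the null fully randomizes
#' membership -- including the overlap between the pair; identical
#' communities then score strongly negative, as they should. `"shared"`
#' applies one common relabeling to both communities (the classic single tip
#' shuffle), which preserves membership overlap and leaves identical
#' communities undefined (zero observed and zero null spread). Values below
#' -2 indicate significantly lower-than-random phylogenetic turnover
#' (homogeneous selection), above +2 higher (variable selection).
#'
#' @inheritParams bmntd
#' @param n_reps Number of null replicates (>= 2).
#' @param null_model `"independent"` (default) or `"shared"` tip shuffle.
#' @return z-score; `NA` (flagged via attribute `flag = "sd_zero"`) when the
#'   null has zero spread around a value different from the observation.
#' @export
bnti <- function(a, b, comm, d, n_reps = 999L,
                 weighting = c("abundance", "presence"),
                 null_model = c("independent", "shared")) {
  weighting <- match.arg(weighting)
  null_model <- match.arg(null_model)
  comm <- validate_community(comm)
  ids <- rownames(comm)
  d <- d[ids, ids]
  if (n_reps < 2L) stop("n_reps must be >= 2")
  obs <- bmntd(a, b, comm, d, weighting)
  S <- length(ids)
  cols <- sort(c(a, b))  # canonical draw order: pair-order invariance
  null <- vapply(seq_len(n_reps), function(r) {
    if (null_model == "shared") {
      idx <- sample.int(S)
      dp <- d[idx, idx]
      dimnames(dp) <- list(ids, ids)
      bmntd(a, b, comm, dp, weighting)
    } else {
      nc <- comm
      nc[, cols[1L]] <- comm[sample.int(S), cols[1L]]
      nc[, cols[2L]] <- comm[sample.int(S), cols[2L]]
      bmntd(a, b, nc, d, weighting)
    }
  }, numeric(1))
  s <- stats::sd(null)
  if (s == 0) {
    if (isTRUE(all.equal(obs, mean(null)))) return(0)
    out <- NA_real_
    attr(out, "flag") <- "sd_zero"
    return(out)
  }
  (obs - mean(null)) / s
}

#' Bray-Curtis dissimilarity between two samples
#'
#' Computed on within-sample relative abundances:
#' \eqn{1 - 2 \sum \min(x_i, y_i) / \sum (x_i + y_i)}.
#'
#' @inheritParams bmntd
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b, comm) {
  comm <- validate_community(comm)
  x <- comm[, a]; y <- comm[, b]
  if (sum(x) == 0 || sum(y) == 0) stop("all-zero sample in pair (",
                                       a, ", ", b, ")")
  x <- x / sum(x); y <- y / sum(y)
  1 - 2 * sum(pmin(x, y)) / sum(x + y)
}

# Raup-Crick score from an observed dissimilarity and its null draws, ties at
# half weight: an exactly null-typical pair scores 0, bounds are [-1, 1].
.rc_from_null <- function(obs, null, tol = 1e-10) {
  n <- length(null)
  2 * ((sum(null < obs - tol) + 0.5 * sum(abs(null - obs) <= tol)) / n) - 1
}

#' Raup-Crick index on Bray-Curtis dissimilarity (RC_Bray)
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair with a
#' null in which each sample is reassembled at its observed richness by
#' drawing taxa from the regional pool with probability proportional to their
#' occupancy, then filled to the observed total abundance by multinomial draws
#' proportional to regional relative abundance (dispersal "blind" to
#' phylogeny, weak selection). RC_Bray below -0.95 indicates less turnover
#' than expected (homogenizing dispersal), above +0.95 more (dispersal
#' limitation). Integer totals are used for the abundance fill; tables whose
#' column sums are below the richness (e.g. relative abundances) degrade to a
#' richness-only null.
#'
#' @inheritParams bmntd
#' @param n_reps Number of null replicates (>= 100 recommended).
#' @return Value in \[-1, 1\]; `NA` with attribute `flag = "degenerate_pool"`
#'   when the regional pool has fewer than 2 taxa.
#' @export
rc_bray <- function(a, b, comm, n_reps = 999L) {
  comm <- validate_community(comm)
  pres <- comm > 0
  occ <- rowSums(pres)
  pool <- which(occ > 0)
  if (length(pool) < 2L) {
    out <- NA_real_
    attr(out, "flag") <- "degenerate_pool"
    return(out)
  }
  reg <- rowSums(comm)[pool]
  reg <- reg / sum(reg)
  occ_p <- occ[pool]
  obs <- bray_curtis(a, b, comm)
  build <- function(N, total) {
    if (N > length(pool)) N <- length(pool)
    sel <- sample(seq_along(pool), N, prob = occ_p)
    x <- rep.int(1, N)
    fill <- total - N
    if (fill > 0) x <- x + stats::rmultinom(1L, fill, prob = reg[sel])[, 1L]
    list(idx = sel, x = x)
  }
  Na <- sum(pres[, a]); Nb <- sum(pres[, b])
  Ta <- max(Na, round(sum(comm[, a]))); Tb <- max(Nb, round(sum(comm[, b])))
  null <- vapply(seq_len(n_reps), function(r) {
    sa <- build(Na, Ta); sb <- build(Nb, Tb)
    xa <- numeric(length(pool)); xb <- numeric(length(pool))
    xa[sa$idx] <- sa$x / sum(sa$x)
    xb[sb$idx] <- sb$x / sum(sb$x)
    1 - 2 * sum(pmin(xa, xb)) / sum(xa + xb)
  }, numeric(1))
  .rc_from_null(obs, null)
}

#' Assembly-process call from beta-NTI and RC_Bray
#'
#' Strict threshold rules: `bnti < -2` homogeneous selection; `bnti > +2`
#' variable selection; otherwise `rc < -0.95` homogenizing dispersal,
#' `rc > +0.95` dispersal limitation, else undominated. Boundary values fall
#' through to the next stage; `NA` inputs give `"undefined"`.
#'
#' @param bnti beta-NTI z-score.
#' @param rc RC_Bray value (may be `NA` when `|bnti| > 2`).
#' @return Process label.
#' @export
assign_process <- function(bnti, rc = NA_real_) {
  if (is.na(bnti)) return("undefined")
  if (bnti < -2) return("homogeneous_selection")
  if (bnti > 2) return("variable_selection")
  if (is.na(rc)) return("undefined")
  if (rc < -0.95) return("homogenizing_dispersal")
  if (rc > 0.95) return("dispersal_limitation")
  "undominated"
}

#' Per-pair turnover statistics and dominant assembly processes
#'
#' Runs beta-MNTD, beta-NTI, Bray-Curtis and (where `|bnti| <= 2`) RC_Bray for
#' every unordered sample pair and assigns the dominant assembly process by
#' the strict threshold rules of [assign_process()]. Process fractions are
#' summarized overall and, when `groups` is given, separately for within- and
#' between-group pairs.
#'
#' @inheritParams bmntd
#' @param n_reps Null replicates for both beta-NTI and RC_Bray.
#' @param groups Optional named vector mapping samples to group labels.
#' @return data.frame of class `process_table` (one row per pair:
#'   `sample_a`, `sample_b`, `bmntd_obs`, `bnti`, `bray_curtis`, `rc_bray`,
#'   `stratum`, `process`) with attribute `summary` (process fractions).
#' @export
assign_processes <- function(comm, d, n_reps = 999L,
                             weighting = c("abundance", "presence"),
                             groups = NULL) {
  weighting <- match.arg(weighting)
  comm <- validate_community(comm)
  samples <- colnames(comm)
  if (length(samples) < 2L) stop("need >= 2 samples")
  prs <- utils::combn(samples, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(p) {
    a <- prs[1L, p]; b <- prs[2L, p]
    bm <- bmntd(a, b, comm, d, weighting)
    zn <- bnti(a, b, comm, d, n_reps, weighting)
    bc <- bray_curtis(a, b, comm)
    rc <- if (!is.na(zn) && abs(zn) <= 2) rc_bray(a, b, comm, n_reps)
          else NA_real_
    stratum <- if (is.null(groups)) NA_character_ else
      if (identical(groups[[a]], groups[[b]])) "within" else "between"
    data.frame(sample_a = a, sample_b = b, bmntd_obs = as.numeric(bm),
               bnti = as.numeric(zn), bray_curtis = bc,
               rc_bray = as.numeric(rc), stratum = stratum,
               process = assign_process(as.numeric(zn), as.numeric(rc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  frac <- function(x) {
    lv <- c("homogeneous_selection", "variable_selection",
            "homogenizing_dispersal", "dispersal_limitation", "undominated",
            "undefined")
    tab <- table(factor(x, levels = lv))
    as.data.frame(tab / max(1L, length(x)), responseName = "fraction")
  }
  summ <- list(overall = frac(out$process))
  if (!is.null(groups)) {
    summ$within <- frac(out$process[out$stratum == "within"])
    summ$between <- frac(out$process[out$stratum == "between"])
  }
  attr(out, "summary") <- summ
  class(out) <- c("process_table", "data.frame")
  out
}
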