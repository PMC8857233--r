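# Phylofactorization on per-ASV phyloscore summaries: sequentially cut the
# tree edge that maximizes the absolute two-sample t statistic (equal
# variance) contrasting the aggregated scores of the tips on the two sides of
# the edge within the bin the edge lives in. Each cut splits one bin in two;
# after f factors the tips are partitioned into f + 1 bins, each clade
# monophyletic within its bin.

#' Two-sample equal-variance t objective
#'
#' Pooled-variance two-sample t test used as the edge objective: the candidate
#' edge's clade scores against the complement scores within the same bin.
#'
#' @param x,y Numeric score vectors for the two sides (each of length >= 2).
#' @return Named vector `c(t_stat, p_value)`; zero pooled variance gives
#'   `t = 0, p = 1` for equal means and `t = +-Inf, p = 0` otherwise.
#' @export
edge_objective <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both sides need >= 2 scored tips")
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2L)
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (dm == 0) return(c(t_stat = 0, p_value = 1))
    return(c(t_stat = sign(dm) * Inf, p_value = 0))
  }
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  c(t_stat = t, p_value = 2 * stats::pt(-abs(t), df = nx + ny - 2L))
}

# t statistic and p from sufficient statistics of the two groups.
.t_from_stats <- function(nx, sx, sxx, ny, sy, syy) {
  vx <- sxx - sx^2 / nx
  vy <- syy - sy^2 / ny
  sp2 <- (vx + vy) / (nx + ny - 2)
  dm <- sx / nx - sy / ny
  if (sp2 <= 0) {
    if (abs(dm) < 1e-12) return(c(0, 1))
    return(c(sign(dm) * Inf, 0))
  }
  t <- dm / sqrt(sp2 * (1 / nx + 1 / ny))
  c(t, 2 * stats::pt(-abs(t), df = nx + ny - 2))
}

#' Consensus taxonomy of a tip set
#'
#' Walks the lineage ranks from domain downwards and keeps a rank as long as
#' at least `threshold` of the tips *classified at that rank* agree on one
#' name; ranks below the first disagreement are truncated.
#'
#' @param tips Character vector of ASV ids.
#' @param taxonomy Taxonomy matrix from [read_taxonomy()]/[parse_lineages()].
#' @param threshold Agreement fraction required among classified tips.
#' @return Lineage string with `d__`/`p__`/... prefixes, or `"Unclassified"`.
#' @export
consensus_taxonomy <- function(tips, taxonomy, threshold = 0.95) {
  tips <- intersect(tips, rownames(taxonomy))
  if (!length(tips)) return("Unclassified")
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  out <- character(0)
  for (r in seq_len(ncol(taxonomy))) {
    vals <- taxonomy[tips, r]
    vals <- vals[nzchar(vals)]
    if (!length(vals)) break
    tab <- sort(table(vals), decreasing = TRUE)
    if (tab[1L] / length(vals) < threshold) break
    out <- c(out, paste0(prefixes[r], names(tab)[1L]))
  }
  if (!length(out)) "Unclassified" else paste(out, collapse = ";")
}

#' Phylofactorization of aggregated phyloscores
#'
#' Iteratively cuts the tree edge that maximizes the absolute equal-variance
#' two-sample t statistic between the aggregated phyloscores of the tips on
#' either side of the edge (within the current bin). Stops when the
#' Bonferroni-adjusted p-value of the best edge (corrected by the number of
#' admissible edges tested that iteration) exceeds `alpha`, or after
#' `max_factors` cuts. Deterministic: objective ties are broken by the
#' smallest edge index.
#'
#' Clades whose mean score is below their complement's are labeled `HoS`
#' (homogeneous selection: members replaced by closer relatives than chance);
#' the converse is `HeS`.
#'
#' @param tree [ape::phylo] tree whose tips are the scored ASVs.
#' @param summaries Either the data.frame from [aggregate_phyloscores()] or a
#'   named numeric vector of per-tip scores.
#' @param metric Column of `summaries` to use (`"total"`, `"mean"`,
#'   `"median"`, `"n_pairs"`, `"mean_over_sd"`); ignored for vector input.
#' @param max_factors Hard cap on the number of factors.
#' @param alpha Significance level for the Bonferroni-adjusted stopping rule.
#' @param taxonomy Optional taxonomy matrix for consensus labels.
#' @param consensus_threshold Agreement threshold for [consensus_taxonomy()].
#' @return Object of class `phylofactorization`: list with `factors` (one row
#'   per cut: `index`, `edge`, `n_clade`, `n_complement`, `t_stat`, `p_value`,
#'   `p_bonferroni`, `direction`, `consensus_taxonomy`), `clades` (list of tip
#'   id vectors), `bins` (named bin id per scored tip), `scores`,
#'   `stop_reason`.
#' @export
phylofactorize <- function(tree, summaries, metric = "total",
                           max_factors = Inf, alpha = 0.05, taxonomy = NULL,
                           consensus_threshold = 0.95) {
  tree <- validate_tree(tree)
  if (is.data.frame(summaries)) {
    if (!metric %in% names(summaries)) stop("unknown metric: ", metric)
    scores_all <- stats::setNames(summaries[[metric]], summaries$asv)
  } else {
    scores_all <- summaries
  }
  scores_all <- scores_all[is.finite(scores_all)]
  tips <- tree$tip.label
  scored <- tips[tips %in% names(scores_all)]
  if (length(scored) < length(tips)) {
    warning(length(tips) - length(scored), " tips without scores dropped")
  }
  if (length(scored) < 4L) stop("need >= 4 scored tips")
  sc <- as.numeric(scores_all[scored])
  n <- length(scored)
  tip_idx <- match(scored, tips)                 # scored index -> tree tip no.
  scored_of_tip <- match(seq_along(tips), tip_idx)

  # per-edge scored-tip descendants (as indices into `scored`)
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  edge_tips <- lapply(desc, function(v) {
    s <- scored_of_tip[v]
    s[!is.na(s)]
  })
  n_edges <- nrow(tree$edge)

  bins <- rep.int(1L, n)
  bin_n <- n
  bin_sum <- sum(sc)
  bin_ssq <- sum(sc^2)
  cut <- logical(n_edges)
  factors <- list()
  clades <- list()
  stop_reason <- "max_factors"
  f <- 0L
  while (f < max_factors) {
    best <- NULL; best_obj <- -Inf; n_adm <- 0L
    for (e in seq_len(n_edges)) {
      if (cut[e]) next
      De <- edge_tips[[e]]
      if (length(De) < 2L) next
      b <- bins[De]
      tab <- tabulate(b, nbins = length(bin_n))
      cand <- which(tab > 0L & tab < bin_n)
      if (length(cand) != 1L) next
      nb <- tab[cand]
      if (nb < 2L || bin_n[cand] - nb < 2L) next
      inb <- De[b == cand]
      sx <- sum(sc[inb]); sxx <- sum(sc[inb]^2)
      tp <- .t_from_stats(nb, sx, sxx,
                          bin_n[cand] - nb, bin_sum[cand] - sx,
                          bin_ssq[cand] - sxx)
      n_adm <- n_adm + 1L
      obj <- abs(tp[1L])
      if (obj > best_obj) {
        best_obj <- obj
        best <- list(edge = e, bin = cand, clade = inb, t = tp[1L],
                     p = tp[2L], sx = sx, sxx = sxx, nb = nb)
      }
    }
    if (is.null(best)) {
      if (f == 0L) stop_reason <- "no_admissible_edge"
      else stop_reason <- "no_admissible_edge"
      break
    }
    p_bonf <- min(1, best$p * n_adm)
    if (p_bonf > alpha) {
      stop_reason <- "alpha"
      break
    }
    f <- f + 1L
    b0 <- best$bin
    mean_clade <- best$sx / best$nb
    mean_comp <- (bin_sum[b0] - best$sx) / (bin_n[b0] - best$nb)
    clade_ids <- scored[best$clade]
    factors[[f]] <- data.frame(
      index = f, edge = best$edge, n_clade = best$nb,
      n_complement = bin_n[b0] - best$nb,
      mean_clade = mean_clade, mean_complement = mean_comp,
      t_stat = best$t, p_value = best$p, p_bonferroni = p_bonf,
      n_edges_tested = n_adm,
      direction = if (mean_clade < mean_comp) "HoS" else "HeS",
      consensus_taxonomy = if (is.null(taxonomy)) NA_character_ else
        consensus_taxonomy(clade_ids, taxonomy, consensus_threshold),
      stringsAsFactors = FALSE)
    clades[[f]] <- clade_ids
    # split bin b0: clade tips move to new bin f + 1
    new_id <- length(bin_n) + 1L
    bins[best$clade] <- new_id
    bin_n <- c(bin_n, best$nb); bin_n[b0] <- bin_n[b0] - best$nb
    bin_sum <- c(bin_sum, best$sx); bin_sum[b0] <- bin_sum[b0] - best$sx
    bin_ssq <- c(bin_ssq, best$sxx); bin_ssq[b0] <- bin_ssq[b0] - best$sxx
    cut[best$edge] <- TRUE
  }
  res <- list(
    factors = if (f) do.call(rbind, factors) else data.frame(),
    clades = clades,
    bins = stats::setNames(bins, scored),
    scores = stats::setNames(sc, scored),
    alpha = alpha, metric = metric, stop_reason = stop_reason)
  class(res) <- "phylofactorization"
  res
}

#' @export
print.phylofactorization <- function(x, ...) {
  nf <- nrow(x$factors)
  cat("phylofactorization:", if (is.null(nf) || !nf) 0 else nf,
      "factor(s), stop reason:", x$stop_reason, "\n")
  if (!is.null(nf) && nf) {
    print(x$factors[, c("index", "n_clade", "t_stat", "p_bonferroni",
                        "direction", "consensus_taxonomy")])
  }
  invisible(x)
}

#' Per-clade report of a phylofactorization
#'
#' Expands each factor into a per-clade summary: size, direction
#' (HoS: clade scores distinctly below the complement; HeS: above), score
#' distribution and the test outcome.
#'
#' @param pf A `phylofactorization` object.
#' @return data.frame, one row per factor/clade.
#' @export
classify_clades <- function(pf) {
  if (!inherits(pf, "phylofactorization")) stop("not a phylofactorization")
  nf <- nrow(pf$factors)
  if (is.null(nf) || !nf) {
    return(data.frame(index = integer(0), n_tips = integer(0),
                      direction = character(0)))
  }
  rows <- lapply(seq_len(nf), function(i) {
    z <- pf$scores[pf$clades[[i]]]
    data.frame(index = i, n_tips = length(z),
               direction = pf$factors$direction[i],
               score_min = min(z), score_median = stats::median(z),
               score_mean = mean(z), score_max = max(z),
               t_stat = pf$factors$t_stat[i],
               p_bonferroni = pf$factors$p_bonferroni[i],
               consensus_taxonomy = pf$factors$consensus_taxonomy[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Jaccard index of two sets
#' @param a,b Character vectors.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard_index <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
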