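# Synthetic-data generators: random trees, community matrices with a planted
# HoS or HeS clade, Jukes-Cantor sequences evolved along the tree, and
# Brownian-motion niche traits. Every generator is reproducible from its
# parameters plus the RNG state; the returned `truth` list records both.

#' Random phylogenetic tree
#'
#' Uniform-attachment random topology (ape's `rtree`) with iid exponential
#' branch lengths (mean 0.05 substitutions/site by default, a realistic scale
#' for 16S amplicon trees). `model = "yule"` uses a Yule pure-birth topology
#' instead.
#'
#' @param n_tips Number of tips (>= 2).
#' @param branch_mean Mean branch length (exponential model).
#' @param model `"uniform"` (rtree-like) or `"yule"`.
#' @param branch_lengths `"exponential"` (iid, mean `branch_mean`) or
#'   `"uniform"` (iid U(0, 1), the `rtree` default).
#' @return An [ape::phylo] tree with tips `t1` ... `tn`.
#' @export
random_tree <- function(n_tips, branch_mean = 0.05,
                        model = c("uniform", "yule"),
                        branch_lengths = c("exponential", "uniform")) {
  model <- match.arg(model)
  branch_lengths <- match.arg(branch_lengths)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  br <- if (branch_lengths == "exponential") {
    function(n) stats::rexp(n, rate = 1 / branch_mean)
  } else {
    stats::runif
  }
  tree <- if (model == "uniform") {
    ape::rtree(n_tips, br = br)
  } else {
    t0 <- ape::rcoal(n_tips)
    t0$edge.length <- br(nrow(t0$edge))
    t0
  }
  validate_tree(tree)
}

#' Pick a monophyletic clade of approximately a given size
#'
#' @param tree A tree.
#' @param size Target number of tips.
#' @param max_frac Largest admissible clade, as a fraction of all tips --
#'   keeps a usable background outside the clade even when `size` is large.
#' @return Character vector of tip ids of the internal clade whose size is
#'   closest to `size` among admissible clades (ties: first in node order).
#' @export
pick_clade <- function(tree, size, max_frac = 0.75) {
  n <- length(tree$tip.label)
  nodes <- (n + 1L):(n + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  sizes <- lengths(desc)
  keep <- sizes <= max(2L, floor(max_frac * n))
  if (!any(keep)) keep <- sizes < n
  nodes <- nodes[keep]; sizes <- sizes[keep]
  best <- nodes[which.min(abs(sizes - size))]
  tree$tip.label[phangorn::Descendants(tree, best, type = "tips")[[1L]]]
}

#' Shrink the branches inside a clade
#'
#' Multiplies all branch lengths strictly below the clade's MRCA by `scale`,
#' producing the short-internal-branch structure of a microdiverse clade
#' (tight NTDs, high within-clade sequence identity) while leaving the rest of
#' the tree untouched.
#'
#' @param tree A tree.
#' @param tips Tip ids of a monophyletic clade.
#' @param scale Multiplier in (0, 1\].
#' @return The modified tree.
#' @export
compress_clade <- function(tree, tips, scale) {
  tree <- validate_tree(tree)
  mrca <- ape::getMRCA(tree, tips)
  below <- unlist(phangorn::Descendants(tree, mrca, type = "all"))
  sel <- tree$edge[, 2L] %in% below
  tree$edge.length[sel] <- tree$edge.length[sel] * scale
  tree
}

.lognormal_abund <- function(n, meanlog, sdlog) {
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Community matrix with a planted homogeneous-selection clade
#'
#' Emulates the occupancy signature of an HoS clade: the clade as a whole
#' occupies (at least one member present) a `clade_occupancy` fraction of
#' samples, while each individual member occupies only `per_asv_occupancy` of
#' samples -- so members are continually replaced by fellow clade members
#' across samples. Background taxa are present iid at `background_occupancy`.
#' Abundances are drawn per presence from a lognormal (the phyloscore itself
#' is abundance-blind; the abundance model only matters for the
#' community-level and Raup-Crick statistics).
#'
#' @param tree Source tree; all its tips become ASVs.
#' @param clade_tips Tip ids of the planted (monophyletic) clade.
#' @param n_samples Number of samples.
#' @param clade_occupancy Fraction of samples occupied by the clade as a
#'   whole.
#' @param per_asv_occupancy Target occupancy of each individual clade member
#'   (must satisfy `per_asv_occupancy * |clade| >= clade_occupancy` and
#'   `per_asv_occupancy <= clade_occupancy`).
#' @param background_occupancy Occupancy of background taxa.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @return List with `comm` (ASV x sample matrix) and `truth` (planted tips,
#'   direction, parameters, realized occupancies).
#' @export
plant_hos_clade <- function(tree, clade_tips, n_samples = 30L,
                            clade_occupancy = 1.0, per_asv_occupancy = 0.3,
                            background_occupancy = 0.1,
                            abundance_meanlog = 0, abundance_sdlog = 1) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  if (!all(clade_tips %in% tips)) stop("clade tips not in tree")
  nc <- length(clade_tips)
  if (per_asv_occupancy > clade_occupancy) {
    stop("per_asv_occupancy must not exceed clade_occupancy")
  }
  if (nc > 0L && per_asv_occupancy * nc < clade_occupancy) {
    stop("infeasible occupancies: per_asv_occupancy * |clade| = ",
         signif(per_asv_occupancy * nc, 3), " < clade_occupancy = ",
         clade_occupancy,
         " (need at least one expected member per occupied sample)")
  }
  samples <- sprintf("s%02d", seq_len(n_samples))
  pres <- matrix(FALSE, length(tips), n_samples,
                 dimnames = list(tips, samples))
  bg <- setdiff(tips, clade_tips)
  pres[bg, ] <- stats::runif(length(bg) * n_samples) < background_occupancy
  if (nc > 0L) {
    p_member <- per_asv_occupancy / clade_occupancy
    occupied <- stats::runif(n_samples) < clade_occupancy
    for (s in which(occupied)) {
      inc <- stats::runif(nc) < p_member
      if (!any(inc)) inc[sample.int(nc, 1L)] <- TRUE
      pres[clade_tips, s] <- inc
    }
  }
  comm <- matrix(0, length(tips), n_samples, dimnames = dimnames(pres))
  npres <- sum(pres)
  comm[pres] <- .lognormal_abund(npres, abundance_meanlog, abundance_sdlog)
  realized_clade <- if (nc) mean(colSums(pres[clade_tips, , drop = FALSE]) > 0)
                    else NA_real_
  realized_per_asv <- if (nc) mean(rowMeans(pres[clade_tips, , drop = FALSE]))
                      else NA_real_
  truth <- list(planted_clade_tips = clade_tips,
                planted_direction = if (nc) "HoS" else "none",
                n_samples = n_samples, clade_occupancy = clade_occupancy,
                per_asv_occupancy = per_asv_occupancy,
                background_occupancy = background_occupancy,
                realized_clade_occupancy = realized_clade,
                realized_per_asv_occupancy = realized_per_asv)
  list(comm = comm, truth = truth)
}

#' Community matrix with a planted heterogeneous-selection clade
#'
#' The clade is confined to the samples of one group (present there at
#' `within_occupancy`), absent everywhere else; background taxa are present
#' iid across all samples. Between-group replacement of clade members by
#' distant taxa yields higher-than-random phylogenetic turnover (positive
#' phyloscores).
#'
#' @param tree Source tree.
#' @param clade_tips Planted clade tip ids (may be empty: pure background).
#' @param sample_groups Character vector of group labels, one per sample.
#' @param target_group Group that hosts the clade (default: first level).
#' @param within_occupancy Clade member occupancy inside the target group.
#' @param background_occupancy Background occupancy.
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @return List with `comm` and `truth` (as [plant_hos_clade()]).
#' @export
plant_hes_clade <- function(tree, clade_tips, sample_groups,
                            target_group = NULL, within_occupancy = 0.7,
                            background_occupancy = 0.1,
                            abundance_meanlog = 0, abundance_sdlog = 1) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  if (!all(clade_tips %in% tips)) stop("clade tips not in tree")
  groups <- as.character(sample_groups)
  if (length(unique(groups)) < 2L) {
    warning("single sample group: degenerates to an occupancy-only planting")
  }
  if (is.null(target_group)) target_group <- groups[1L]
  n_samples <- length(groups)
  samples <- sprintf("s%02d", seq_len(n_samples))
  pres <- matrix(FALSE, length(tips), n_samples,
                 dimnames = list(tips, samples))
  bg <- setdiff(tips, clade_tips)
  pres[bg, ] <- stats::runif(length(bg) * n_samples) < background_occupancy
  in_grp <- which(groups == target_group)
  if (length(clade_tips)) {
    pres[clade_tips, in_grp] <-
      stats::runif(length(clade_tips) * length(in_grp)) < within_occupancy
  }
  comm <- matrix(0, length(tips), n_samples, dimnames = dimnames(pres))
  comm[pres] <- .lognormal_abund(sum(pres), abundance_meanlog,
                                 abundance_sdlog)
  truth <- list(planted_clade_tips = clade_tips,
                planted_direction = if (length(clade_tips)) "HeS" else "none",
                sample_groups = stats::setNames(groups, samples),
                target_group = target_group,
                within_occupancy = within_occupancy,
                background_occupancy = background_occupancy)
  list(comm = comm, truth = truth)
}

#' Evolve nucleotide sequences along a tree (Jukes-Cantor)
#'
#' Root sequence iid uniform over ACGT; substitutions accumulate along each
#' branch under JC69 with expected `branch length x rate_scale` substitutions
#' per site (via [phangorn::simSeq()]). The JC expected identity between two
#' tips at patristic distance d is \eqn{1 - 3/4 (1 - e^{-4d/3})}, the
#' closed-form anchor used in the package's tests.
#'
#' @param tree Source tree.
#' @param length Sequence length (>= 50 recommended).
#' @param rate_scale Multiplier on branch lengths.
#' @return Named character vector of uppercase sequences, one per tip.
#' @export
evolve_sequences <- function(tree, length = 300L, rate_scale = 1) {
  tree <- validate_tree(tree)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA", rate = rate_scale)
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Brownian-motion niche traits on a tree
#'
#' Independent Brownian traits evolved along the branches (variance
#' `sigma^2` per unit branch length), giving tip values whose similarity
#' decays with patristic distance -- the phylogenetically conserved niche
#' substrate for [mantel_correlogram()].
#'
#' @param tree Source tree.
#' @param sigma Brownian standard deviation per unit branch length.
#' @param n_traits Number of independent traits.
#' @return Matrix, tips x traits.
#' @export
bm_traits <- function(tree, sigma = 1, n_traits = 4L) {
  tree <- validate_tree(tree)
  if (sigma <= 0) stop("sigma must be > 0")
  out <- vapply(seq_len(n_traits), function(t)
    ape::rTraitCont(tree, model = "BM", sigma = sigma),
    numeric(length(tree$tip.label)))
  dimnames(out) <- list(tree$tip.label,
                        paste0("trait", seq_len(n_traits)))
  out
}

#' Sample environment table from tip traits
#'
#' Each sample's value of a variable is the abundance-weighted mean of the
#' traits of the taxa present in it, plus Gaussian measurement noise -- an
#' environment whose per-ASV niche optima correlate with the phylogeny.
#'
#' @param comm Community matrix.
#' @param traits Tip x trait matrix from [bm_traits()].
#' @param noise_sd Measurement noise standard deviation.
#' @return data.frame, samples in rows, one column per trait.
#' @export
sample_env_from_traits <- function(comm, traits, noise_sd = 0.1) {
  comm <- validate_community(comm)
  tr <- traits[rownames(comm), , drop = FALSE]
  w <- sweep(comm, 2L, pmax(colSums(comm), .Machine$double.eps), "/")
  env <- t(w) %*% tr +
    matrix(stats::rnorm(ncol(comm) * ncol(tr), sd = noise_sd),
           ncol(comm), ncol(tr))
  as.data.frame(env)
}
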