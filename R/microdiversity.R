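# Screening clades for putative microdiversity: nearest taxon distances,
# beta-nearest ASV nucleotide similarity with the >97% sub-taxon criterion,
# distribution contrasts against the background, per-clade rarefaction, and
# the depth-vs-NTD diagnostic for random-tree bias.

#' Nearest taxon distance per tip
#'
#' The shortest patristic distance between each tip and any other tip. Low
#' within-clade NTDs indicate fine-scale diversification; NTD depends only on
#' shortest paths, so clades of unequal phylogenetic depth remain comparable.
#'
#' @param tree An [ape::phylo] tree, or `NULL` if `d` is given.
#' @param d Optional precomputed patristic matrix.
#' @return Named numeric vector of per-tip NTDs.
#' @export
ntd <- function(tree = NULL, d = NULL) {
  if (is.null(d)) d <- patristic_matrix(tree)
  if (nrow(d) < 2L) stop("need >= 2 tips")
  dd <- d
  diag(dd) <- Inf
  apply(dd, 1L, min)
}

#' Alignment parameters for pairwise nucleotide identity
#'
#' @param match Match score.
#' @param mismatch Mismatch score (<= 0).
#' @param gap_open Gap opening penalty (<= 0).
#' @param gap_extend Gap extension penalty (<= 0).
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -2,
                             gap_extend = -0.5) {
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    stop("penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_params")
}

#' Global pairwise nucleotide identity
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' [Biostrings::pairwiseAlignment()]); identity = matching columns divided by
#' alignment columns excluding terminal gaps, times 100. End-gap-free identity
#' suits amplicons of unequal trimming. Input gaps (`-`) are stripped before
#' alignment; `N` scores as a mismatch.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param params An [alignment_params()] object.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- gsub("-", "", toupper(seq_a), fixed = TRUE)
  seq_b <- gsub("-", "", toupper(seq_b), fixed = TRUE)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (seq_a == seq_b) return(100)
  if (seq_a > seq_b) {  # canonical order: identity is symmetric even when
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp  # optimal alignments tie
  }
  bases <- c("A", "C", "G", "T", "N")
  sm <- matrix(params$mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(sm) <- params$match
  sm["N", ] <- params$mismatch; sm[, "N"] <- params$mismatch
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sm,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  both <- which(p != "-" & s != "-")
  lo <- min(both); hi <- max(both)
  cols <- seq(lo, hi)
  100 * sum(p[cols] == s[cols] & p[cols] != "-") / length(cols)
}

# Identity cache keyed on the unordered pair, shared across one analysis.
.identity_cache <- function() new.env(parent = emptyenv())

.cached_identity <- function(a, b, seqs, params, cache) {
  key <- paste(sort(c(a, b)), collapse = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- pairwise_identity(seqs[[a]], seqs[[b]], params)
  cache[[key]] <- val
  val
}

#' Beta-nearest ASV nucleotide similarity
#'
#' For each focal ASV and each sample where it is absent (but present
#' elsewhere), finds the phylogenetically nearest ASV present in that sample
#' (its beta-nearest ASV) and computes their nucleotide identity; ties in
#' nearest distance average the identity over the tied taxa. Similarities
#' above 97% mark spatial replacements among sub-taxa, the putative-ecotype
#' criterion. Presence/absence only; abundances never enter.
#'
#' @param comm Community matrix.
#' @param d Patristic distance matrix.
#' @param seqs Named character vector of ASV sequences.
#' @param params Alignment parameters.
#' @param tol Tie tolerance on nearest distances.
#' @return List with `per_asv` (data.frame `asv`, `median_similarity`,
#'   `n_samples`) and `replacements` (long data.frame `asv`, `sample`,
#'   `nearest`, `n_tied`, `similarity`). ASVs absent nowhere are excluded and
#'   listed in attribute `skipped_everywhere_present`.
#' @export
beta_nearest_similarity <- function(comm, d, seqs,
                                    params = alignment_params(),
                                    tol = 1e-12) {
  comm <- validate_community(comm)
  ids <- rownames(comm)
  miss <- setdiff(ids, names(seqs))
  if (length(miss)) stop("ASVs without sequences: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  d <- d[ids, ids]
  pres <- comm > 0
  cache <- .identity_cache()
  occ <- rowSums(pres)
  focal <- ids[occ > 0]
  skipped <- ids[occ == ncol(pres)]
  rows <- list(); pos <- 0L
  for (a in setdiff(focal, skipped)) {
    absent_in <- colnames(pres)[!pres[a, ] & colSums(pres) > 0]
    for (smp in absent_in) {
      present <- ids[pres[, smp]]
      dv <- d[a, present]
      mn <- min(dv)
      tied <- present[dv <= mn + tol]
      sim <- mean(vapply(tied, function(b)
        .cached_identity(a, b, seqs, params, cache), numeric(1)))
      pos <- pos + 1L
      rows[[pos]] <- data.frame(asv = a, sample = smp, nearest = tied[1L],
                                n_tied = length(tied), similarity = sim,
                                stringsAsFactors = FALSE)
    }
  }
  repl <- if (pos) do.call(rbind, rows) else
    data.frame(asv = character(0), sample = character(0),
               nearest = character(0), n_tied = integer(0),
               similarity = numeric(0))
  med <- vapply(split(repl$similarity, repl$asv), stats::median, numeric(1))
  per_asv <- data.frame(asv = names(med), median_similarity = as.numeric(med),
                        n_samples = as.integer(table(repl$asv)[names(med)]),
                        stringsAsFactors = FALSE, row.names = NULL)
  out <- list(per_asv = per_asv, replacements = repl)
  attr(out, "skipped_everywhere_present") <- skipped
  out
}

#' Microdiversity report for a clade against a background
#'
#' Contrasts a clade's nearest-taxon-distance distribution and beta-nearest
#' similarity distribution against a background tip set: two-sided Wilcoxon
#' rank-sum p-values for both metrics and the fraction of replacements with
#' identity strictly above 97% per group (computed on per-replacement values,
#' not per-ASV medians).
#'
#' @param clade_tips,background_tips Tip id vectors.
#' @param tree Tree (or pass `d`).
#' @param comm Community matrix.
#' @param seqs Named sequence vector.
#' @param d Optional precomputed patristic matrix.
#' @param beta Optional precomputed result of [beta_nearest_similarity()]
#'   (reused across clades).
#' @param params Alignment parameters.
#' @return List of class `clade_report`: per-group NTD and similarity values,
#'   `frac_over_97`, Wilcoxon p-values, flags.
#' @export
clade_microdiversity_report <- function(clade_tips, background_tips,
                                        tree = NULL, comm, seqs = NULL,
                                        d = NULL, beta = NULL,
                                        params = alignment_params()) {
  if (is.null(d)) d <- patristic_matrix(tree)
  if (!length(clade_tips) || !length(background_tips)) {
    stop("both tip sets must be non-empty")
  }
  nt <- ntd(d = d)
  ntd_clade <- nt[intersect(clade_tips, names(nt))]
  ntd_bg <- nt[intersect(background_tips, names(nt))]
  if (is.null(beta)) {
    if (is.null(seqs)) stop("provide seqs or a precomputed beta result")
    beta <- beta_nearest_similarity(comm, d, seqs, params)
  }
  repl <- beta$replacements
  sim_clade <- repl$similarity[repl$asv %in% clade_tips]
  sim_bg <- repl$similarity[repl$asv %in% background_tips]
  wtest <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  out <- list(
    n_tips = length(clade_tips),
    ntd_clade = ntd_clade, ntd_background = ntd_bg,
    similarity_clade = sim_clade, similarity_background = sim_bg,
    frac_over_97 = c(clade = mean(sim_clade > 97),
                     background = mean(sim_bg > 97)),
    p_ntd = wtest(ntd_clade, ntd_bg),
    p_similarity = wtest(sim_clade, sim_bg),
    underpowered = length(clade_tips) < 2L || length(background_tips) < 2L)
  class(out) <- "clade_report"
  out
}

#' @export
print.clade_report <- function(x, ...) {
  cat("clade microdiversity report (", x$n_tips, " tips)\n", sep = "")
  cat("  NTD median clade/background: ",
      signif(stats::median(x$ntd_clade), 4), " / ",
      signif(stats::median(x$ntd_background), 4),
      "  (Wilcoxon p = ", signif(x$p_ntd, 3), ")\n", sep = "")
  cat("  frac > 97% clade/background: ",
      signif(x$frac_over_97[["clade"]], 3), " / ",
      signif(x$frac_over_97[["background"]], 3),
      "  (Wilcoxon p = ", signif(x$p_similarity, 3), ")\n", sep = "")
  if (x$underpowered) cat("  [underpowered: a group has < 2 tips]\n")
  invisible(x)
}

#' Per-clade rarefaction of observed richness
#'
#' Subsamples the clade's pooled sequence counts without replacement at the
#' requested depths and reports the mean (+/- sd over replicates) number of
#' distinct clade ASVs observed -- the saturation check against
#' inadequate-sampling bias in the presence/absence matrix.
#'
#' @param comm Community count matrix.
#' @param clade_tips ASV ids of the clade.
#' @param depths Integer subsampling depths.
#' @param reps Replicates per depth.
#' @return data.frame `depth`, `mean_richness`, `sd_richness`.
#' @export
clade_rarefaction <- function(comm, clade_tips, depths, reps = 100L) {
  comm <- validate_community(comm)
  counts <- round(rowSums(comm[intersect(clade_tips, rownames(comm)), ,
                               drop = FALSE]))
  counts <- counts[counts > 0]
  if (!length(counts)) stop("clade has no sequence counts")
  N <- sum(counts)
  if (any(depths > N)) {
    warning("depths above the total count (", N, ") truncated")
    depths <- pmin(depths, N)
  }
  depths <- sort(unique(as.integer(depths)))
  bounds <- cumsum(counts)
  res <- lapply(depths, function(dp) {
    rich <- vapply(seq_len(reps), function(r) {
      picked <- sample.int(N, dp)
      length(unique(findInterval(picked - 1L, bounds) + 1L))
    }, numeric(1))
    data.frame(depth = dp, mean_richness = mean(rich),
               sd_richness = stats::sd(rich))
  })
  do.call(rbind, res)
}

#' Phylogenetic depth versus nearest taxon distance
#'
#' Tests whether NTD depends on distance from the root -- the bias diagnostic
#' for comparing clades of unequal phylogenetic depth. `level = "tip"`
#' correlates each tip's root distance with its NTD; `level = "clade"`
#' correlates each internal clade's root-to-MRCA distance with the median NTD
#' of its members (>= `min_tips` tips, root excluded). Real datasets
#' typically show no relationship at either level; on uniform-attachment
#' random trees the clade-level correlation has a weak negative tendency, in
#' which case NTD values may optionally be detrended (see `detrend`).
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param level `"tip"` or `"clade"`.
#' @param min_tips Minimum clade size at `level = "clade"`.
#' @param detrend If `TRUE`, also returns per-tip NTD values detrended by a
#'   linear fit of log NTD on root distance.
#' @return List: `rho`, `p`, `data` (per-unit depth and NTD), optionally
#'   `ntd_detrended`; zero variance gives `rho = NA` with
#'   `flag = "zero_variance"`.
#' @export
depth_vs_ntd <- function(tree, level = c("tip", "clade"), min_tips = 3L,
                         detrend = FALSE) {
  level <- match.arg(level)
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  node_depth <- ape::node.depth.edgelength(tree)
  nt <- ntd(tree)
  if (level == "tip") {
    depth <- node_depth[seq_len(n)]
    vals <- unname(nt)
    out <- list(data = data.frame(unit = tree$tip.label, depth = depth,
                                  ntd = vals, row.names = NULL))
  } else {
    nodes <- setdiff((n + 1L):(n + tree$Nnode), n + 1L)  # internal, not root
    desc <- phangorn::Descendants(tree, nodes, type = "tips")
    keep <- lengths(desc) >= min_tips
    nodes <- nodes[keep]
    depth <- node_depth[nodes]
    vals <- vapply(desc[keep], function(v) stats::median(nt[v]), numeric(1))
    out <- list(data = data.frame(unit = as.character(nodes), depth = depth,
                                  ntd = vals, row.names = NULL))
  }
  if (length(vals) < 3L || stats::sd(vals) == 0 || stats::sd(depth) == 0) {
    out$rho <- NA_real_; out$p <- NA_real_; out$flag <- "zero_variance"
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(depth, vals, method = "spearman"))
  out$rho <- unname(ct$estimate)
  out$p <- ct$p.value
  if (detrend) {
    tip_depth <- node_depth[seq_len(n)]
    fit <- stats::lm(log(nt) ~ tip_depth)
    out$ntd_detrended <- stats::setNames(exp(stats::residuals(fit) +
                                               mean(log(nt))),
                                         tree$tip.label)
  }
  out
}
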