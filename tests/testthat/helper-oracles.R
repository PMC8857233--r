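# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own computational paths.

worked_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

# Patristic distances by explicit path walking over the node graph (DFS from
# each tip), independent of cophenetic.phylo.
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nbr <- lapply(seq_len(n_node), function(i) list())
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    nbr[[a]] <- c(nbr[[a]], list(c(b, w)))
    nbr[[b]] <- c(nbr[[b]], list(c(a, w)))
  }
  out <- matrix(0, n_tip, n_tip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(n_tip)) {
    dist <- rep(NA_real_, n_node)
    dist[start] <- 0
    stack <- start
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      for (nb in nbr[[v]]) {
        if (is.na(dist[nb[1L]])) {
          dist[nb[1L]] <- dist[v] + nb[2L]
          stack <- c(stack, nb[1L])
        }
      }
    }
    out[start, ] <- dist[seq_len(n_tip)]
  }
  out
}

# beta-MNTD by an explicit double loop over taxa.
oracle_bmntd <- function(a, b, comm, d, weighting = "abundance") {
  pres <- comm > 0
  vals <- c(); w <- c()
  for (i in rownames(comm)) {
    in_a <- pres[i, a]; in_b <- pres[i, b]
    if (in_a == in_b) next
    own <- if (in_a) a else b
    other <- if (in_a) b else a
    best <- Inf
    for (j in rownames(comm)) if (pres[j, other] && j != i) {
      best <- min(best, d[i, j])
    }
    # nearest over taxa present in the other sample (i itself cannot be there)
    vals <- c(vals, best)
    w <- c(w, if (weighting == "abundance")
      comm[i, own] / sum(comm[, own]) else 1)
  }
  if (!length(vals)) return(0)
  sum(vals * (w / sum(w)))
}

# Optimal global affine-gap alignment score (Gotoh), Biostrings convention:
# a gap of length L costs gap_open + L * gap_extend (penalties positive here).
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                            gap_extend = 0.5) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Closed-form expected rarefied richness under hypergeometric subsampling.
oracle_expected_richness <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

# Small random presence/absence dataset on a random tree.
random_dataset <- function(n_tips, n_samples, occupancy = 0.4,
                           branch_mean = 0.05) {
  tree <- random_tree(n_tips, branch_mean = branch_mean)
  pres <- matrix(stats::runif(n_tips * n_samples) < occupancy, n_tips,
                 n_samples,
                 dimnames = list(tree$tip.label,
                                 sprintf("s%02d", seq_len(n_samples))))
  # ensure no empty sample / no absent-everywhere-or-present-everywhere taxon
  for (s in seq_len(n_samples)) {
    if (!any(pres[, s])) pres[sample.int(n_tips, 2L), s] <- TRUE
  }
  comm <- matrix(0, n_tips, n_samples, dimnames = dimnames(pres))
  comm[pres] <- stats::rlnorm(sum(pres))
  list(tree = tree, comm = comm, d = patristic_matrix(tree))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
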