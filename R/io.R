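#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the rest
#' of the package relies on: branch lengths must be present (all patristic
#' distances are substitution-scaled, so a tree without lengths is rejected
#' rather than defaulted), tip labels must be unique, and the tree must carry
#' at least two tips. Zero-length edges are legal (frequent in amplicon trees)
#' but counted and flagged, because downstream log-distance statistics must
#' apply a floor before taking logs.
#'
#' @param path Path to a Newick file. Quoted labels and multifurcations are
#'   supported; branch lengths are mandatory.
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::phylo] object with attribute `zero_length_edges` giving the
#'   number of zero-length edges found.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("Newick parse failure: empty input")
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse failure at character ", nchar(text) + 1L,
         ": missing terminating ';'")
  }
  depth <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0L)) {
    stop("Newick parse failure at character ", which(depth < 0L)[1L],
         ": unbalanced ')'")
  }
  if (depth[length(depth)] != 0L) {
    stop("Newick parse failure at character ", nchar(text),
         ": unbalanced '('")
  }
  if (!grepl(",", text, fixed = TRUE)) stop("tree must have >= 2 tips")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse failure: unreadable tree in ",
                          if (is.null(path)) "text" else path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_tree(tree)
}

#' Validate a phylo object against the package's tree contract
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly augmented with a `zero_length_edges` attribute.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances are undefined")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("tree has missing, non-finite or negative branch lengths")
  }
  nz <- sum(tree$edge.length == 0)
  attr(tree, "zero_length_edges") <- nz
  tree
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path. Patristic
#' distances are invariant under rerooting, so all downstream turnover
#' statistics are unchanged; rooting matters only for root-to-tip depths.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return The midpoint-rooted tree.
#' @export
midpoint_root <- function(tree) {
  tree <- validate_tree(tree)
  out <- phangorn::midpoint(tree)
  validate_tree(out)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of tips; the
#' substrate for all nearest-taxon statistics in the package.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return A symmetric numeric matrix ordered as `tree$tip.label`.
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Read an ASV x sample abundance table from TSV
#'
#' Expects ASVs as rows and samples as columns with a header row; `#` lines are
#' ignored. When a tree is supplied, a transposed table is auto-detected and
#' flipped only if its column names (and not its row names) match the tree
#' tips unambiguously.
#'
#' @param path Tab-delimited file; first column holds row identifiers.
#' @param tree Optional tree used for orientation detection.
#' @return Numeric matrix, ASVs in rows, samples in columns.
#' @export
read_community <- function(path, tree = NULL) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(tree)) {
    row_hits <- mean(rownames(m) %in% tree$tip.label)
    col_hits <- mean(colnames(m) %in% tree$tip.label)
    if (col_hits > 0.5 && row_hits <= 0.5) m <- t(m)
  }
  validate_community(m)
}

#' Validate a community abundance matrix
#' @param m Numeric matrix, ASVs in rows, samples in columns.
#' @return The validated matrix.
#' @export
validate_community <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("community matrix must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("community matrix needs ASV row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated ASV ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids")
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("community matrix has negative or non-finite entries")
  }
  m
}

#' Drop ASVs observed in fewer than a minimum number of samples
#'
#' Removes ASVs present (abundance > 0) in fewer than `min_samples` samples.
#' The default of 2 removes singleton observations, the guard against
#' sequencing-error false positives that would otherwise bias the
#' presence/absence matrix the phyloscores are computed from. Idempotent;
#' samples are never removed.
#'
#' @param m Community matrix (ASV x sample).
#' @param min_samples Minimum number of samples an ASV must occur in.
#' @return Filtered community matrix.
#' @export
filter_min_samples <- function(m, min_samples = 2L) {
  m <- validate_community(m)
  if (min_samples < 1L) stop("min_samples must be >= 1")
  keep <- rowSums(m > 0) >= min_samples
  if (!any(keep)) stop("all ASVs removed by the min-sample filter")
  m[keep, , drop = FALSE]
}

#' Convert relative abundances to absolute abundances
#'
#' Multiplies per-sample relative abundances by per-sample total cell counts
#' (e.g. cells per gram of sediment from flow cytometry). Count tables are
#' first closed to relative abundances, so column sums of the result equal the
#' cell counts.
#'
#' @param m Community matrix (counts or relative abundances).
#' @param cell_counts Named numeric vector, one positive count per sample.
#' @return Absolute-abundance matrix.
#' @export
to_absolute <- function(m, cell_counts) {
  m <- validate_community(m)
  missing <- setdiff(colnames(m), names(cell_counts))
  if (length(missing)) {
    stop("missing cell counts for samples: ", paste(missing, collapse = ", "))
  }
  cc <- cell_counts[colnames(m)]
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("cell counts must be positive for samples: ",
         paste(colnames(m)[!is.finite(cc) | cc <= 0], collapse = ", "))
  }
  tot <- colSums(m)
  if (any(tot == 0)) stop("empty samples: ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  out <- sweep(m, 2L, tot / cc, "/")
  dimnames(out) <- dimnames(m)
  out
}

#' Read ASV representative sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicated sequence ids")
  if (any(nchar(seqs) == 0L)) stop("empty sequences in ", path)
  seqs
}

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Read a rank-delimited taxonomy table
#'
#' Two tab-delimited columns: ASV id and a `;`-delimited lineage. Optional
#' `k__`/`p__`/... prefixes are stripped; missing ranks stay explicitly empty.
#'
#' @param path TSV file (`#` comments ignored). A header row is detected and
#'   skipped if its first field is not reused later as an id.
#' @return Character matrix, ASVs in rows, columns `domain` ... `species`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) > 1L && grepl("taxon|lineage|id|asv|feature",
                             tolower(df[1L, 1L]))) {
    df <- df[-1L, , drop = FALSE]
  }
  parse_lineages(stats::setNames(as.character(df[[2L]]), df[[1L]]))
}

#' Parse `;`-delimited lineage strings into a rank matrix
#' @param lineages Named character vector of lineage strings.
#' @return Character matrix with one row per id and columns `domain`...`species`.
#' @export
parse_lineages <- function(lineages) {
  if (anyDuplicated(names(lineages))) stop("duplicated taxonomy ids")
  out <- matrix("", nrow = length(lineages), ncol = length(.TAX_RANKS),
                dimnames = list(names(lineages), .TAX_RANKS))
  parts <- strsplit(lineages, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    n <- min(length(p), length(.TAX_RANKS))
    if (n > 0L) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}

#' Read a sample metadata / environment table
#' @param path TSV, samples in rows (first column = sample id).
#' @return data.frame with sample ids as row names.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, row.names = 1L, check.names = FALSE,
                    comment.char = "#")
}

#' Read per-sample cell counts
#' @param path Two-column TSV: sample id, cells per gram.
#' @return Named numeric vector.
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                          comment.char = "#")
  stats::setNames(as.numeric(df[[1L]]), rownames(df))
}

#' Cross-validate tree, community matrix, sequences and taxonomy
#'
#' Reports identifier congruence across the inputs (tips vs ASV ids vs sequence
#' ids vs taxonomy ids), zero-length branches and empty samples. In strict mode
#' any mismatch is an error; otherwise the report is returned for inspection
#' and the caller decides.
#'
#' @param tree [ape::phylo].
#' @param m Community matrix.
#' @param seqs Optional named sequence vector.
#' @param taxonomy Optional taxonomy matrix from [read_taxonomy()].
#' @param strict Raise an error on any mismatch?
#' @return A list of class `phyloscore_validation` with per-check id vectors
#'   and a logical `ok`.
#' @export
validate_dataset <- function(tree, m, seqs = NULL, taxonomy = NULL,
                             strict = FALSE) {
  tree <- validate_tree(tree)
  m <- validate_community(m)
  rep <- list(
    tips_without_abundance = setdiff(tree$tip.label, rownames(m)),
    asvs_not_in_tree = setdiff(rownames(m), tree$tip.label),
    asvs_without_sequence = if (is.null(seqs)) character(0) else
      setdiff(rownames(m), names(seqs)),
    asvs_without_taxonomy = if (is.null(taxonomy)) character(0) else
      setdiff(rownames(m), rownames(taxonomy)),
    empty_samples = colnames(m)[colSums(m) == 0],
    zero_length_edges = attr(tree, "zero_length_edges")
  )
  rep$ok <- !length(rep$tips_without_abundance) &&
    !length(rep$asvs_not_in_tree) && !length(rep$asvs_without_sequence) &&
    !length(rep$asvs_without_taxonomy) && !length(rep$empty_samples)
  class(rep) <- "phyloscore_validation"
  if (strict && !rep$ok) {
    bad <- unlist(rep[c("tips_without_abundance", "asvs_not_in_tree",
                        "asvs_without_sequence", "asvs_without_taxonomy",
                        "empty_samples")])
    stop("dataset ids are not congruent: ", paste(bad, collapse = ", "))
  }
  rep
}

#' @export
print.phyloscore_validation <- function(x, ...) {
  cat("phyloscore dataset validation:",
      if (x$ok) "congruent\n" else "MISMATCHES\n")
  for (f in c("tips_without_abundance", "asvs_not_in_tree",
              "asvs_without_sequence", "asvs_without_taxonomy",
              "empty_samples")) {
    if (length(x[[f]])) {
      cat("  ", f, ": ", paste(utils::head(x[[f]], 10L), collapse = ", "),
          if (length(x[[f]]) > 10L) " ..." else "", "\n", sep = "")
    }
  }
  cat("  zero-length edges:", x$zero_length_edges, "\n")
  invisible(x)
}
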