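# End-to-end orchestration: validate -> (optional) conservatism check ->
# community-level turnover -> phyloscores -> phylofactorization ->
# per-clade microdiversity reports. Every stochastic stage consumes a
# sub-seed derived deterministically from the master seed, so a full run is
# reproducible from (inputs, seed).

.stage_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 13L + offset) %% 2147483647)
}

.maybe_seed <- function(s) if (!is.null(s)) set.seed(s)

#' Run the full phyloscore analysis pipeline
#'
#' Executes, in order: dataset validation, the phylogenetic-conservatism
#' prerequisite check (Mantel correlogram of niche vs phylogenetic distance,
#' if `env` is given), community-level turnover with assembly-process
#' assignment, per-ASV phyloscores and their aggregation, phylofactorization
#' into HoS/HeS clades, and (if sequences are given) per-clade microdiversity
#' reports against the non-clade background. Stages that lack their inputs
#' are skipped and recorded in `skipped`.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param comm Community matrix (ASV x sample); ASVs must be tree tips.
#' @param seqs Optional named sequence vector (enables the similarity screen).
#' @param taxonomy Optional taxonomy matrix (enables consensus labels).
#' @param env Optional sample environment table (enables the conservatism
#'   check).
#' @param groups Optional named sample-to-group vector.
#' @param M Null draws per phyloscore record.
#' @param turnover_reps Null replicates for beta-NTI / RC_Bray.
#' @param run_turnover Run the community-level stage? (It is the most
#'   expensive stage on large datasets.)
#' @param alpha,max_factors,metric Phylofactorization controls.
#' @param pool,sampling Phyloscore null controls (see [all_phyloscores()]).
#' @param min_samples ASV prevalence filter applied before analysis.
#' @param seed Master seed; every stochastic stage uses a sub-seed derived
#'   from it.
#' @param out_dir Optional directory: stage tables are written as TSV plus a
#'   `manifest.json` with parameters and sub-seeds.
#' @param verbose Log stage progress to stderr.
#' @return List of class `phyloscore_pipeline` with elements `validation`,
#'   `conservatism`, `turnover`, `records`, `summaries`, `factors`,
#'   `microdiversity`, `skipped`, `params`.
#' @export
run_pipeline <- function(tree, comm, seqs = NULL, taxonomy = NULL,
                         env = NULL, groups = NULL, M = 100L,
                         turnover_reps = 999L, run_turnover = TRUE,
                         alpha = 0.05, max_factors = 20L, metric = "total",
                         pool = "regional", sampling = "stratified",
                         min_samples = 2L, seed = NULL, out_dir = NULL,
                         verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[phyloscore] ", ...)
  t_all <- proc.time()[["elapsed"]]
  skipped <- character(0)

  comm <- filter_min_samples(validate_community(comm), min_samples)
  keep <- intersect(tree$tip.label, rownames(comm))
  if (!length(keep)) stop("no shared ids between tree and community matrix")
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, keep)
  }
  comm <- comm[tree$tip.label, , drop = FALSE]
  validation <- validate_dataset(tree, comm, seqs, taxonomy, strict = FALSE)
  if (length(validation$asvs_without_sequence) && !is.null(seqs)) {
    stop("sequences missing for ASVs: ",
         paste(utils::head(validation$asvs_without_sequence, 5L),
               collapse = ", "))
  }
  d <- patristic_matrix(tree)
  log_msg(nrow(comm), " ASVs x ", ncol(comm), " samples")

  conservatism <- NULL
  if (!is.null(env)) {
    .maybe_seed(.stage_seed(seed, 1L))
    log_msg("conservatism check (Mantel correlogram)")
    prof <- niche_optima(comm, env)
    ids <- rownames(prof$standardized)
    conservatism <- mantel_correlogram(d[ids, ids], niche_distance(prof))
  } else skipped <- c(skipped, "conservatism")

  turnover <- NULL
  if (run_turnover) {
    .maybe_seed(.stage_seed(seed, 2L))
    log_msg("community-level turnover (", turnover_reps, " reps)")
    turnover <- assign_processes(comm, d, n_reps = turnover_reps,
                                 groups = groups)
  } else skipped <- c(skipped, "turnover")

  .maybe_seed(.stage_seed(seed, 3L))
  log_msg("phyloscores (M = ", M, ")")
  records <- all_phyloscores(comm, d, M = M, sampling = sampling,
                             pool = pool, groups = groups)
  summaries <- aggregate_phyloscores(records, asv_ids = rownames(comm))

  log_msg("phylofactorization")
  factors <- phylofactorize(tree, summaries, metric = metric,
                            max_factors = max_factors, alpha = alpha,
                            taxonomy = taxonomy)

  microdiversity <- NULL
  nf <- nrow(factors$factors)
  if (!is.null(seqs) && !is.null(nf) && nf > 0L) {
    log_msg("microdiversity reports for ", nf, " clade(s)")
    beta <- beta_nearest_similarity(comm, d, seqs)
    in_any <- unique(unlist(factors$clades))
    background <- setdiff(rownames(comm), in_any)
    microdiversity <- lapply(seq_len(nf), function(i)
      clade_microdiversity_report(factors$clades[[i]], background,
                                  comm = comm, d = d, beta = beta))
  } else if (is.null(seqs)) skipped <- c(skipped, "microdiversity")

  out <- list(validation = validation, conservatism = conservatism,
              turnover = turnover, records = records, summaries = summaries,
              factors = factors, microdiversity = microdiversity,
              skipped = skipped,
              params = list(M = M, turnover_reps = turnover_reps,
                            alpha = alpha, max_factors = max_factors,
                            metric = metric, pool = pool,
                            sampling = sampling, min_samples = min_samples,
                            seed = seed),
              elapsed = proc.time()[["elapsed"]] - t_all)
  class(out) <- "phyloscore_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' Write pipeline stage tables to a directory
#'
#' Writes `records.tsv`, `summaries.tsv`, `factors.tsv`, `bins.tsv`, and when
#' available `turnover.tsv` and `correlogram.tsv`, plus `manifest.json`
#' (parameters, sub-seeds and stage row counts) when the jsonlite package is
#' installed.
#'
#' @param x A `phyloscore_pipeline` object.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(x$records, "records.tsv")
  wt(x$summaries, "summaries.tsv")
  nf <- nrow(x$factors$factors)
  if (!is.null(nf) && nf > 0L) wt(x$factors$factors, "factors.tsv")
  wt(data.frame(asv = names(x$factors$bins), bin = x$factors$bins),
     "bins.tsv")
  if (!is.null(x$turnover)) wt(as.data.frame(x$turnover), "turnover.tsv")
  if (!is.null(x$conservatism)) wt(as.data.frame(x$conservatism),
                                   "correlogram.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- c(x$params,
                  list(n_records = nrow(x$records),
                       n_factors = if (is.null(nf)) 0L else nf,
                       skipped = x$skipped,
                       sub_seeds = if (!is.null(x$params$seed))
                         vapply(1:3, function(o)
                           .stage_seed(x$params$seed, o), integer(1))
                       else NULL))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(out_dir)
}

#' @export
print.phyloscore_pipeline <- function(x, ...) {
  cat("phyloscore pipeline run\n")
  cat("  records:", nrow(x$records), " ASVs:", nrow(x$summaries), "\n")
  nf <- nrow(x$factors$factors)
  cat("  factors:", if (is.null(nf)) 0L else nf, "\n")
  if (!is.null(x$turnover)) {
    s <- attr(x$turnover, "summary")$overall
    top <- s[which.max(s$fraction), ]
    cat("  dominant process:", as.character(top$Var1),
        sprintf("(%.1f%% of pairs)\n", 100 * top$fraction))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "),
                             "\n")
  invisible(x)
}
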