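## End-to-end orchestration: extract chains, cluster, align, superimpose,
## reduce redundancy, decompose, report. Stage failures are isolated per
## cluster; the run report lists them. The alternative entry point consumes
## a pre-computed alignment plus coordinate files and starts directly at the
## structure-extraction step.

#' Pipeline run configuration
#'
#' Defaults mirror the method's published settings: identity and coverage
#' thresholds 0.8, redundancy cut 0.1 Angstrom, Calpha fitting, mean
#' centering, at least 5 residues aligned to the reference.
#'
#' @param identity,coverage sequence clustering thresholds in (0, 1].
#' @param rms_cut redundancy RMSD threshold (Angstrom).
#' @param atoms `"ca"` or `"backbone"` superposition atoms.
#' @param centering `"mean"` or `"reference"`.
#' @param weighting apply per-position coverage weights?
#' @param monomer_only keep only chains from monomeric biological units?
#' @param min_aligned minimum positions aligned to the reference.
#' @param cluster_backend,align_backend see [cluster_sequences()] and
#'   [align_cluster()].
#' @param out_dir optional output directory for ensemble files.
#' @param format `"cif"` or `"pdb"` ensemble files.
#' @param seed RNG seed for downstream stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(identity = 0.8, coverage = 0.8, rms_cut = 0.1,
                       atoms = c("ca", "backbone"),
                       centering = c("mean", "reference"),
                       weighting = TRUE, monomer_only = FALSE,
                       min_aligned = 5L,
                       cluster_backend = "builtin",
                       align_backend = "auto",
                       out_dir = NULL, format = "cif", seed = 1L) {
  stopifnot_scalar_prob(identity, "identity")
  stopifnot_scalar_prob(coverage, "coverage")
  structure(list(identity = identity, coverage = coverage, rms_cut = rms_cut,
                 atoms = match.arg(atoms), centering = match.arg(centering),
                 weighting = weighting, monomer_only = monomer_only,
                 min_aligned = min_aligned,
                 cluster_backend = cluster_backend,
                 align_backend = align_backend,
                 out_dir = out_dir, format = format, seed = seed),
            class = "run_config")
}

collection_report_row <- function(name, ens, decomp, msa_stats, sp) {
  small <- ens$n <= 2L
  dims <- if (!is.null(decomp))
    vapply(c(50, 80, 85, 90, 95, 99), function(t) dimensionality(decomp, t), 0L)
  else rep(NA_integer_, 6L)
  M <- rmsd_matrix(ens)$values
  data.frame(
    cluster = name, n = ens$n, m = ens$m,
    reference = ens$member_ids[ens$reference_index],
    singleton_or_pair = small,
    msa_identity = msa_stats["identity"], msa_coverage = msa_stats["coverage"],
    score_rel = sp,
    d50 = dims[1], d80 = dims[2], d85 = dims[3],
    d90 = dims[4], d95 = dims[5], d99 = dims[6],
    top_mode_variance = if (!is.null(decomp))
      decomp$eigenvalues[1] / decomp$total_variance else NA_real_,
    top_mode_collectivity = if (!is.null(decomp))
      collectivity(decomp$modes[, 1], decomp$m) else NA_real_,
    max_rmsd = if (ens$n > 1L) max(M, na.rm = TRUE) else 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

build_one_collection <- function(records, msa, config) {
  ens <- build_ensemble(records, msa,
                        weighting = config$weighting,
                        centering = config$centering,
                        atoms = config$atoms,
                        min_aligned = config$min_aligned,
                        rms_cut = config$rms_cut)
  decomp <- if (ens$n >= 2L) motion_pca(ens) else NULL
  list(ensemble = ens, decomp = decomp)
}

#' Run the full pipeline on structure files
#'
#' Steps: extract chain sequences and backbone coordinates from every input
#' file; cluster the sequences at the configured identity/coverage levels;
#' align each cluster; build, superimpose and prune a conformational
#' ensemble per cluster; decompose each ensemble into linear motions.
#' A failing cluster is reported and skipped; the pipeline continues.
#'
#' @param paths character vector of structure files, or a directory
#'   containing `.cif`/`.pdb` files.
#' @param config a [run_config()].
#' @return A list with `collections` (per cluster: `ensemble`, `decomp`,
#'   `msa`), `report` (one data frame row per cluster), `counts` (per-stage
#'   chain counts), `failures`.
#' @export
run_full <- function(paths, config = run_config()) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(cif|pdb)$", full.names = TRUE)
  if (length(paths) == 0L) stop("no input structure files")
  records <- list()
  read_failures <- character(0)
  for (p in paths) {
    recs <- tryCatch(extract_chain_records(p, monomer_only = config$monomer_only),
                     error = function(e) {
                       read_failures <<- c(read_failures,
                                           sprintf("%s: %s", p, conditionMessage(e)))
                       list()
                     })
    records <- c(records, recs)
  }
  if (length(records) == 0L)
    return(list(collections = list(), report = NULL,
                counts = c(parsed = 0L), failures = read_failures))
  clusters <- cluster_sequences(records, identity = config$identity,
                                coverage = config$coverage,
                                backend = config$cluster_backend)
  ids <- vapply(records, function(r) r$id, "")
  names(records) <- ids
  collections <- list()
  report <- list()
  failures <- read_failures
  for (cl in clusters) {
    name <- cl$representative_id
    res <- tryCatch({
      msa <- align_cluster(records[cl$member_ids],
                           backend = config$align_backend)
      built <- build_one_collection(records[cl$member_ids], msa, config)
      ens <- built$ensemble
      msa_stats <- msa_identity_coverage(ens$msa)
      sp <- if (ens$n >= 2L) sum_of_pairs_score(ens$msa) else NA_real_
      if (!is.null(config$out_dir))
        write_ensemble_files(ens, config$out_dir, format = config$format,
                             name = gsub("[^A-Za-z0-9_]", "_", name))
      list(collection = list(ensemble = ens, decomp = built$decomp,
                             msa = ens$msa),
           row = collection_report_row(name, ens, built$decomp, msa_stats, sp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("cluster %s: %s", name,
                                      conditionMessage(res)))
    } else {
      collections[[name]] <- res$collection
      report[[name]] <- res$row
    }
  }
  list(collections = collections,
       report = if (length(report)) do.call(rbind, report) else NULL,
       counts = c(parsed = length(records),
                  clusters = length(clusters),
                  kept = sum(vapply(collections, function(x) x$ensemble$n, 0L)),
                  dropped_superposition = sum(vapply(collections, function(x)
                    length(x$ensemble$dropped), 0L)),
                  removed_redundant = sum(vapply(collections, function(x)
                    length(x$ensemble$removed_redundant %||% character(0)), 0L))),
       failures = failures)
}

#' Build one collection from a pre-computed alignment
#'
#' Bypasses sequence clustering and alignment: reads an MSA (FASTA; row
#' names must be `<structure>_<chain>` ids) and the corresponding coordinate
#' files, then superimposes, prunes and decomposes exactly as [run_full()]
#' does. Supports reference centering and uncertainty weighting, the
#' settings used when driving the pipeline from a structure-based alignment.
#'
#' @param msa_path FASTA alignment (reference-trimmed: no columns inserted
#'   relative to the intended reference).
#' @param coord_paths structure files (or a directory) covering every MSA
#'   row.
#' @param config a [run_config()].
#' @param reference_id optional row id to force as the reference.
#' @return A list with `ensemble`, `decomp`, `report` (single row).
#' @export
run_from_alignment <- function(msa_path, coord_paths, config = run_config(),
                               reference_id = NULL) {
  fa <- read_fasta(msa_path)
  msa <- postprocess_msa(protein_msa(fa$ids, fa$seqs))
  if (length(coord_paths) == 1L && dir.exists(coord_paths))
    coord_paths <- list.files(coord_paths, pattern = "\\.(cif|pdb)$",
                              full.names = TRUE)
  records <- list()
  for (p in coord_paths)
    records <- c(records, extract_chain_records(p,
                                                monomer_only = config$monomer_only))
  ids <- vapply(records, function(r) r$id, "")
  missing_rows <- setdiff(msa$ids, ids)
  if (length(missing_rows) > 0L)
    stop("MSA rows without coordinates: ", paste(missing_rows, collapse = ", "))
  ens <- build_ensemble(records, msa,
                        weighting = config$weighting,
                        centering = config$centering,
                        atoms = config$atoms,
                        min_aligned = config$min_aligned,
                        rms_cut = config$rms_cut,
                        reference_id = reference_id)
  decomp <- if (ens$n >= 2L) motion_pca(ens) else NULL
  msa_stats <- msa_identity_coverage(ens$msa)
  sp <- if (ens$n >= 2L) sum_of_pairs_score(ens$msa) else NA_real_
  if (!is.null(config$out_dir))
    write_ensemble_files(ens, config$out_dir, format = config$format)
  list(ensemble = ens, decomp = decomp,
       report = collection_report_row("from_alignment", ens, decomp,
                                      msa_stats, sp))
}
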