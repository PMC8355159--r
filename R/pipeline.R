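# End-to-end orchestration: ingest (or simulate) -> clone inference ->
# per-subset metrics -> cross-subset overlap, with a content-hash manifest so
# reruns are verifiable.

#' Pipeline run configuration
#'
#' @param airr_tsv Path to an AIRR Rearrangement TSV, or NULL to simulate.
#' @param germline_v,germline_j Paths to germline V/J FASTA files (required
#'   for SHM statistics on real input; the simulator provides its own).
#' @param simulate Set TRUE to generate input with the repertoire simulator.
#' @param sim_config A \code{\link{simConfig}} used when \code{simulate} is
#'   TRUE; its seed is overridden by \code{seed}.
#' @param threshold CDR3 amino-acid identity floor for clustering
#'   (default 0.85).
#' @param max_nt_dist Consensus collapse distance in nucleotides (default 2).
#' @param mutated_threshold_percent Mutation percent at or above which a
#'   clone counts as mutated (default 1).
#' @param top_n_vh Number of top VH genes in the usage matrix (default 20).
#' @param functional_only Restrict all analyses to functional rearrangements
#'   (default TRUE).
#' @param out_dir Output directory.
#' @param seed Seed for simulation (ignored for file input).
#' @param column_map Passed to \code{\link{readAirrTsv}}.
#' @return Config list of class \code{"run_config"}.
#' @export
runConfig <- function(airr_tsv = NULL, germline_v = NULL, germline_j = NULL,
                      simulate = is.null(airr_tsv), sim_config = simConfig(),
                      threshold = 0.85, max_nt_dist = 2,
                      mutated_threshold_percent = 1.0, top_n_vh = 20L,
                      functional_only = TRUE, out_dir = "igh_clonal_run",
                      seed = 1L, column_map = NULL) {
  if (!simulate && is.null(airr_tsv))
    stop("config error: either supply airr_tsv or set simulate = TRUE")
  structure(list(airr_tsv = airr_tsv, germline_v = germline_v,
                 germline_j = germline_j, simulate = simulate,
                 sim_config = sim_config, threshold = threshold,
                 max_nt_dist = max_nt_dist,
                 mutated_threshold_percent = mutated_threshold_percent,
                 top_n_vh = as.integer(top_n_vh),
                 functional_only = functional_only,
                 out_dir = out_dir, seed = as.integer(seed),
                 column_map = column_map),
            class = "run_config")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the clonal-landscape pipeline
#'
#' Executes ingest (or simulation), functional filtering, clone inference,
#' per-subset repertoire metrics and per-mouse cross-subset overlap, writing
#' every stage output as TSV/JSON into \code{config$out_dir} together with a
#' run log (parameters, seed, package version) and a manifest listing each
#' output file with its MD5 content hash. Reruns with an identical config
#' reproduce identical hashes.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisible list with \code{clone_set}, \code{germlines},
#'   \code{manifest} (data.frame file/md5) and \code{paths}.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  germlines <- NULL
  truth <- NULL
  if (config$simulate) {
    records <- stage("simulate", {
      sc <- config$sim_config
      sc$seed <- config$seed
      sim <- simulateRepertoire(sc)
      germlines <- sim$germlines
      truth <- sim$truth
      sim_paths <- writeSimulation(sim, file.path(config$out_dir, "input"))
      paths <- c(paths, sim_paths)
      sim$records
    })
  } else {
    records <- stage("ingest", {
      rec <- readAirrTsv(config$airr_tsv, column_map = config$column_map)
      if (!is.null(config$germline_v))
        germlines <- readGermlineFasta(config$germline_v, config$germline_j)
      rec
    })
    paths["skip_report"] <- .writeTsv(skipReport(records),
                                      file.path(config$out_dir,
                                                "skip_report.tsv"))
  }

  if (config$functional_only)
    records <- stage("functional_filter", filterFunctional(records))

  clone_set <- stage("clone_inference",
                     callClones(records, threshold = config$threshold,
                                max_nt_dist = config$max_nt_dist))
  cp <- file.path(config$out_dir, c("clones.tsv", "clone_assignments.tsv"))
  stage("clone_tables", writeCloneTables(clone_set, cp[1L], cp[2L]))
  paths[c("clones", "assignments")] <- cp

  stage("metrics", {
    paths["d20"] <- .writeTsv(d20BySample(clone_set),
                               file.path(config$out_dir, "d20_by_sample.tsv"))
    paths["replicate_jaccard"] <- .writeTsv(
      replicateOverlap(clone_set),
      file.path(config$out_dir, "replicate_jaccard.tsv"))
    paths["cdr3_lengths"] <- .writeTsv(
      cdr3LengthDistribution(clone_set),
      file.path(config$out_dir, "cdr3_lengths.tsv"))
    vh <- vhUsageMatrix(clone_set, top_n = config$top_n_vh)
    paths["vh_counts"] <- .writeTsv(
      data.frame(gene = rownames(vh$counts), vh$counts,
                 check.names = FALSE),
      file.path(config$out_dir, "vh_usage_counts.tsv"))
    paths["vh_normalized"] <- .writeTsv(
      data.frame(gene = rownames(vh$normalized), vh$normalized,
                 check.names = FALSE),
      file.path(config$out_dir, "vh_usage_normalized.tsv"))
    if (!is.null(germlines)) {
      paths["shm"] <- .writeTsv(
        shmByCloneSubset(clone_set, germlines),
        file.path(config$out_dir, "shm_by_clone_subset.tsv"))
      paths["profiles"] <- .writeTsv(
        subsetProfiles(clone_set, germlines,
                       config$mutated_threshold_percent),
        file.path(config$out_dir, "subset_profiles.tsv"))
    } else {
      paths["profiles"] <- .writeTsv(
        subsetProfiles(clone_set),
        file.path(config$out_dir, "subset_profiles.tsv"))
    }
  })

  stage("overlap", {
    for (m in unique(clones(clone_set)$mouse_id)) {
      pm <- presenceMatrix(clone_set, m)
      if (ncol(pm) < 2L) next
      ov <- subsetOverlap(clone_set, m)
      paths[paste0("jaccard_", m)] <- .writeTsv(
        data.frame(subset = rownames(jaccard(ov)), jaccard(ov),
                   check.names = FALSE),
        file.path(config$out_dir, sprintf("overlap_jaccard_%s.tsv", m)))
      paths[paste0("cosine_", m)] <- .writeTsv(
        data.frame(subset = rownames(cosine(ov)), cosine(ov),
                   check.names = FALSE),
        file.path(config$out_dir, sprintf("overlap_cosine_%s.tsv", m)))
      vp <- file.path(config$out_dir, sprintf("venn_%s.json", m))
      jsonlite::write_json(as.list(vennRegions(ov)), vp, auto_unbox = TRUE)
      paths[paste0("venn_", m)] <- vp
      tr <- presenceTracks(pm)
      paths[paste0("tracks_", m)] <- .writeTsv(
        data.frame(clone_id = rownames(tr$tracks), tr$tracks,
                   check.names = FALSE),
        file.path(config$out_dir, sprintf("presence_tracks_%s.tsv", m)))
    }
  })

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("IghClonal %s", as.character(utils::packageVersion("IghClonal"))),
    sprintf("seed: %d", config$seed),
    sprintf("identity threshold: %g", config$threshold),
    sprintf("collapse distance (nt): %g", config$max_nt_dist),
    sprintf("mutated threshold (%%): %g", config$mutated_threshold_percent),
    sprintf("functional only: %s", config$functional_only),
    sprintf("clones: %d", nClones(clone_set)),
    sprintf("records: %d", nrow(cloneRecords(clone_set)))
  ), log_path)
  paths["log"] <- log_path

  manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  .writeTsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(clone_set = clone_set, germlines = germlines, truth = truth,
                 manifest = manifest, paths = paths))
}
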