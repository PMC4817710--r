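#' Run the full decomposition pipeline on a FASTA file
#'
#' Reads a sample-tagged amplicon FASTA, pads reads to uniform length,
#' optionally subsamples per sample, decomposes the dataset, and writes
#' the standard output files into `output_dir`:
#' \itemize{
#'   \item `MATRIX-COUNT.txt`, `MATRIX-PERCENT.txt` — sample x node
#'     observation matrices (TSV);
#'   \item `NODE-REPRESENTATIVES.fasta` — representative sequence per
#'     final node;
#'   \item `TOPOLOGY.txt`, `TOPOLOGY.gml` — the decomposition tree as
#'     an edge list and as GML;
#'   \item `RUNINFO.txt` — key=value run log (omitted with
#'     `quick = TRUE`, which runs the raw decomposition and core
#'     outputs only).
#' }
#'
#' @param input path to the input FASTA file.
#' @param output_dir output directory (created if missing).
#' @param M minimum substantive abundance; the string `"auto"` (or
#'   `NULL`) resolves to [recommend_M()] of the input read count.
#' @param m0,c,normalize_m see [med_params()].
#' @param sample_pattern see [read_amplicon_fasta()].
#' @param subsample optional per-sample read cap (see
#'   [subsample_reads()]); `NULL` disables subsampling.
#' @param seed integer seed used for subsampling (required when
#'   `subsample` is set).
#' @param quick logical; skip the RUNINFO summary log and write only
#'   the decomposition outputs.
#' @param verbose print a run summary on completion.
#' @return The `med_topology`, invisibly.
#' @export
med_run <- function(input, output_dir, M = "auto", m0 = 0.0965, c = 4L,
                    normalize_m = TRUE,
                    sample_pattern = "^(.+)_\\d+$",
                    subsample = NULL, seed = NULL, quick = FALSE,
                    verbose = FALSE) {
  reads <- read_amplicon_fasta(input, sample_pattern)
  reads <- pad_reads(reads)
  if (!is.null(subsample)) {
    if (is.null(seed)) stop("subsampling requires a seed")
    reads <- subsample_reads(reads, subsample, seed)
  }
  if (identical(M, "auto")) M <- NULL
  params <- med_params(M = M, m0 = m0, c = c, normalize_m = normalize_m)
  topology <- med_decompose(reads, params)

  if (length(final_nodes(topology)) == 0L &&
      topology$nodes[[topology$root_id]]$status == "discarded") {
    stop("the entire dataset fails the minimum substantive abundance ",
         "criterion (M = ", topology$params$M,
         "): the most abundant unique sequence occurs only ",
         topology$nodes[[topology$root_id]]$top_unique_count, " time(s)")
  }

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  om <- observation_matrix(topology)
  write_observation_matrices(om, output_dir)
  write_representatives(topology,
                        file.path(output_dir, "NODE-REPRESENTATIVES.fasta"))
  export_topology(topology,
                  file.path(output_dir, "TOPOLOGY.txt"),
                  file.path(output_dir, "TOPOLOGY.gml"))
  if (!quick) {
    extra <- list(input = normalizePath(input),
                  sample_pattern = sample_pattern)
    if (!is.null(subsample)) {
      extra$subsample <- subsample
      extra$seed <- seed
    }
    write_runinfo(topology, file.path(output_dir, "RUNINFO.txt"),
                  extra = extra)
  }
  if (verbose) print(run_summary(topology))
  invisible(topology)
}
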