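# Pipeline driver: executes a declared sequence of stages against one
# shared seed and writes a manifest sufficient to re-run deterministic
# stages bit-identically.

#' Run a staged analysis pipeline
#'
#' Executes stages in declared order, passing in-memory results forward
#' (a `scan` stage uses the genome from a preceding `synth` stage unless
#' given a `genome_path`).  Every run writes a JSON manifest recording
#' the seed, package version, per-stage parameters and per-stage
#' summaries.
#'
#' Supported stages and their parameters:
#' \describe{
#'   \item{`synth`}{`length`, `planted`, `reference`, optional
#'     `gc_fraction`; writes `genome.fasta` and `truth.bed`.}
#'   \item{`scan`}{`reference`, `max_mismatch`, optional `genome_path`;
#'     writes `hits.bed`.}
#'   \item{`tally`}{`catalog_path` (TSV) or `records` (data.frame);
#'     writes `tally.tsv`.}
#'   \item{`compete`}{`ratio`, `death_fraction`; closed-form generations
#'     (raw and to two significant figures) into the manifest.}
#'   \item{`simulate`}{`death_fraction`, `generations`, optional `cap`,
#'     `n_replicates`; writes `simulation.tsv` (the checkpoint summary).}
#' }
#'
#' @param stages A list of stage specs, each a list with `stage` plus the
#'   stage's parameters.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed echoed into the manifest and used by every
#'   stochastic stage.
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(stages, out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  manifest <- list(seed = seed,
                   package_version =
                     as.character(utils::packageVersion("iceatt")),
                   stages = list())
  for (k in seq_along(stages)) {
    spec <- stages[[k]]
    stage <- spec$stage
    if (is.null(stage)) {
      stop("stage ", k, " has no 'stage' field")
    }
    summary <- tryCatch(
      switch(stage,
        synth = {
          g <- make_genome(length = spec$length, planted = spec$planted,
                           reference = spec$reference,
                           gc_fraction = spec$gc_fraction %||% 0.435,
                           seed = seed)
          write_fasta(g$genome, file.path(out_dir, "genome.fasta"))
          write_bed(g$truth, file.path(out_dir, "truth.bed"))
          state$genome <- g$genome
          state$truth <- g$truth
          list(n_planted = nrow(g$truth),
               genome_length = sum(Biostrings::width(g$genome)))
        },
        scan = {
          genome <- if (!is.null(spec$genome_path)) {
            read_fasta(spec$genome_path)
          } else if (!is.null(state$genome)) {
            state$genome
          } else {
            stop("no genome available: give genome_path or run synth first")
          }
          hits <- scan_genome(genome, spec$reference, spec$max_mismatch)
          write_bed(hits, file.path(out_dir, "hits.bed"))
          state$hits <- hits
          list(n_hits = nrow(hits),
               max_mismatch = spec$max_mismatch)
        },
        tally = {
          records <- if (!is.null(spec$catalog_path)) {
            read_catalog(spec$catalog_path)
          } else {
            spec$records
          }
          tal <- tally_sites(records)
          write_catalog(tal$sites, file.path(out_dir, "tally.tsv"))
          list(n_sites = tal$n_sites,
               total_insertions = tal$total_insertions,
               modal_locus = tal$modal_site$locus,
               modal_percent = tal$modal_site$percent)
        },
        compete = {
          g <- generations_to_ratio(spec$ratio, spec$death_fraction)
          list(ratio = spec$ratio,
               death_fraction = spec$death_fraction,
               generations = g,
               generations_2sf = signif(g, 2))
        },
        simulate = {
          sim <- simulate_competition(
            death_fraction = spec$death_fraction,
            generations = spec$generations,
            cap = spec$cap %||% 1e6,
            n_replicates = spec$n_replicates %||% 50,
            seed = seed)
          s <- summary(sim)
          utils::write.table(s, file.path(out_dir, "simulation.tsv"),
                             sep = "\t", quote = FALSE,
                             row.names = FALSE)
          last <- s[nrow(s), ]
          list(final_mean_ratio = last$mean_ratio,
               final_se = last$se,
               expected_ratio = last$expected_ratio)
        },
        stop("unknown stage: ", stage)
      ),
      error = function(e) {
        stop("stage '", stage, "' (position ", k, ") failed: ",
             conditionMessage(e), call. = FALSE)
      }
    )
    manifest$stages[[k]] <- list(stage = stage, summary = summary)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
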