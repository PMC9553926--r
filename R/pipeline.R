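#' Read and validate a pipeline configuration
#'
#' YAML with the input paths and the condition block. Defaults mirror the
#' standard experiment: protection window 10..46, RNase A, edit position
#' 32, negative ions, 0.3 Da tolerance, 50% 18O water.
#'
#' @param path YAML file, or a list already in memory.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(window = c(10L, 46L), enzyme = "RNaseA",
                   position = 32L, ion = "[M-H]-", tolerance = 0.3,
                   normalizer = "m5U", seed = 1L,
                   edit_fraction = 0, ce_efficiency = 1, o18_fraction = 0.5,
                   edit_state = "Y", out_dir = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$window <- as.integer(cfg$window)
  if (length(cfg$window) != 2L || cfg$window[1] > cfg$window[2])
    stop("config: window must be two increasing integers")
  if (!cfg$enzyme %in% c("RNaseA", "RNaseT1"))
    stop("config: unknown enzyme '", cfg$enzyme, "'")
  if (cfg$tolerance <= 0) stop("config: tolerance must be positive")
  for (k in c("edit_fraction", "ce_efficiency", "o18_fraction"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop("config: ", k, " outside [0,1]")
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[pseudomap] %-10s %s", stage, paste0(...)))
}

require_file <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

#' Run the MALDI editing-state pipeline
#'
#' Oligo protection, in-silico RNase digestion, theoretical species of the
#' diagnostic fragment under the cyanoethylation/18O chemistry, peak
#' matching, and editing-state inference — the full readout chain from a
#' modified-sequence description plus an observed peak list to an
#' [infer_editing_state()] call. When `out_dir` is set, writes
#' `assignments.tsv`, `call.json` and `run_log.txt`.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) with
#'   `fasta`, `mods` (optional) and `peaks` paths, or those objects passed
#'   directly via `seq` and `peaks`.
#' @param seq Optional [mod_rna_seq()] (bypasses `fasta`/`mods`).
#' @param peaks Optional [peak_list()] (bypasses the `peaks` path).
#' @return The `editing_call`, invisibly alongside written reports.
#' @export
run_maldi_pipeline <- function(config, seq = NULL, peaks = NULL) {
  config <- read_pipeline_config(config)
  if (is.null(seq)) {
    require_file(config$fasta, "FASTA")
    seq <- read_modified_sequence(config$fasta, config$mods)
  }
  if (is.null(peaks)) {
    require_file(config$peaks, "peak list")
    peaks <- read_peak_list(config$peaks)
  }
  pipeline_log("input", seq$id, ": ", length(seq), " residues, ",
               nrow(peaks), " peaks")
  prot <- protect_window(seq, config$window[1], config$window[2])
  pipeline_log("protect", "window ", config$window[1], "..",
               config$window[2], " -> ", length(prot), " residues")
  theo <- diagnostic_species(prot, config$position, enzyme = config$enzyme,
                             ion = config$ion)
  assignments <- match_peaks(theo, peaks, config$tolerance)
  pipeline_log("match", nrow(assignments), "/", nrow(theo),
               " diagnostic species matched (",
               nrow(peaks) - nrow(assignments), " peaks unassigned)")
  call <- infer_editing_state(assignments, config$position)
  pipeline_log("call", "state ", call$state, ", fraction ",
               sprintf("%.3f", call$fraction))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(assignments,
                       file.path(config$out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(position = call$position, state = call$state,
           fraction = call$fraction),
      file.path(config$out_dir, "call.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(
      paste0("pseudomap ", as.character(utils::packageVersion("pseudomap"))),
      paste0("seed: ", config$seed),
      paste0("window: ", config$window[1], "..", config$window[2]),
      paste0("enzyme: ", config$enzyme),
      paste0("position: ", config$position),
      paste0("ion: ", config$ion),
      paste0("tolerance_da: ", config$tolerance)),
      file.path(config$out_dir, "run_log.txt"))
  }
  invisible(call)
}

#' Run the nucleoside MRM quantification pipeline
#'
#' Reads a signal table, normalizes every channel to the reference
#' nucleoside (m5U by default) and, when `out_dir` is set, writes the
#' normalized table.
#'
#' @param config A `pipeline_config` with a `signals` path, or a signal
#'   table passed via `signal_table`.
#' @param signal_table Optional in-memory signal table.
#' @return The normalized [quantify()] table.
#' @export
run_mrm_pipeline <- function(config, signal_table = NULL) {
  config <- read_pipeline_config(config)
  if (is.null(signal_table)) {
    require_file(config$signals, "signal table")
    signal_table <- read_signal_table(config$signals)
  }
  out <- quantify(signal_table, normalizer = config$normalizer)
  pipeline_log("quantify", nrow(out), " channels normalized to ",
               config$normalizer)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(config$out_dir, "quant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
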