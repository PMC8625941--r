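#' Pipeline configuration
#'
#' Defaults are the published operating point of the analysis: log2 fold
#' change cutoff 1, BH-adjusted p <= 0.05, assignment windows of +/-5 nt
#' (+/-10 nt for terminators) and trend threshold +/-0.65.
#'
#' @param seed Master seed for the synthetic inputs.
#' @param outdir Output directory for stage tables and the manifest.
#' @param enzymes Enzyme comparisons to run (each needs a cognate mutant
#'   strain in the simulation).
#' @param sim Named list of [sim_config()] overrides.
#' @param diff Named list of [diff_end_params()] overrides.
#' @param window_default,window_terminator Assignment windows (nt).
#' @param trend_threshold Trend classification threshold.
#' @param gate_ends End-type gating flag, see [assign_end_mechanisms()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "srnaends-run",
                            enzymes = c("RNaseE", "RNaseIII", "PNPase"),
                            sim = list(), diff = list(),
                            window_default = 5, window_terminator = 10,
                            trend_threshold = 0.65, gate_ends = TRUE) {
  structure(list(seed = as.integer(seed), outdir = outdir, enzymes = enzymes,
                 sim = sim, diff = diff, window_default = window_default,
                 window_terminator = window_terminator,
                 trend_threshold = trend_threshold, gate_ends = gate_ends),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   `write_pipeline_config()` returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv_commented <- function(df, path, comments) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE))
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: simulate annotation and strain tracks; call differential ends per
#' enzyme comparison (wild type vs cognate mutant); classify sRNA origins;
#' assign end-generation mechanisms from TSS, terminators and the called
#' differential ends; quantify a simulated densitometry table. Every stage
#' writes a TSV under `outdir` and the run ends with a JSON manifest listing
#' the parameters actually used and the MD5 checksum of every output. A
#' failing stage aborts with a stage-labeled error and leaves a `FAILED`
#' marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest path.
#' @export
run_full <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(config$outdir, "FAILED")
  unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed_marker)
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
  }
  outputs <- character()
  put <- function(df, file, comments) {
    path <- file.path(config$outdir, file)
    write_tsv_commented(df, path, comments)
    outputs <<- c(outputs, path)
    path
  }

  scfg <- stage("configure", do.call(sim_config, modifyList(
    list(seed = config$seed), config$sim)))
  dparams <- stage("configure", do.call(diff_end_params, config$diff))

  ann <- stage("simulate", simulate_annotation(scfg))
  put(ann$srnas, "srnas.tsv",
      "simulated sRNAs; coordinates 0-based half-open; end5/end3 single nt")
  wt <- stage("simulate", simulate_end_tracks(ann, "WT", scfg))

  diff_all <- stage("call-ends", {
    bind_rows(lapply(config$enzymes, function(enz) {
      strain <- names(strain_enzyme)[match(enz, strain_enzyme)]
      if (is.na(strain)) {
        abort(paste0("no mutant tracks available for enzyme '", enz, "'"))
      }
      mut <- simulate_end_tracks(ann, strain, scfg)
      call_differential_ends(wt, mut, enz, dparams)
    }))
  })
  put(diff_all, "differential_ends.tsv",
      c("differential RNA 5'/3' ends, wild type vs enzyme mutants",
        sprintf("lfc_cutoff=%g alpha=%g min_count=%d pseudocount=%g stat=%s",
                dparams$lfc_cutoff, dparams$alpha, dparams$min_count,
                dparams$pseudocount, dparams$stat),
        "log2fc is wild type over mutant (CPM scale); positions 0-based"))

  origins <- stage("classify-origin", {
    tibble(srna_id = ann$srnas$srna_id,
           origin = classify_origin(ann$srnas, ann$utrs, ann$genes))
  })
  put(origins, "origins.tsv", "per-sRNA genomic origin class")
  put(summarize_origins(origins$origin), "origin_summary.tsv",
      "origin class counts and fractions")

  calls <- stage("assign-mechanisms", {
    feats <- bind_rows(ann$tss, ann$terminators,
                       diff_ends_to_features(diff_all))
    assign_end_mechanisms(ann$srnas, feats,
                          window_default = config$window_default,
                          window_terminator = config$window_terminator,
                          gate_ends = config$gate_ends)
  })
  put(calls, "mechanism_calls.tsv",
      sprintf("per-end mechanism calls; windows +/-%g nt (terminator +/-%g nt)",
              config$window_default, config$window_terminator))
  put(summarize_mechanisms(calls, origins), "mechanism_summary.tsv",
      "mechanism incidence by origin class and end")

  quant <- stage("quantify", {
    probes <- head(ann$srnas$srna_id, 4)
    tab <- simulate_signal_table(
      true_lfcs = setNames(c(1.5, -1.2, 0.2, 0), probes),
      true_ratios = setNames(c(2, 4, 1, 8), probes),
      noise_cv = 0.1, n_replicates = scfg$n_replicates, seed = config$seed)
    fc <- probe_fold_changes(tab$signals, tab$truth$reference_condition,
                             threshold = config$trend_threshold)
    list(signals = tab$signals, fold_changes = fc,
         ratios = ratio_table(tab$signals))
  })
  put(quant$fold_changes, "signal_trends.tsv",
      sprintf("mature-species log2 fold changes vs reference; trend threshold +/-%g",
              config$trend_threshold))
  put(quant$ratios, "mature_precursor_ratios.tsv",
      "per-replicate mature/precursor signal ratios")

  manifest <- list(
    package = "srnaends",
    version = as.character(utils::packageVersion("srnaends")),
    seed = config$seed,
    parameters = list(
      diff = unclass(dparams),
      window_default = config$window_default,
      window_terminator = config$window_terminator,
      trend_threshold = config$trend_threshold,
      gate_ends = config$gate_ends,
      sim = unclass(scfg)),
    stages = c("simulate", "call-ends", "classify-origin",
               "assign-mechanisms", "quantify"),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(f) list(md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(annotation = ann, differential_ends = diff_all,
                 origins = origins, mechanism_calls = calls,
                 quantification = quant, manifest = manifest_path,
                 outputs = outputs))
}
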