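# Run orchestration: reproducible result-file generation for the base case
# and the full analysis suite, with a manifest per output directory.

.vte_write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(out_dir, command, config, seed, n_psa) {
  lines <- c(
    paste0("command: ", command),
    paste0("config: ", if (is.character(config)) config else "<in-memory parameter set>"),
    paste0("seed: ", seed),
    paste0("n_psa: ", n_psa),
    paste0("package: vtecea ",
           as.character(utils::packageVersion("vtecea"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

.resolve_config <- function(config) {
  if (is.character(config)) load_parameters(config) else {
    validate_parameters(config)
    config
  }
}

# Base-case computation and file output, without a manifest (so that
# run_full_analysis can produce exactly one manifest per directory).
.run_base_case_core <- function(params, out_dir) {
  strategies <- all_strategies(params)
  results <- lapply(strategies, function(s) build_and_rollback(params, s))
  tab <- incremental_table(results)
  pathways <- do.call(rbind, lapply(results, function(r) r$pathways))
  .vte_write_csv(as.data.frame(tab), file.path(out_dir, "base_case_results.csv"))
  .vte_write_csv(pathways, file.path(out_dir, "pathways.csv"))
  # debug log: every resolved probability, for diagnosing discrepancies
  log_lines <- unlist(lapply(strategies, function(pr) {
    c(sprintf("strategy %s (%s):", pr$strategy$name, pr$strategy$phase),
      sprintf("  p_hypo = %s", .fmt_num(pr$p_hypo)),
      sprintf("  p_dvt = %s", .fmt_num(pr$p_dvt)),
      sprintf("  p_pe_given_dvt = %s", .fmt_num(pr$p_pe_given_dvt)),
      sprintf("  p_minor = %s", .fmt_num(pr$p_minor)),
      sprintf("  p_major = %s", .fmt_num(pr$p_major)),
      sprintf("  c_prophylaxis = %s", .fmt_num(pr$c_prophylaxis)))
  }))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  list(results = results, table = tab)
}

#' Run the deterministic base case and write result files
#'
#' Computes the base-case rollback for the three strategies and writes the
#' incremental results table (`base_case_results.csv`), the enumerated
#' pathway table (`pathways.csv`), a log of every resolved probability
#' (`run.log`), and a run manifest (`manifest.txt`) to `out_dir`. Reruns
#' with the same configuration produce byte-identical result CSVs.
#'
#' @param config Path to a parameter configuration file, or a `vte_params`
#'   object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the per-strategy `results` and the
#'   incremental `table`.
#' @export
run_base_case <- function(config, out_dir) {
  params <- .resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- .run_base_case_core(params, out_dir)
  .write_manifest(out_dir, "base-case", config, params$rng_seed, NA)
  invisible(out)
}

#' Run the full analysis suite and write result files
#'
#' Executes the deterministic base case, both one-way tornado analyses (the
#' IPC-vs-no-prophylaxis cost-effectiveness ratio and the IPC-vs-LMWH cost
#' difference), the VTE-incidence threshold analysis, the IPC phase scenario
#' analysis, and the probabilistic sensitivity analysis with its
#' acceptability curve. Writes eight result CSVs
#' (`base_case_results.csv`, `pathways.csv`, `owsa_icer_ipc_vs_none.csv`,
#' `owsa_delta_cost_ipc_vs_lmwh.csv`, `threshold_vte.csv`, `scenario.csv`,
#' `psa_draws.csv`, `ceac.csv`), a resolved-probability log (`run.log`), and
#' one manifest (`manifest.txt`). Reruns with the same configuration and
#' seed produce byte-identical result CSVs.
#'
#' @param config Path to a parameter configuration file, or a `vte_params`
#'   object.
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed for the PSA (default: the configuration's
#'   `rng_seed`).
#' @param n Number of PSA draws (default: the configuration's `n_psa`).
#' @return Invisibly, a list with components `base_case`, `owsa_icer`,
#'   `owsa_cost`, `threshold`, `scenario`, `psa`, `ceac`.
#' @export
run_full_analysis <- function(config, out_dir, seed = NULL, n = NULL) {
  params <- .resolve_config(config)
  if (is.null(seed)) seed <- params$rng_seed
  if (is.null(n)) n <- params$n_psa
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  base <- .run_base_case_core(params, out_dir)

  owsa_icer <- one_way_sensitivity(params, "icer_ipc_vs_none")
  .vte_write_csv(as.data.frame(owsa_icer),
                 file.path(out_dir, "owsa_icer_ipc_vs_none.csv"))
  owsa_cost <- one_way_sensitivity(params, "delta_cost_ipc_vs_lmwh")
  .vte_write_csv(as.data.frame(owsa_cost),
                 file.path(out_dir, "owsa_delta_cost_ipc_vs_lmwh.csv"))

  thr <- threshold_vte_incidence(params)
  .vte_write_csv(thr$grid, file.path(out_dir, "threshold_vte.csv"))

  scen <- scenario_analysis(params)
  .vte_write_csv(scen, file.path(out_dir, "scenario.csv"))

  psa <- run_psa(params, n = n, seed = seed)
  .vte_write_csv(psa$samples, file.path(out_dir, "psa_draws.csv"))
  ceac <- acceptability_curve(psa)
  .vte_write_csv(as.data.frame(ceac), file.path(out_dir, "ceac.csv"))

  .write_manifest(out_dir, "all", config, seed, n)
  invisible(list(base_case = base, owsa_icer = owsa_icer,
                 owsa_cost = owsa_cost, threshold = thr, scenario = scen,
                 psa = psa, ceac = ceac))
}
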