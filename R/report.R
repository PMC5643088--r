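# Figure-level reporting: turn per-cell source-data tables or a full
# synthetic run into tidy summary CSVs.

#' Reproduce figure-level summary tables from per-cell source data
#'
#' For each figure panel in a long-format source-data table, writes one
#' tidy CSV of per-condition summary statistics plus, when the panel holds
#' exactly two conditions, the appropriate non-parametric test: the paired
#' Wilcoxon signed-rank test when the two conditions share every cell id
#' (within-subject design), otherwise the Mann-Whitney U test. Panels whose
#' inputs are unusable are skipped with a logged reason.
#'
#' @param source a `pb_source_data` table (see [read_source_data()]) or a
#'   path to one.
#' @param out_dir output directory for the per-panel CSVs (NULL to skip
#'   writing).
#' @return invisibly, a list with `summaries` (per panel x condition),
#'   `tests` (data.frame), `skipped` (named character of reasons).
#' @export
reproduce_tables <- function(source, out_dir = NULL) {
  if (is.character(source)) source <- read_source_data(source)
  pb_assert(inherits(source, "pb_source_data"), "not a source-data table",
            "pb_input_error")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); tests <- list(); skipped <- character(0)
  for (panel in unique(source$figure_panel)) {
    sub <- source[source$figure_panel == panel, ]
    conds <- unique(sub$condition)
    sm <- do.call(rbind, lapply(conds, function(cn) {
      s <- summarize_values(sub$value[sub$condition == cn])
      cbind(figure_panel = panel, condition = cn, s)
    }))
    summaries[[panel]] <- sm
    if (length(conds) == 2L) {
      a <- sub[sub$condition == conds[1], ]
      b <- sub[sub$condition == conds[2], ]
      paired <- setequal(a$cell_id, b$cell_id) && nrow(a) == nrow(b)
      tr <- if (paired) {
        d <- b$value[match(a$cell_id, b$cell_id)] - a$value
        wilcoxon_signed_rank(d, label = sprintf("%s: %s vs %s", panel,
                                                conds[2], conds[1]))
      } else {
        mann_whitney(a$value, b$value,
                     label = sprintf("%s: %s vs %s", panel,
                                     conds[1], conds[2]))
      }
      tests[[panel]] <- data.frame(figure_panel = panel,
                                   test_name = tr$test_name,
                                   statistic = tr$statistic,
                                   p_raw = tr$p_raw,
                                   comparison_label = tr$comparison_label)
    } else if (length(conds) > 2L) {
      skipped[panel] <- "more than two conditions; pairwise tests not inferred"
    }
    if (!is.null(out_dir))
      write.csv(sm, file.path(out_dir, paste0(panel, "_summary.csv")),
                row.names = FALSE)
  }
  tests_df <- if (length(tests)) do.call(rbind, tests) else
    data.frame(figure_panel = character(0), test_name = character(0),
               statistic = numeric(0), p_raw = numeric(0),
               comparison_label = character(0))
  if (nrow(tests_df) > 1L)
    tests_df$p_adjusted <- holm_bonferroni(tests_df$p_raw)
  else if (nrow(tests_df) == 1L)
    tests_df$p_adjusted <- tests_df$p_raw
  if (!is.null(out_dir) && nrow(tests_df))
    write.csv(tests_df, file.path(out_dir, "tests.csv"), row.names = FALSE)
  invisible(list(summaries = summaries, tests = tests_df, skipped = skipped))
}

#' Run the full synthetic study and emit figure-style tables
#'
#' End-to-end smoke path: simulates the main experiment types at the given
#' configuration, runs each analysis, and writes one tidy CSV per panel
#' (paired-pulse ratio, AMPA:NMDA ratio, train rates, sCRACM response
#' curve). Problem sizes are kept small; this is an orchestration check,
#' not a power analysis.
#'
#' @param cfg a `pb_sim_config`.
#' @param out_dir output directory.
#' @param n_cells cells per synthetic "experiment".
#' @return invisibly, a named list of the tables written.
#' @export
run_synthetic_study <- function(cfg = sim_config(), out_dir = NULL,
                                n_cells = 5) {
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  # paired-pulse ratio at 20 Hz
  prot2 <- stim_protocol(c(0.1, 0.15))
  pprs <- vapply(seq_len(n_cells), function(i) {
    cfg_i <- sim_config(seed = cfg$seed + i, synapse = cfg$synapse)
    sim <- simulate_epsc(cfg_i, prot2, holding_mv = -70)
    eps <- extract_epochs(sim$rec, prot2, pre_s = 0.02, post_s = 0.05)
    compute_ppr(measure_epsc(eps[[1]]), measure_epsc(eps[[2]]))
  }, 0)
  out$ppr <- cbind(panel = "ppr_20hz", summarize_values(pprs))

  # AMPA:NMDA ratio with the 40 ms rule
  prot1 <- stim_protocol(0.1)
  ratios <- vapply(seq_len(n_cells), function(i) {
    cfg_i <- sim_config(seed = cfg$seed + 100 + i, synapse = cfg$synapse)
    lo <- simulate_epsc(cfg_i, prot1, holding_mv = -70)
    cfg_i2 <- sim_config(seed = cfg$seed + 200 + i, synapse = cfg$synapse)
    hi <- simulate_epsc(cfg_i2, prot1, holding_mv = 40)
    e_lo <- extract_epochs(lo$rec, prot1, 0.02, 0.15)[[1]]
    e_hi <- extract_epochs(hi$rec, prot1, 0.02, 0.15)[[1]]
    compute_ampa_nmda(e_lo, e_hi)$ratio
  }, 0)
  out$ampa_nmda <- cbind(panel = "ampa_nmda", summarize_values(ratios))

  # train following at 10 Hz
  tr <- stim_protocol(5 + (0:9) * 0.1)
  rates <- vapply(seq_len(n_cells), function(i) {
    cfg_i <- sim_config(seed = cfg$seed + 300 + i)
    sim <- simulate_pacemaker(cfg_i, tr, duration_s = 8)
    spikes <- classify_evoked(detect_spikes(sim$soma), tr)
    intra_stimulus_rate(spikes, tr)$intra_rate_hz
  }, 0)
  out$train <- cbind(panel = "intra_rate_10hz", summarize_values(rates))

  # sCRACM response-frequency curve
  maps <- lapply(seq_len(n_cells), function(i) {
    cfg_i <- sim_config(seed = cfg$seed + 400 + i, scracm = cfg$scracm)
    sim <- simulate_scracm(cfg_i, cell_id = sprintf("cell%02d", i))
    build_scracm_map(sim$cell_id, sim$morphology, sim$spots, sim$epochs,
                     sim$noise_sd_pa)
  })
  out$scracm <- response_frequency_curve(maps, bin_um = 10)

  if (!is.null(out_dir)) {
    for (nm in names(out))
      write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  invisible(out)
}
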