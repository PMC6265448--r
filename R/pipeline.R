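# End-to-end pipeline: simulate (or read) L and D ensembles, measure,
# classify, analyse groups and distributions, compare with Welch's test,
# and write a deterministic TSV report bundle.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param config_l,config_d [synthetic_config()] objects for the two
#'   systems; either may be `NULL` to skip that system (then no comparison
#'   is run).
#' @param criteria A [criteria_config()].
#' @param bin_width Histogram bin width, degrees.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir,
                            config_l = synthetic_config("L"),
                            config_d = synthetic_config("D"),
                            criteria = criteria_config(),
                            bin_width = 5, overwrite = FALSE) {
  structure(list(out_dir = out_dir, config_l = config_l, config_d = config_d,
                 criteria = criteria, bin_width = bin_width,
                 overwrite = overwrite), class = "PipelineConfig")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.4f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.pipeline_system <- function(ens, label, criteria, bin_width, out_dir) {
  m3 <- measure_ensemble(ens, "O3p")
  m2 <- measure_ensemble(ens, "O2p")
  write_measures_table(m3, file.path(out_dir, paste0("measures_", label, "_O3p.tsv")))
  write_measures_table(m2, file.path(out_dir, paste0("measures_", label, "_O2p.tsv")))
  v3 <- classify(m3, criteria)
  v2 <- classify(m2, criteria)
  vout <- v3; vout$frame_id <- vout$frame_id + 1L; vout$run_id <- vout$run_id + 1L
  utils::write.table(vout, file.path(out_dir, paste0("verdicts_", label, "_O3p.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c3 <- count_reactive(ens, "O3p", criteria, measures = m3)
  c2 <- count_reactive(ens, "O2p", criteria, measures = m2)
  .write_tsv(data.frame(run = seq_along(c3$per_run),
                        reactive_O3p = c3$per_run, reactive_O2p = c2$per_run),
             file.path(out_dir, paste0("per_run_counts_", label, ".tsv")))
  grp <- assign_group(m3[v3$reactive, , drop = FALSE])
  .write_tsv(as.data.frame(table(group = grp)),
             file.path(out_dir, paste0("groups_", label, ".tsv")))
  hist_rows <- list()
  for (tau in c("tau_1", "tau_2", "tau_3", "tau_4", "tau_5")) {
    h_all <- dihedral_distribution(m3, tau, bin_width)
    row <- data.frame(tau = tau, mid = h_all$mids, prob_all = h_all$prob)
    if (any(v3$reactive)) {
      h_re <- dihedral_distribution(m3[v3$reactive, , drop = FALSE], tau, bin_width)
      row$prob_reactive <- h_re$prob
    } else {
      row$prob_reactive <- NA_real_
    }
    hist_rows[[tau]] <- row
  }
  .write_tsv(do.call(rbind, hist_rows),
             file.path(out_dir, paste0("distributions_", label, ".tsv")))
  list(counts_o3p = c3, counts_o2p = c2,
       summary = summarize_ensemble(ens, criteria, m3, m2))
}

#' Run the full analysis pipeline
#'
#' Simulates the configured L and D ensembles, measures both nucleophile
#' choices, classifies every frame, writes measures/verdict/count TSVs,
#' group tables and dihedral distributions per system, compares O3'
#' per-run counts with Welch's t-test, and records a manifest (seed,
#' parameters, package version). Identical configuration and seed give
#' byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with both system summaries and the Welch
#'   comparison.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) && !config$overwrite) {
    stop("output directory ", out, " is not empty (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (sys in c("L", "D")) {
    sc <- config[[paste0("config_", tolower(sys))]]
    if (is.null(sc)) next
    message("pipeline: sampling ", sys, " system (",
            sc$n_runs, " x ", sc$frames_per_run, " frames)")
    ens <- sample_ensemble(sc)
    res[[sys]] <- .pipeline_system(ens, sys, config$criteria,
                                   config$bin_width, out)
    if (!is.null(ens$planted)) {
      res[[sys]]$planted_total <- sum(ens$planted)
    }
  }
  if (!is.null(res$L) && !is.null(res$D)) {
    w <- welch_t_test(res$L$counts_o3p$per_run, res$D$counts_o3p$per_run)
    .write_tsv(data.frame(t = w$t, df = w$df, p = w$p,
                          mean_L = w$mean1, mean_D = w$mean2,
                          total_L = res$L$counts_o3p$total,
                          total_D = res$D$counts_o3p$total),
               file.path(out, "welch_comparison.tsv"))
    res$welch <- w
  }
  manifest <- list(
    package = "minihelix",
    version = as.character(utils::packageVersion("minihelix")),
    seed_L = if (!is.null(config$config_l)) config$config_l$seed,
    seed_D = if (!is.null(config$config_d)) config$config_d$seed,
    criteria = unclass(config$criteria),
    n_runs = if (!is.null(config$config_l)) config$config_l$n_runs,
    frames_per_run = if (!is.null(config$config_l)) config$config_l$frames_per_run)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
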