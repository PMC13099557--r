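# Configuration-driven orchestration of the full analysis.

#' Read a flat key = value pipeline configuration
#'
#' Plain-text, one `key = value` per line, `#` comments; values are parsed
#' as numbers where possible. Diffable provenance is the point.
#'
#' @param path File path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  structure(out, class = c("pipeline_config", "list"))
}

#' Assemble a pipeline configuration in code
#'
#' @param tree Path to the newick tree.
#' @param habitat_table Path to the habitat trait table (optional).
#' @param feeding_table Path to the feeding trait table (optional).
#' @param out_dir Output directory.
#' @param rho Sampling fraction (single value or per-habitat overrides as a
#'   named list).
#' @param grid_width Grid interval width (My).
#' @param seed Integer seed.
#' @param generations,pre_burn_in,thin MCMC settings shared by the stages.
#' @param stages Character vector of stages to run, in order, among
#'   `"ebd"`, `"congruence"`, `"bds"`, `"hisse"`.
#' @param truncate_to Common comparison window (My) for rate summaries.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(tree, habitat_table = NULL, feeding_table = NULL,
                            out_dir = "divpace_out", rho = 1, grid_width = 1,
                            seed = 1, generations = 2000, pre_burn_in = 500,
                            thin = 10,
                            stages = c("ebd", "congruence", "bds", "hisse"),
                            truncate_to = NULL) {
  structure(list(tree = tree, habitat_table = habitat_table,
                 feeding_table = feeding_table, out_dir = out_dir,
                 rho = rho, grid_width = grid_width, seed = seed,
                 generations = generations, pre_burn_in = pre_burn_in,
                 thin = thin, stages = stages, truncate_to = truncate_to),
            class = c("pipeline_config", "list"))
}

#' Truncate rate summaries to a common recent window
#'
#' Clips each summary to ages `[0, window]` and recomputes the grand
#' medians over the retained intervals, so trees with different root ages
#' are compared over the same timescale.
#'
#' @param summaries A list of `rate_summary` objects.
#' @param window Window length in My (default 193).
#' @return List of clipped `rate_summary` objects.
#' @export
truncate_to_common_window <- function(summaries, window = 193) {
  lapply(summaries, function(s) {
    if (window > max(s$intervals$age_old) + 1e-9) {
      stop("window (", window, " My) exceeds the summary's grid span")
    }
    keep <- s$intervals$age_old <= window + 1e-9
    s$intervals <- s$intervals[keep, , drop = FALSE]
    s$grand_median <- c(lambda = median(s$intervals$lambda_median),
                        mu = median(s$intervals$mu_median),
                        r = median(s$intervals$r_median))
    s$truncate_to <- window
    s
  })
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order (EBD rate-through-time, congruence
#' checks on the EBD posterior-median trajectory, branch-specific shift
#' detection, HiSSE-2 when a feeding table is supplied), writing per-stage
#' CSV outputs and a JSON manifest recording inputs, seeds and convergence.
#' Stage failures abort with the manifest recording partial completion.
#'
#' @param config A `pipeline_config` (or path to one).
#' @return The manifest, invisibly; written as `manifest.json` in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  if (is.null(cfg$stages)) cfg$stages <- c("ebd", "congruence")
  cfg$stages <- trimws(unlist(strsplit(cfg$stages, ",")))
  if (is.null(cfg$out_dir)) cfg$out_dir <- "divpace_out"
  for (d in c("rho", "grid_width", "seed", "generations", "pre_burn_in",
              "thin")) {
    if (is.null(cfg[[d]])) {
      cfg[[d]] <- formals(pipeline_config)[[d]]
    }
  }
  if (is.null(cfg$tree) || !file.exists(cfg$tree)) {
    stop("config error: tree path missing or nonexistent")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), started = format(Sys.time()),
                   stages = list(), package_version =
                     as.character(utils::packageVersion("divpace")))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  on.exit(write_manifest())

  log_msg <- function(...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  }
  phy <- read_ultrametric_tree(cfg$tree)
  settings <- mcmc_settings(generations = cfg$generations,
                            thin = cfg$thin, pre_burn_in = cfg$pre_burn_in,
                            n_runs = 2, seed = cfg$seed)
  grid <- time_grid_for_tree(phy, cfg$grid_width)
  rho <- if (is.list(cfg$rho)) cfg$rho[[1]] else cfg$rho
  summary_ebd <- NULL

  if ("ebd" %in% cfg$stages) {
    log_msg("EBD: calibrating zeta for %d intervals", grid$n_intervals)
    zeta <- calibrate_zeta(grid$n_intervals, mc_reps = 2e4,
                           seed = substream_seed(cfg$seed, "zeta"))
    log_msg("EBD: zeta = %.6g; running %d generations x 2",
            zeta, cfg$generations)
    traces <- run_ebd_mcmc(phy, grid, zeta, rho, settings)
    conv <- check_convergence(traces, burn_in_fraction = 0.25)
    summary_ebd <- summarize_rates(combine_traces(traces),
                                   truncate_to = cfg$truncate_to)
    write.csv(summary_ebd$intervals,
              file.path(cfg$out_dir, "ebd_rates.csv"), row.names = FALSE)
    manifest$stages$ebd <- list(
      zeta = zeta, converged = conv$converged,
      grand_median = as.list(summary_ebd$grand_median),
      mean_acceptance = mean(unlist(lapply(traces, `[[`, "acceptance")),
                             na.rm = TRUE),
      min_ess = min(conv$parameters$ess))
    log_msg("EBD: done (converged: %s)", conv$converged)
  }

  if ("congruence" %in% cfg$stages) {
    ref <- if (!is.null(summary_ebd)) {
      rate_trajectory(grid, summary_ebd$intervals$lambda_median,
                      summary_ebd$intervals$mu_median)
    } else {
      rate_trajectory(grid, 0.1, 0.05)
    }
    log_msg("congruence: 4 scenarios + joint sampling")
    scen <- lapply(c("constant-mu", "exp-increasing-mu", "constant-lambda",
                     "exp-decreasing-lambda"),
                   function(s) scenario_test(ref, s))
    jset <- sample_congruent_set(
      ref, congruence_sampler_config(seed = substream_seed(cfg$seed, "cong")))
    trends <- summarize_trends(jset)
    members_df <- do.call(rbind, lapply(seq_along(scen), function(i) {
      data.frame(member = scen[[i]]$scenario, valid = scen[[i]]$valid)
    }))
    write.csv(members_df, file.path(cfg$out_dir, "congruence_scenarios.csv"),
              row.names = FALSE)
    write.csv(data.frame(transition = seq_along(trends$agreement),
                         agreement = trends$agreement),
              file.path(cfg$out_dir, "congruence_agreement.csv"),
              row.names = FALSE)
    manifest$stages$congruence <- list(
      valid_scenarios = members_df$member[members_df$valid],
      n_joint_members = length(jset$members),
      trend_threshold = trends$threshold)
    log_msg("congruence: done")
  }

  if ("bds" %in% cfg$stages) {
    log_msg("BDS: shift detection")
    traces <- run_bds_mcmc(phy, rho = rho, settings = settings)
    shifts <- detect_shifts(traces)
    write.csv(as.data.frame(shifts), file.path(cfg$out_dir, "bds_shifts.csv"),
              row.names = FALSE)
    manifest$stages$bds <- list(
      n_shifts = nrow(shifts),
      mean_acceptance = mean(unlist(lapply(traces, `[[`, "acceptance")),
                             na.rm = TRUE))
    log_msg("BDS: %d shifts at PP > 0.5", nrow(shifts))
  }

  if ("hisse" %in% cfg$stages && !is.null(cfg$feeding_table)) {
    log_msg("HiSSE-2: state-dependent diversification")
    ft <- read_trait_table(cfg$feeding_table)
    states <- setNames(ifelse(ft$classification == "benthic", 1L,
                              ifelse(ft$classification == "nonbenthic",
                                     0L, NA)),
                       ft$species)
    keep <- intersect(phy$tip.label, names(states)[!is.na(states)])
    phy_h <- prune_to_set(phy, keep)
    traces <- run_hisse_mcmc(phy_h, states[phy_h$tip.label], rho = rho,
                             settings = settings)
    comb <- combine_hisse_traces(traces)
    tstats <- list(T_1.0A = t_statistic(comb, 1.0, "A"),
                   T_1.3A = t_statistic(comb, 1.3, "A"),
                   T_1.5A = t_statistic(comb, 1.5, "A"),
                   T_1.0B = t_statistic(comb, 1.0, "B"),
                   T_1.3B = t_statistic(comb, 1.3, "B"),
                   T_1.5B = t_statistic(comb, 1.5, "B"))
    stt <- states_through_time(traces)
    write.csv(stt, file.path(cfg$out_dir, "hisse_states_through_time.csv"),
              row.names = FALSE)
    jsonlite::write_json(tstats, file.path(cfg$out_dir, "hisse_tstat.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$hisse <- tstats
    log_msg("HiSSE-2: done")
  }

  manifest$finished <- format(Sys.time())
  manifest$seed <- cfg$seed
  write_manifest()
  on.exit()
  invisible(manifest)
}

#' Pool HiSSE runs into one trace
#' @param traces List of `hisse_trace` objects.
#' @return A single `hisse_trace` with stacked samples and pooled maps.
#' @export
combine_hisse_traces <- function(traces) {
  out <- traces[[1]]
  out$samples <- do.call(rbind, lapply(traces, `[[`, "samples"))
  out$maps <- unlist(lapply(traces, `[[`, "maps"), recursive = FALSE)
  out
}
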