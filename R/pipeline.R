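#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable parameter of the pipeline in one serializable
#' list: simulation sizes, preprocessing settings, surface-Laplacian
#' parameters, spectral settings, and inference settings. A configuration
#' plus its seed reproduces a run bit for bit.
#'
#' @param n_participants Cohort size for simulation mode.
#' @param seed Master seed; participant s uses `seed + s`.
#' @param out_dir Output directory for tables and the run log.
#' @param input_dir Directory of BrainVision triplets (preprocess mode).
#' @param covariates_file CSV of covariates/ratings (analyze mode).
#' @param cutoff,transition High-pass parameters, Hz.
#' @param target_rate Analysis sampling rate, Hz.
#' @param line_freq Line-noise frequency, Hz.
#' @param window,overlap Epoch window and overlap, s.
#' @param reject_threshold Amplitude rejection threshold, uV.
#' @param csd_m,csd_n_terms,csd_lambda,csd_head_radius Surface-Laplacian
#'   parameters.
#' @param f0 Stimulation frequency, Hz.
#' @param a_priori A-priori electrode of interest.
#' @param fdr_alpha Significance level reported in the log.
#' @param bootstrap_B Bootstrap resamples for the correlation table.
#' @param write_brainvision Write simulated sessions as BrainVision
#'   triplets (simulate mode).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_participants = 10, seed = 1L,
                       out_dir = tempfile("ssvepmod_run_"),
                       input_dir = NULL, covariates_file = NULL,
                       cutoff = 1, transition = 2, target_rate = 256,
                       line_freq = 60, window = 2, overlap = 1,
                       reject_threshold = 100,
                       csd_m = 4, csd_n_terms = 50, csd_lambda = 1e-5,
                       csd_head_radius = 10,
                       f0 = 25, a_priori = "Oz", fdr_alpha = 0.05,
                       bootstrap_B = 2000, write_brainvision = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full SSVEP moderation pipeline
#'
#' Orchestrates simulation, preprocessing, surface Laplacian, spectral
#' estimation, and the two-stage moderation analysis, writing CSV tables
#' and a run log to `config$out_dir`:
#' \itemize{
#'   \item `covariates.csv`, `ratings.csv` - simulated participant data
#'   \item `psd_table.csv` - participant x electrode x brightness 25 Hz dB
#'   \item `level1_analysis1.csv`, `level1_analysis2.csv` - first-level
#'     coefficients
#'   \item `level2_analysis1.csv`, `level2_analysis2.csv` - second-level
#'     results (b, LL, UL, SE, SS, MSE, F, p, p_FDR, partial eta-squared)
#'   \item `topography_<model>.csv` - per-electrode second-level values
#'     with montage coordinates, for scalp maps
#'   \item `correlations.csv` - bootstrapped moderator correlations
#'   \item `run_log.txt` - stage log including epoch rejection counts
#' }
#'
#' @param config A [run_config()].
#' @param mode One of `"simulate"`, `"preprocess"`, `"analyze"`,
#'   `"report"`, `"all"`. `"all"` chains every stage on simulated data.
#' @param planted A [planted_model()] for simulation.
#' @param session A [session_spec()] for simulation.
#' @return Invisibly, a list with the in-memory results (`covariates`,
#'   `ratings`, `psd`, `analysis1`, `analysis2`, `correlations`,
#'   `log`).
#' @export
run_pipeline <- function(config = run_config(), mode = "all",
                         planted = planted_model(),
                         session = session_spec()) {
  mode <- match.arg(mode, c("simulate", "preprocess", "analyze", "report",
                            "all"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- character()
  say <- function(...) logf <<- c(logf, sprintf(...))
  montage <- montage_1020(a_priori = config$a_priori)
  res <- list()

  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  # --- simulate -----------------------------------------------------------
  recs <- NULL
  if (mode %in% c("simulate", "all")) {
    tryCatch({
      params <- cohort_params(n_participants = config$n_participants,
                              seed = config$seed)
      cohort <- generate_cohort(params)
      say("simulated cohort of %d participants (seed %d)",
          nrow(cohort), config$seed)
      recs <- lapply(seq_len(nrow(cohort)), function(i)
        generate_session_eeg(cohort[i, ], planted, session,
                             seed = config$seed + i, montage = montage))
      names(recs) <- cohort$participant
      res$covariates <- cohort
      if (config$write_brainvision) {
        for (pid in names(recs))
          write_brainvision(recs[[pid]], file.path(config$out_dir, pid))
        say("wrote %d BrainVision triplets", length(recs))
      }
    }, error = function(e) fail("simulate", e))
  }

  # --- preprocess + CSD + spectral ---------------------------------------
  if (mode %in% c("preprocess", "all")) {
    tryCatch({
      if (is.null(recs)) {
        files <- list.files(config$input_dir, pattern = "\\.vhdr$",
                            full.names = TRUE)
        if (length(files) == 0) stop("no .vhdr files in input_dir")
        recs <- lapply(files, read_brainvision)
        names(recs) <- sub("\\.vhdr$", "", basename(files))
      }
      kernel <- build_csd_kernel(montage, m = config$csd_m,
                                 n_terms = config$csd_n_terms,
                                 lambda = config$csd_lambda,
                                 head_radius = config$csd_head_radius)
      esets <- list()
      for (pid in names(recs)) {
        rec <- preprocess_recording(recs[[pid]], cutoff = config$cutoff,
                                    transition = config$transition,
                                    target_rate = config$target_rate,
                                    line_freq = config$line_freq)
        eset <- reject_epochs(
          epoch_blocks(rec, config$window, config$overlap),
          config$reject_threshold)
        rej <- attr(eset, "rejection_counts")
        say("%s: %d/%d epochs rejected", pid, sum(rej$n_rejected),
            nrow(eset$meta))
        esets[[pid]] <- apply_laplacian(eset, kernel)
      }
      res$psd <- build_psd_table(esets, f0 = config$f0)
      mb <- attr(res$psd, "missing_blocks")
      if (!is.null(mb))
        say("missing blocks (all epochs rejected): %d", nrow(mb))
      utils::write.csv(res$psd, file.path(config$out_dir, "psd_table.csv"),
                       row.names = FALSE)
    }, error = function(e) fail("preprocess", e))
  }

  # --- simulate ratings (needs PSD) --------------------------------------
  if (mode %in% c("simulate", "all") && !is.null(res$psd)) {
    tryCatch({
      drv <- config$a_priori
      res$ratings <- dplyr::bind_rows(
        lapply(seq_len(nrow(res$covariates)), function(i) {
          pid <- res$covariates$participant[i]
          pb <- res$psd[res$psd$participant == pid &
                          res$psd$electrode == drv,
                        c("brightness", "psd_db")]
          r <- generate_ratings(res$covariates[i, ], pb, planted,
                                seed = config$seed + 10000L + i)
          r$participant <- pid
          r
        }))
      write_participants_csv(res$covariates,
                             file.path(config$out_dir, "covariates.csv"),
                             res$ratings)
      utils::write.csv(res$ratings,
                       file.path(config$out_dir, "ratings.csv"),
                       row.names = FALSE)
    }, error = function(e) fail("simulate-ratings", e))
  }

  # --- analyze ------------------------------------------------------------
  if (mode %in% c("analyze", "report", "all")) {
    tryCatch({
      if (is.null(res$psd)) {
        res$psd <- tibble::as_tibble(utils::read.csv(
          file.path(config$out_dir, "psd_table.csv")))
      }
      if (is.null(res$covariates) && !is.null(config$covariates_file)) {
        cv <- tibble::as_tibble(utils::read.csv(config$covariates_file))
        rcols <- grep("^rating_", names(cv), value = TRUE)
        res$covariates <- cv[, setdiff(names(cv), rcols)]
        res$ratings <- tidyr::pivot_longer(
          cv[, c("participant", rcols)], dplyr::all_of(rcols),
          names_to = "brightness", values_to = "rating",
          names_transform = function(x)
            as.numeric(sub("^rating_", "", x)))
      }
      res$analysis1 <- analyze_brightness(res$psd, config$a_priori)
      say("analysis 1: %d electrodes", length(unique(res$psd$electrode)))
      if (!is.null(res$ratings)) {
        res$analysis2 <- analyze_moderation(res$psd, res$ratings,
                                            res$covariates,
                                            config$a_priori)
        res$correlations <- moderator_corr_table(res$covariates,
                                                 B = config$bootstrap_B,
                                                 seed = config$seed)
      }
      check_level2_identities(res$analysis1$level2)
      if (!is.null(res$analysis2)) check_level2_identities(res$analysis2$level2)
    }, error = function(e) fail("analyze", e))
  }

  # --- report -------------------------------------------------------------
  if (mode %in% c("report", "all")) {
    tryCatch({
      tidy_l2 <- function(l2) {
        l2[, c("electrode", "model", "term", "b", "ci_lo", "ci_hi", "se",
               "ss", "mse", "f", "p", "p_fdr", "eta_p2", "df_num",
               "df_den")]
      }
      utils::write.csv(tidy_l2(res$analysis1$level2),
                       file.path(config$out_dir, "level2_analysis1.csv"),
                       row.names = FALSE)
      utils::write.csv(res$analysis1$level1,
                       file.path(config$out_dir, "level1_analysis1.csv"),
                       row.names = FALSE)
      pos <- tibble::tibble(electrode = montage$labels,
                            x = montage$pos[, 1], y = montage$pos[, 2],
                            z = montage$pos[, 3])
      topo <- function(l2, model) {
        dplyr::left_join(
          l2[l2$model == model & l2$term == "Intercept",
             c("electrode", "b", "p", "p_fdr")],
          pos, by = "electrode")
      }
      utils::write.csv(topo(res$analysis1$level2, "Intercept"),
                       file.path(config$out_dir,
                                 "topography_intercept.csv"),
                       row.names = FALSE)
      utils::write.csv(topo(res$analysis1$level2, "Brightness"),
                       file.path(config$out_dir,
                                 "topography_brightness.csv"),
                       row.names = FALSE)
      if (!is.null(res$analysis2)) {
        utils::write.csv(tidy_l2(res$analysis2$level2),
                         file.path(config$out_dir, "level2_analysis2.csv"),
                         row.names = FALSE)
        utils::write.csv(res$analysis2$level1,
                         file.path(config$out_dir, "level1_analysis2.csv"),
                         row.names = FALSE)
        utils::write.csv(res$correlations,
                         file.path(config$out_dir, "correlations.csv"),
                         row.names = FALSE)
      }
      say("report written to %s", config$out_dir)
    }, error = function(e) fail("report", e))
  }

  res$log <- logf
  writeLines(logf, file.path(config$out_dir, "run_log.txt"))
  invisible(res)
}

# Defensive invariants asserted on every emitted second-level table:
# F = SS/MSE for 1-df terms, partial eta-squared reconstructs from
# (SS, df_den, MSE), and the CI reconstructs from (b, SE, df_den).
check_level2_identities <- function(l2, tol = 1e-8) {
  stopifnot(
    all(abs(l2$f - l2$ss / (l2$df_num * l2$mse)) <= tol * pmax(1, l2$f)),
    all(abs(l2$eta_p2 - l2$ss / (l2$ss + l2$df_den * l2$mse)) <= tol),
    all(abs(l2$ci_lo - (l2$b - stats::qt(0.975, l2$df_den) * l2$se)) <=
          tol * pmax(1, abs(l2$b))),
    all(abs(l2$ci_hi - (l2$b + stats::qt(0.975, l2$df_den) * l2$se)) <=
          tol * pmax(1, abs(l2$b)))
  )
  invisible(l2)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()], used by the
#' `inst/cli/ssvepmod.R` script. Subcommands: `simulate`, `preprocess`,
#' `analyze`, `report`, `all`. Flags: `--config <yaml>`,
#' `--seed <int>`, `--out <dir>`, `--n <participants>`,
#' `--electrode <label>`, `--alpha <fdr alpha>`, `--input <dir>`,
#' `--covariates <csv>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: ssvepmod <simulate|preprocess|analyze|report|all>",
        "[--config F] [--seed N] [--out DIR] [--n N] [--electrode CH]",
        "[--alpha A] [--input DIR] [--covariates CSV]\n")
    return(invisible(0L))
  }
  mode <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  config <- if (!is.null(opt("--config"))) read_run_config(opt("--config"))
            else run_config()
  if (!is.null(opt("--seed"))) config$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--out"))) config$out_dir <- opt("--out")
  if (!is.null(opt("--n")))
    config$n_participants <- as.integer(opt("--n"))
  if (!is.null(opt("--electrode"))) config$a_priori <- opt("--electrode")
  if (!is.null(opt("--alpha"))) config$fdr_alpha <- as.numeric(opt("--alpha"))
  if (!is.null(opt("--input"))) config$input_dir <- opt("--input")
  if (!is.null(opt("--covariates")))
    config$covariates_file <- opt("--covariates")
  status <- tryCatch({
    run_pipeline(config, mode = mode)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
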