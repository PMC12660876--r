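#' Write per-unit encoding scores as TSV
#'
#' @param cv An `encoding_cv` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scores_tsv <- function(cv, path) {
  df <- data.frame(unit_id = seq_along(cv$r2_mean),
                   r2 = cv$r2_mean, z_r2 = cv$z_r2_mean)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a unit time-series matrix from a plain-text file
#'
#' Accepts whitespace- or tab-separated matrices (scans x units), with or
#' without a header row.
#'
#' @param path File path.
#' @param header Whether the first line holds column names.
#' @return Numeric matrix.
#' @export
read_timeseries_matrix <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, header = header))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized keys (all optional, nested): `task.*` ([task_config()]
#' arguments), `observer.*` ([observer_config()]), `encoding.{model,
#' estimate, K, width}`, `ridge.lambda`, `null.n_sequences`, `seed`,
#' `simulate.{n_voxels, noise_ratio}`, `recover.{n_experiments,
#' n_voxels}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_config: configuration file not found: ", path,
         call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_config: the 'yaml' package is required for YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_call <- function(fun, cfg_section) {
  if (is.null(cfg_section)) return(fun())
  args <- cfg_section[intersect(names(cfg_section),
                                names(formals(fun)))]
  do.call(fun, args)
}

#' Run manifest describing a pipeline invocation
#'
#' @param command Command name.
#' @param config Configuration list as run.
#' @param seed Integer seed.
#' @param outputs Character vector of files written.
#' @return A list suitable for JSON serialization.
#' @export
run_manifest <- function(command, config, seed, outputs) {
  list(command = command,
       package_version =
         as.character(utils::packageVersion("probencode")),
       seed = seed,
       timestamp = format(Sys.time(), tz = "UTC",
                          "%Y-%m-%dT%H:%M:%SZ"),
       config = config,
       outputs = outputs)
}

#' Execute a pipeline stage and write its outputs
#'
#' Library-style entry point mirrored by the `inst/cli/probencode.R`
#' script. Commands:
#' \describe{
#'   \item{simulate}{Generate task sessions; write per-session events and
#'     normative-estimate TSVs.}
#'   \item{observer}{Run the ideal observer on events TSVs found in the
#'     output of a previous `simulate`; write estimates TSVs.}
#'   \item{fit}{Simulate an experiment under the configured generative
#'     code and evaluate the configured encoding model; write per-unit
#'     scores.}
#'   \item{characterize}{As `fit`, then characterize every unit's tuning
#'     curve; write the characterization table.}
#'   \item{decode}{As `fit`, then run 5-bin correlation-distance
#'     decoding; write per-fold accuracies.}
#'   \item{recover}{Run the model-recovery simulation; write the mean
#'     z-R2 and best-fit fraction matrices.}
#' }
#' A `manifest.json` recording the command, configuration, seed and
#' output files is always written. Identical command + seed produce
#' byte-identical outputs.
#'
#' @param command One of the commands above.
#' @param config Configuration list (see [read_config()]) or a file path.
#' @param seed Integer seed for every source of randomness.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "observer", "fit",
                                     "characterize", "decode",
                                     "recover"),
                         config = list(), seed = 1L, out_dir = ".") {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  task <- config_call(task_config, config$task)
  obs <- config_call(observer_config, config$observer)
  lambda <- config$ridge$lambda %||% 1
  n_null <- config$null$n_sequences %||% 100L
  spec <- config_call(encoding_spec, config$encoding)
  outputs <- character(0)
  out <- function(name) file.path(out_dir, name)

  if (command == "simulate" || command == "observer") {
    set.seed(seed)
    for (s in seq_len(task$n_sessions)) {
      sq <- generate_sequence(task, seed = NULL,
                              session_id = paste0("session", s))
      trc <- run_ideal_observer(sq$values, obs)
      f1 <- out(sprintf("events_session%d.tsv", s))
      f2 <- out(sprintf("estimates_session%d.tsv", s))
      write_events_tsv(sq, f1)
      write_estimates_tsv(trc, f2)
      outputs <- c(outputs, f1, f2)
    }
  } else if (command %in% c("fit", "characterize", "decode")) {
    n_voxels <- config$simulate$n_voxels %||% 20L
    noise_ratio <- config$simulate$noise_ratio %||% 9
    sim <- simulate_experiment(task, spec, n_voxels = n_voxels,
                               noise_ratio = noise_ratio, seed = seed,
                               obs = obs)
    if (command == "decode") {
      bp <- estimate_bin_patterns(sim$seqs, sim$Y,
                                  estimate = spec$estimate,
                                  n_top = config$decode$n_top %||% 100L,
                                  lambda = lambda, n_null = n_null,
                                  seed = seed, obs = obs,
                                  reports = sim$reports)
      dec <- suppressWarnings(decode_bins(bp))
      f <- out("decoding_accuracy.tsv")
      utils::write.table(
        data.frame(fold = seq_along(dec$accuracy_by_fold),
                   accuracy = dec$accuracy_by_fold),
        f, sep = "\t", row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, f)
    } else {
      cv <- evaluate_encoding(sim$seqs, sim$Y, spec, lambda = lambda,
                              n_null = n_null, seed = seed, obs = obs,
                              reports = sim$reports)
      f <- out("scores.tsv")
      write_scores_tsv(cv, f)
      outputs <- c(outputs, f)
      if (command == "characterize") {
        if (is.null(spec$basis)) {
          stop("run_pipeline: characterize requires a versatile encoding spec",
               call. = FALSE)
        }
        Xp <- NULL  # full-data refit for curve reconstruction
        designs <- lapply(seq_along(sim$seqs), function(s)
          build_design(sim$seqs[[s]], sim$traces[[s]], spec,
                       reports = sim$reports[[s]]))
        Xp <- preprocess_sessions(lapply(designs, `[[`, "X"),
                                  tr = task$tr)
        Yp <- preprocess_sessions(sim$Y, tr = task$tr)
        fit <- fit_encoding(do.call(rbind, Xp), do.call(rbind, Yp),
                            lambda, designs[[1]]$interest_mask)
        tab <- characterize_units(
          fit$weights[designs[[1]]$interest_mask, , drop = FALSE],
          spec$basis)
        f2 <- out("characterization.tsv")
        write_characterization_tsv(tab, f2)
        outputs <- c(outputs, f2)
      }
    }
  } else if (command == "recover") {
    rec <- model_recovery(
      n_experiments = config$recover$n_experiments %||% 10L,
      n_voxels = config$recover$n_voxels %||% 20L,
      lambda = lambda, n_null = n_null, seed = seed,
      task = task, obs = obs)
    f1 <- out("recovery_mean_z_r2.tsv")
    f2 <- out("recovery_frac_best.tsv")
    utils::write.table(rec$mean_z_r2, f1, sep = "\t", quote = FALSE)
    utils::write.table(rec$frac_best, f2, sep = "\t", quote = FALSE)
    outputs <- c(outputs, f1, f2)
  }

  manifest <- run_manifest(command, config, seed, outputs)
  mpath <- out("manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), mpath)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
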