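#' Default pipeline configuration
#'
#' All stage settings in one named list; [runPipeline()] merges user
#' overrides onto these defaults, and the merged snapshot is recorded in the
#' run manifest so every unstated setting is inspectable.
#'
#' @return named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(preset = "p48a_like", n_residues = 68L, tm_ns = NA_real_,
       field_mhz = 600.13, r_nh_angstrom = 1.02, csa_ppm = -160,
       gamma_ratio = -9.8656, diffusion = "iso", seed = 1L,
       height_cv = 0.02, n_rate_replicates = 2L, n_noe_pairs = 3L,
       n_mc = 0L, sigma_floor = 0.005, gof_level = 0.90, ftest_level = 0.80,
       n_sims = 500L, gof_method = "monte_carlo")
}

.mergeConfig <- function(config) {
  out <- pipelineDefaults()
  for (nm in names(config)) out[[nm]] <- config[[nm]]
  out
}

.schemaError <- function(msg) {
  stop(structure(class = c("schema_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.inputDigests <- function(inputs) {
  files <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && length(x) == 1 && file.exists(x), logical(1))])
  if (length(files) == 0) return(list())
  as.list(tools::md5sum(files))
}

.stageManifest <- function(command, config, inputs, out_dir) {
  list(command = command, config = config,
       inputs = .inputDigests(inputs),
       seed = config$seed,
       tool_version = as.character(utils::packageVersion("spinrelax")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages as a reproducible pipeline. Stages:
#' \describe{
#'   \item{simulate}{generate a ground-truth profile and noisy decay data;
#'     writes decays.tsv, rates_true.tsv, truth.tsv.}
#'   \item{rates}{fit R1/R2/NOE from a decay table (`inputs$decays`);
#'     writes rates.tsv.}
#'   \item{modelfree}{model-free analysis of a rate table (`inputs$rates`);
#'     optimizes tau_m unless `config$tm_ns` is set; writes modelfree.tsv.}
#'   \item{compare}{residue-by-residue comparison of two model-free result
#'     tables (`inputs$a`, `inputs$b`); writes comparison.tsv, report.txt.}
#' }
#' Every stage writes its outputs atomically plus a `manifest.json`
#' recording the command, merged config, input digests, seed and package
#' version. Input-schema violations raise a condition of class
#' "schema_error" naming the offending columns (the command-line wrapper
#' maps these to exit status 2); per-residue convergence failures are
#' reported in the output status column, not as errors.
#'
#' @param command one of "simulate", "rates", "modelfree", "compare".
#' @param config named list of overrides onto [pipelineDefaults()].
#' @param inputs named list of input file paths (stage-dependent).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with output paths and the manifest.
#' @export
runPipeline <- function(command = c("simulate", "rates", "modelfree",
                                    "compare"),
                        config = list(), inputs = list(),
                        out_dir = ".") {
  command <- match.arg(command)
  cfg <- .mergeConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- spectrometerContext(cfg$field_mhz, cfg$r_nh_angstrom, cfg$csa_ppm,
                             cfg$gamma_ratio)
  outputs <- list()

  if (command == "simulate") {
    tm <- if (is.na(cfg$tm_ns)) 6.38 else cfg$tm_ns
    prof <- makeProfile(cfg$preset, n_residues = cfg$n_residues, tm_ns = tm,
                        seed = cfg$seed)
    sim <- simulateDecays(prof, ctx,
                          noiseModel(cfg$height_cv, cfg$n_rate_replicates,
                                     cfg$n_noe_pairs, cfg$seed))
    truth <- sim$truth
    truth$te_ns <- truth$te * 1e9
    outputs$decays <- .writeTsv(sim$decays, file.path(out_dir, "decays.tsv"))
    outputs$rates_true <- .writeTsv(sim$rates,
                                    file.path(out_dir, "rates_true.tsv"))
    outputs$truth <- .writeTsv(
      truth[, c("residue", "residue_name", "region", "model", "s2", "te_ns",
                "rex")],
      file.path(out_dir, "truth.tsv"))
    message(sprintf("[simulate] %s: %d observable residues, cv = %g, seed = %d",
                    sim$manifest$run_id, nrow(truth), cfg$height_cv, cfg$seed))
  } else if (command == "rates") {
    if (is.null(inputs$decays)) .schemaError("rates stage requires inputs$decays")
    decays <- tryCatch(readDecayTable(inputs$decays),
                       error = function(e) .schemaError(conditionMessage(e)))
    rates <- fitDecayTable(decays)
    outputs$rates <- .writeTsv(rates, file.path(out_dir, "rates.tsv"))
    message(sprintf("[rates] fitted %d residues (%d flagged)", nrow(rates),
                    sum(rates$status != "ok")))
  } else if (command == "modelfree") {
    if (is.null(inputs$rates)) .schemaError("modelfree stage requires inputs$rates")
    records <- tryCatch(readRateTable(inputs$rates),
                        error = function(e) .schemaError(conditionMessage(e)))
    diffusion <- if (is.na(cfg$tm_ns)) NULL else
      diffusionModel(cfg$tm_ns,
                     kind = if (cfg$diffusion == "axial")
                       "axially_symmetric" else "isotropic",
                     anisotropy_ratio = if (cfg$diffusion == "axial") 1.25
                     else NA_real_)
    sel <- selectionConfig(cfg$gof_level, cfg$ftest_level, cfg$n_sims,
                           cfg$gof_method, seed = cfg$seed)
    res <- modelfreeAnalysis(records, ctx, diffusion = diffusion,
                             config = sel, mc_draws = cfg$n_mc,
                             mc_seed = cfg$seed)
    outputs$modelfree <- .writeTsv(res, file.path(out_dir, "modelfree.tsv"))
    tm_used <- attr(res, "diffusion")@tm * 1e9
    cfg$tm_ns_used <- tm_used
    message(sprintf("[modelfree] %d residues, tau_m = %.3f ns, %d converged",
                    nrow(res), tm_used, sum(res$status != "failed")))
  } else if (command == "compare") {
    if (is.null(inputs$a) || is.null(inputs$b))
      .schemaError("compare stage requires inputs$a and inputs$b")
    a <- readModelfreeResults(inputs$a)
    b <- readModelfreeResults(inputs$b)
    # optional rate tables widen the comparison to R1/R2/NOE
    if (!is.null(inputs$rates_a))
      a <- merge(readRateTable(inputs$rates_a)[, c("residue", "R1", "R2", "NOE")],
                 a, by = "residue", all = TRUE)
    if (!is.null(inputs$rates_b))
      b <- merge(readRateTable(inputs$rates_b)[, c("residue", "R1", "R2", "NOE")],
                 b, by = "residue", all = TRUE)
    cmp <- buildComparisonTable(a, b,
                                label_a = if (!is.null(config$label_a))
                                  config$label_a else "A",
                                label_b = if (!is.null(config$label_b))
                                  config$label_b else "B")
    outputs$comparison <- .writeTsv(as.data.frame(cmp),
                                    file.path(out_dir, "comparison.tsv"))
    report <- renderComparisonReport(cmp)
    tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
    writeLines(report, tmp)
    file.rename(tmp, file.path(out_dir, "report.txt"))
    outputs$report <- file.path(out_dir, "report.txt")
    message(sprintf("[compare] %d comparison rows (%d with missing data)",
                    nrow(cmp), sum(cmp$missing)))
  }

  manifest <- .stageManifest(command, cfg, inputs, out_dir)
  manifest$outputs <- lapply(outputs, basename)
  writeManifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(outputs = outputs, manifest = manifest))
}
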