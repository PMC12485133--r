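#' Run the analysis pipeline from a YAML configuration
#'
#' Wires the stages end to end: synthetic-data generation, CSP computation
#' and residue classification, restraint generation, PRE back-calculation
#' with two-state population fitting, and kinetic simulation/decomposition.
#' Stages execute in dependency order; each stage writes plain-text outputs
#' under `out_dir` and a run manifest records the configuration hash, seed
#' and a digest of every output file, so identical config + seed yields
#' identical digests.
#'
#' @param config Path to a YAML file, or an equivalent named list, with
#'   optional fields `seed`, `out_dir`, `stages` (subset of `"synth"`,
#'   `"csp"`, `"restraints"`, `"pre_fit"`, `"kinetics"`) and per-stage
#'   parameter blocks.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "allogap-run")
  stages <- cfg$stages %||% c("synth", "csp", "restraints", "pre_fit",
                              "kinetics")
  known <- c("synth", "csp", "restraints", "pre_fit", "kinetics")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  deps <- list(csp = "synth", restraints = c("synth", "csp"),
               pre_fit = "synth", kinetics = character())
  for (st in stages) {
    missing_dep <- setdiff(deps[[st]] %||% character(), stages)
    if (length(missing_dep) > 0) {
      abort(paste0("stage '", st, "' requires upstream stage(s): ",
                   paste(missing_dep, collapse = ", ")))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, t0) {
    message(sprintf("[allogap] stage %-10s seed %d  %.2fs",
                    stage, seed, as.numeric(Sys.time()) - t0))
  }
  outputs <- character()
  spec <- do.call(synthetic_spec, c(list(seed = seed),
                                    cfg$synthetic %||% list()))
  state <- new.env(parent = emptyenv())

  if ("synth" %in% stages) {
    t0 <- as.numeric(Sys.time())
    state$toy <- gen_toy_complex(spec)
    state$peaks <- gen_peak_tables(spec)
    f1 <- file.path(out_dir, "state_a.pdb")
    f2 <- file.path(out_dir, "state_b.pdb")
    write_pdb_ensemble(state$toy$state_a, f1)
    write_pdb_ensemble(state$toy$state_b, f2)
    f3 <- file.path(out_dir, "peaks_free.csv")
    f4 <- file.path(out_dir, "peaks_bound.csv")
    write_peak_table(state$peaks$free, f3)
    write_peak_table(state$peaks$bound, f4)
    outputs <- c(outputs, f1, f2, f3, f4)
    log_stage("synth", t0)
  }
  if ("csp" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cfg_csp <- do.call(csp_config, cfg$csp %||% list())
    state$csps <- compute_csp(state$peaks$free, state$peaks$bound, cfg_csp)
    rsa <- relative_solvent_accessibility(state$toy$state_a, chain = "B",
                                          n_points = 240)
    state$classes <- classify_residues(state$csps, rsa, state$toy$state_a,
                                       chain = "B", cfg_csp)
    f <- file.path(out_dir, "csp.csv")
    utils::write.csv(as.data.frame(state$classes), f, row.names = FALSE)
    outputs <- c(outputs, f)
    log_stage("csp", t0)
  }
  if ("restraints" %in% stages) {
    t0 <- as.numeric(Sys.time())
    pre <- gen_pre_profiles(state$toy, noise_sd = 0)
    # classify the labelled chain from its own (synthetic) peak tables so
    # both molecules contribute to the ambiguous restraints
    spec_a <- spec
    spec_a$interface_residues <- c(13, 15, 17)
    peaks_a <- gen_peak_tables(spec_a, residues = seq(1, 29, by = 2))
    csps_a <- compute_csp(peaks_a$free, peaks_a$bound, csp_config())
    rsa_a <- relative_solvent_accessibility(state$toy$state_a, chain = "A",
                                            n_points = 240)
    classes_a <- classify_residues(csps_a, rsa_a, state$toy$state_a,
                                   chain = "A", csp_config())
    airs <- build_airs(active_a = attr(state$classes, "active"),
                       passive_a = attr(state$classes, "passive"),
                       active_b = attr(classes_a, "active"),
                       passive_b = attr(classes_a, "passive"),
                       chain_a = "B", chain_b = "A")
    unam <- pre_restraints(pre, state$toy$label_site, probe_chain = "B")
    f <- file.path(out_dir, "restraints.tbl")
    write_tbl(airs, unam, f)
    outputs <- c(outputs, f)
    log_stage("restraints", t0)
  }
  if ("pre_fit" %in% stages) {
    t0 <- as.numeric(Sys.time())
    profile <- gen_pre_profiles(state$toy)
    fit <- fit_two_state(attr(profile, "profile_a"),
                         attr(profile, "profile_b"), profile)
    f <- file.path(out_dir, "pre_fit.json")
    jsonlite::write_json(as.list(glance(fit)), f, auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, f)
    log_stage("pre_fit", t0)
  }
  if ("kinetics" %in% stages) {
    t0 <- as.numeric(Sys.time())
    params <- default_kinetic_params()
    dec <- decompose_activation(params)
    trans <- build_network(assay_condition("trans"), params)
    res <- list(
      decomposition = as.list(dec$gains),
      c50_trans = c50(titration_curve(trans)),
      za_efficiency = dec$efficiencies$efficiency[1])
    f <- file.path(out_dir, "kinetics.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    log_stage("kinetics", t0)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("allogap")),
    seed = seed,
    config_hash = digest_object(cfg),
    stages = stages,
    outputs = lapply(setNames(outputs, basename(outputs)), digest_file))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

digest_file <- function(path) unname(tools::md5sum(path))

digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE), tmp)
  digest_file(tmp)
}
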