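# End-to-end driver: simulate (or read) a cohort, preprocess, run the
# correlation grid per trait (optionally per stratum), and write a
# machine-readable run report.  All outputs are deterministic functions of
# the configuration (including the seed): no timestamps.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param input optional path to an existing cohort CSV; when `NULL` a
#'   cohort is simulated from `sim_config`.
#' @param sim_config a [twin_sim_config()] used when `input` is `NULL`.
#' @param traits traits to analyze, subset of `c("bmi", "height")`.
#' @param ages integer age range for the grid, within `[1, 19]`.
#' @param model_tag `"AE"` or `"ACE"`.
#' @param design `"five_group"` or `"single_sex"`.
#' @param ci_method `"wald"` or `"profile"`.
#' @param min_pairs minimum jointly informative pairs per grid cell.
#' @param stratify_by optional cohort column to stratify the grid runs by
#'   (e.g. `"cohort"` to emulate region-wise reruns).
#' @param seed integer seed governing all randomness (passed into the
#'   simulation config).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input = NULL,
                            sim_config = NULL,
                            traits = c("bmi", "height"),
                            ages = 1:19,
                            model_tag = c("AE", "ACE"),
                            design = c("five_group", "single_sex"),
                            ci_method = c("wald", "profile"),
                            min_pairs = 30,
                            stratify_by = NULL,
                            seed = 1) {
  model_tag <- match.arg(model_tag)
  design <- match.arg(design)
  ci_method <- match.arg(ci_method)
  ages <- sort(unique(as.integer(ages)))
  if (length(ages) < 2L || any(ages < 1L) || any(ages > 19L))
    stop("ages must contain at least two distinct integers in [1, 19]")
  traits <- match.arg(traits, several.ok = TRUE)
  if (is.null(input) && is.null(sim_config))
    sim_config <- twin_sim_config(ages = ages, seed = seed)
  structure(list(out_dir = out_dir, input = input, sim_config = sim_config,
                 traits = traits, ages = ages, model_tag = model_tag,
                 design = design, ci_method = ci_method,
                 min_pairs = min_pairs, stratify_by = stratify_by,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

panel_trait_name <- function(trait) if (trait == "bmi") "logBMI" else trait

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> grid for every configured
#' trait (and stratum, if requested), writes the cohort, panel, long-format
#' grids and square matrices under `config$out_dir`, and emits
#' `report.json` plus a `MANIFEST` of produced files. A stage failure is
#' captured in the report (`success = FALSE`, failing stage and message);
#' outputs produced before the failure are preserved.
#'
#' @param config a [pipeline_config()].
#' @return the run report (a list), invisibly. Report fields: `success`,
#'   `seed`, `version`, `stages`, per-trait cell/convergence counts, and
#'   `error` on failure.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  report <- list(success = FALSE,
                 seed = config$seed,
                 version = as.character(utils::packageVersion("twinace")),
                 stages = character(0),
                 grids = list())
  note <- function(f) manifest <<- c(manifest, f)
  stage <- function(name) report$stages <<- c(report$stages, name)

  finish <- function() {
    writeLines(c(manifest,
                 if (!report$success) "STATUS: INCOMPLETE" else "STATUS: COMPLETE"),
               file.path(config$out_dir, "MANIFEST"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(report)
  }

  result <- tryCatch({
    stage("cohort")
    if (is.null(config$input)) {
      cohort <- simulate_cohort(config$sim_config)
      write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
      note("cohort.csv")
    } else {
      cohort <- read_cohort_csv(config$input)
    }
    report$n_records <- nrow(cohort)
    report$n_families <- length(unique(cohort$family_id))

    stage("preprocess")
    panel <- build_panel(cohort, traits = config$traits)
    write_panel_csv(panel, file.path(config$out_dir, "panel.csv"))
    note("panel.csv")

    stage("grid")
    strata <- if (is.null(config$stratify_by)) list(all = panel) else {
      if (!config$stratify_by %in% names(cohort))
        stop("stratification column '", config$stratify_by, "' not in cohort")
      key <- cohort[[config$stratify_by]][match(panel$family_id, cohort$family_id)]
      split(panel, key)
    }
    for (sname in names(strata)) {
      sp <- strata[[sname]]
      class(sp) <- c("phenotype_panel", "data.frame")
      for (trait in config$traits) {
        grid <- run_grid(sp, panel_trait_name(trait), ages = config$ages,
                         model_tag = config$model_tag, design = config$design,
                         min_pairs = config$min_pairs,
                         ci_method = config$ci_method)
        tag <- if (sname == "all") trait else paste(trait, sname, sep = "_")
        gfile <- paste0("grid_", tag, ".csv")
        write_grid_csv(grid, file.path(config$out_dir, gfile))
        note(gfile)
        mdir <- file.path(config$out_dir, paste0("matrices_", tag))
        write_grid_matrices(grid, mdir)
        note(paste0("matrices_", tag, "/"))
        s <- attr(grid, "grid_summary")
        s$n_coefficients <- sum(!is.na(grid$r_A))
        report$grids[[tag]] <- s
      }
    }
    report$success <- TRUE
    finish()
  }, error = function(e) {
    report$error <<- list(stage = utils::tail(report$stages, 1),
                          message = conditionMessage(e))
    finish()
  })
  result
}

# ---- configuration serialization -----------------------------------------

#' Write / read a simulation config as YAML
#'
#' Matrices are stored as decay scalars when they were built by
#' [cor_decay()]-style defaults, otherwise as full row lists; the reader
#' reconstructs and re-validates through [twin_sim_config()].
#'
#' @param config a [twin_sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  tr <- lapply(config$traits, function(sp) {
    list(a2 = unname(sp$shares[, "a2", "M"]),
         c2 = unname(sp$shares[, "c2", "M"]),
         e2 = unname(sp$shares[, "e2", "M"]),
         R_A = apply(sp$R_A, 1, as.numeric, simplify = FALSE),
         R_C = apply(sp$R_C, 1, as.numeric, simplify = FALSE),
         R_E = apply(sp$R_E, 1, as.numeric, simplify = FALSE),
         dz_mean_offset = sp$dz_mean_offset,
         cohort_effects = as.list(sp$cohort_effects),
         birth_year_slope = sp$birth_year_slope,
         log_normal = sp$log_normal)
  })
  yaml::write_yaml(list(ages = config$ages,
                        n_pairs_per_group = as.list(config$n_pairs_per_group),
                        rg_os = config$rg_os,
                        missingness_rate = config$missingness_rate,
                        birth_year_range = config$birth_year_range,
                        seed = config$seed,
                        traits = tr), path, precision = 17L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  traits <- lapply(raw$traits, function(t) {
    as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else x
    trait_spec(a2 = unlist(t$a2), c2 = unlist(t$c2), e2 = unlist(t$e2),
               R_A = as_mat(t$R_A), R_C = as_mat(t$R_C), R_E = as_mat(t$R_E),
               dz_mean_offset = t$dz_mean_offset,
               cohort_effects = unlist(t$cohort_effects),
               birth_year_slope = t$birth_year_slope,
               log_normal = t$log_normal)
  })
  twin_sim_config(ages = unlist(raw$ages),
                  n_pairs_per_group = unlist(raw$n_pairs_per_group),
                  traits = traits,
                  rg_os = raw$rg_os,
                  missingness_rate = unlist(raw$missingness_rate),
                  birth_year_range = unlist(raw$birth_year_range),
                  seed = raw$seed)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, standardized components, correlations, log-likelihood
#' and convergence diagnostics (not the internal sufficient statistics).
#'
#' @param fit a `twin_fit`.
#' @param path JSON file path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(model = fit$model_tag, design = fit$design,
              trait = fit$trait, ages = fit$ages,
              logL = fit$logL, converged = fit$converged,
              grad_norm = fit$grad_norm, n_iter = fit$n_iter,
              n_restarts = fit$n_restarts, n_jittered = fit$n_jittered,
              n_pairs = as.list(fit$n_pairs), n_dropped = fit$n_dropped,
              rg_os = fit$rg_os,
              paths = lapply(fit$paths, function(p) lapply(p, function(L)
                apply(L, 1, as.numeric, simplify = FALSE))),
              summary = fit$summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
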