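# End-to-end orchestration: generate -> geometry/sample -> fit, with a
# reproducibility manifest. Each stage consumes only files produced by
# earlier stages, so deleting downstream artifacts and rerunning from
# mid-pipeline reproduces them.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (a phantom cohort is generated under
#'   `out_dir/cohort`) or `"real"` (an existing cohort directory laid out
#'   as in [generate_cohort()] is read).
#' @param phantom for synthetic mode: arguments forwarded to
#'   [phantom_config()] (the global `seed` is injected).
#' @param cohort_dir for real mode: existing cohort directory.
#' @param geometry a [geometry_options()] list (entries override defaults).
#' @param sampling list with `md_threshold` (default 1e-3 mm^2/s).
#' @param models list with `df_method` and `scopes` (default
#'   `list("all")`; tract names add per-tract fits).
#' @param out_dir output directory.
#' @param seed global seed propagated to every stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), phantom = list(),
                       cohort_dir = NULL, geometry = list(),
                       sampling = list(), models = list(),
                       out_dir, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "real" && is.null(cohort_dir))
    stop("real mode requires `cohort_dir`")
  if (mode == "synthetic" && !is.null(cohort_dir))
    stop("exactly one input mode: synthetic config and cohort_dir are mutually exclusive")
  geometry <- utils::modifyList(geometry_options(), geometry)
  sampling <- utils::modifyList(list(md_threshold = 1e-3), sampling)
  models <- utils::modifyList(
    list(df_method = "satterthwaite", scopes = list("all"),
         md_scale = 1e4), models)
  structure(list(mode = mode, phantom = phantom, cohort_dir = cohort_dir,
                 geometry = geometry, sampling = sampling, models = models,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the [run_config()] fields.
#' @param overrides named list of overriding entries (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  raw <- utils::modifyList(raw, overrides)
  do.call(run_config, raw)
}

stage <- function(name, out_dir, expr) {
  marker <- file.path(out_dir, paste0(name, ".incomplete"))
  file.create(marker)
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  unlink(marker)
  res
}

#' Run the full pipeline
#'
#' Stages: cohort (generate phantom or load real), table (geometry +
#' sampling + CSF flagging, written as CSV), fit (both model families per
#' outcome and scope), report (CSV tables + JSON manifest). Reruns with an
#' identical configuration produce bit-identical tables and manifests. A
#' failing stage aborts with a stage-named error and leaves a
#' `<stage>.incomplete` marker in the output directory.
#'
#' @param config a `run_config`, or the path to its JSON file.
#' @return Invisible list with the records, fits and report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("cohort", out_dir, {
    if (config$mode == "synthetic") {
      ph <- config$phantom
      ph$seed <- config$seed
      pc <- do.call(phantom_config, ph)
      cohort_dir <- file.path(out_dir, "cohort")
      generate_cohort(pc, cohort_dir)
      message(sprintf("[cohort] generated %d participants in %s",
                      pc$n_participants, cohort_dir))
      load_cohort(cohort_dir, config$geometry$tract_threshold)
    } else {
      if (!dir.exists(config$cohort_dir))
        stop(sprintf("cohort directory '%s' does not exist",
                     config$cohort_dir))
      load_cohort(config$cohort_dir, config$geometry$tract_threshold)
    }
  })

  records <- stage("table", out_dir, {
    r <- assemble_table(cohort, options = config$geometry)
    r <- apply_csf_exclusion(r, config$sampling$md_threshold)
    write_records(r, file.path(out_dir, "table.csv"))
    message(sprintf("[table] %d records (%d flagged CSF-contaminated)",
                    nrow(r), sum(r$excluded_csf)))
    r
  })

  fits <- stage("fit", out_dir, {
    fl <- list()
    for (scope in config$models$scopes) {
      for (outcome in c("fa", "md")) {
        fl[[paste("gradient", outcome, scope, sep = "_")]] <-
          fit_gradient_model(records, outcome, scope,
                             df_method = config$models$df_method,
                             md_scale = config$models$md_scale)
        has_both <- all(c("tract_wmh", "nearby") %in%
                          records$wmh_type[if (scope == "all") TRUE else
                            records$tract == scope])
        if (has_both) {
          fl[[paste("comparison", outcome, scope, sep = "_")]] <-
            fit_type_comparison_model(records, outcome, scope,
                                      df_method = config$models$df_method,
                                      md_scale = config$models$md_scale)
        }
      }
    }
    fl
  })

  report <- stage("report", out_dir, {
    report_tables(fits, out_dir, manifest_extra = list(
      config = unclass(config),
      seed = config$seed,
      n_records = nrow(records),
      n_csf_excluded = sum(records$excluded_csf)))
  })
  invisible(list(records = records, fits = fits, report = report))
}

#' Validate a real-mode cohort directory
#'
#' Checks, per participant, the presence and grid compatibility of the
#' five volume kinds (tract maps, WMH mask, NAWM mask, FA, MD). Reports
#' every violation, not just the first. Participants with zero WMH voxels
#' are legal but flagged `no_lesion` (they contribute no records);
#' tracts without a WMH intersection are normal and not a violation.
#'
#' @param dir cohort directory.
#' @return list with `participants` (inventory data.frame: id, n_tracts,
#'   n_wmh_voxels, no_lesion, ok) and `violations` (character vector).
#' @export
validate_real_cohort <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("cohort directory '%s' does not exist", dir))
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  violations <- character()
  inv <- list()
  for (pdir in pdirs) {
    pid <- basename(pdir)
    tfiles <- sort(list.files(pdir, pattern = "^tract_.*\\.nii(\\.gz)?$",
                              full.names = TRUE))
    if (length(tfiles) == 0L)
      violations <- c(violations,
                      sprintf("%s: no tract probability maps", pid))
    vols <- list()
    ok <- TRUE
    for (tf in tfiles) {
      v <- tryCatch(read_volume(tf, "probability"), error = function(e) {
        violations <<- c(violations, sprintf("%s: %s", pid,
                                             conditionMessage(e)))
        ok <<- FALSE
        NULL
      })
      if (!is.null(v)) vols[[basename(tf)]] <- v
    }
    n_wmh <- NA_integer_
    for (stem in c("wmh_mask", "nawm_mask", "fa", "md")) {
      f <- NULL
      for (ext in c(".nii.gz", ".nii")) {
        cand <- file.path(pdir, paste0(stem, ext))
        if (file.exists(cand)) { f <- cand; break }
      }
      if (is.null(f)) {
        violations <- c(violations,
                        sprintf("%s: missing %s volume", pid, stem))
        ok <- FALSE
        next
      }
      kind <- if (stem %in% c("wmh_mask", "nawm_mask")) "mask" else "scalar"
      v <- tryCatch(read_volume(f, kind), error = function(e) {
        violations <<- c(violations, sprintf("%s: %s", pid,
                                             conditionMessage(e)))
        ok <<- FALSE
        NULL
      })
      if (!is.null(v)) {
        vols[[stem]] <- v
        if (stem == "wmh_mask") n_wmh <- mask_count(v)
      }
    }
    if (length(vols) > 1L) {
      gridchk <- tryCatch({ assert_common_grid(vols); TRUE },
                          error = function(e) {
                            violations <<- c(violations,
                                             sprintf("%s: %s", pid,
                                                     conditionMessage(e)))
                            FALSE
                          })
      ok <- ok && gridchk
    }
    inv[[pid]] <- data.frame(
      id = pid, n_tracts = length(tfiles),
      n_wmh_voxels = n_wmh,
      no_lesion = !is.na(n_wmh) && n_wmh == 0L,
      ok = ok, stringsAsFactors = FALSE)
  }
  participants <- if (length(inv) > 0L) do.call(rbind, inv) else
    data.frame(id = character(), n_tracts = integer(),
               n_wmh_voxels = integer(), no_lesion = logical(),
               ok = logical(), stringsAsFactors = FALSE)
  rownames(participants) <- NULL
  list(participants = participants, violations = violations)
}
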