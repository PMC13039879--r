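# Shared I/O: sample-level pupil TSV, epoch HDF5 container, YAML run
# configuration, and the end-to-end pipeline with a reproducibility
# manifest.

#' Write / read sample-level pupil recordings as TSV
#'
#' Layout: one row per sample with columns `subject_id`, `block`,
#' `index_in_block`, `t_ms`, `left_mm`, `right_mm`, `valid_l`, `valid_r`.
#' Unknown extra columns are preserved on a round-trip. Files without
#' validity columns are accepted: validity is then inferred from
#' missingness and a note is attached as attribute `"coerced"`.
#'
#' @param samples A `data.frame` of samples (e.g. from
#'   [cohort_pupil_samples()]).
#' @param path File path.
#' @return `write_samples` returns `path` invisibly; `read_samples` the
#'   samples `data.frame` (zero rows for an empty file).
#' @export
write_samples <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  if (nrow(tab) == 0L) return(tab)
  required <- c("subject_id", "block", "index_in_block", "t_ms",
                "left_mm", "right_mm")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("sample file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  coerced <- character(0)
  for (v in c("valid_l", "valid_r")) {
    if (!v %in% names(tab)) {
      src <- if (v == "valid_l") "left_mm" else "right_mm"
      tab[[v]] <- is.finite(tab[[src]])
      coerced <- c(coerced, sprintf("%s inferred from missingness of %s",
                                    v, src))
    } else tab[[v]] <- as.logical(tab[[v]])
  }
  if (length(coerced)) attr(tab, "coerced") <- coerced
  tab
}

#' Flatten a cohort's pupil recordings to a sample table
#'
#' @param cohort An `oddball_cohort`.
#' @return Long `data.frame` in the [write_samples()] layout.
#' @export
cohort_pupil_samples <- function(cohort) {
  stopifnot(inherits(cohort, "oddball_cohort"))
  parts <- list()
  for (rec in cohort) {
    trials <- rec$schedule$trials
    for (i in seq_along(rec$pupil)) {
      ps <- rec$pupil[[i]]
      if (is.null(ps)) next
      parts[[length(parts) + 1L]] <- data.frame(
        subject_id = rec$subject_id, block = trials$block[i],
        index_in_block = trials$index_in_block[i],
        ps[c("t_ms", "left_mm", "right_mm", "valid_l", "valid_r")],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, parts)
}

#' Write / read a cohort's epochs as an HDF5 container
#'
#' One dataset per subject and trial (`/<subject>/trial<idx>`, channels x
#' time) with sampling-rate and window attributes at the file root. Requires
#' the `rhdf5` package.
#'
#' @param cohort An `oddball_cohort`.
#' @param path HDF5 file path.
#' @return `write_epochs_h5` returns `path` invisibly; `read_epochs_h5` a
#'   nested list `subject -> trial index -> erp_epoch`.
#' @export
write_epochs_h5 <- function(cohort, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("write_epochs_h5() requires the rhdf5 package", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rate <- NULL; t_axis <- NULL
  for (rec in cohort) {
    rhdf5::h5createGroup(path, rec$subject_id)
    for (i in seq_along(rec$epochs)) {
      ep <- rec$epochs[[i]]
      if (is.null(ep)) next
      if (is.null(rate)) { rate <- ep$rate; t_axis <- ep$t }
      rhdf5::h5write(ep$data, path,
                     sprintf("%s/trial%03d", rec$subject_id, i))
    }
  }
  rhdf5::h5write(rate, path, "rate_hz")
  rhdf5::h5write(t_axis, path, "t_ms")
  rhdf5::h5write(rownames(cohort[[1L]]$epochs[[
    which(!vapply(cohort[[1L]]$epochs, is.null, logical(1L)))[1L]]]$data),
    path, "channels")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs_h5
#' @export
read_epochs_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("read_epochs_h5() requires the rhdf5 package", call. = FALSE)
  rate <- as.numeric(rhdf5::h5read(path, "rate_hz"))
  t_axis <- as.numeric(rhdf5::h5read(path, "t_ms"))
  channels <- as.character(rhdf5::h5read(path, "channels"))
  contents <- rhdf5::h5ls(path)
  subjects <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
  out <- list()
  for (s in subjects) {
    trials <- contents$name[contents$group == paste0("/", s)]
    out[[s]] <- list()
    for (tr in trials) {
      data <- rhdf5::h5read(path, paste0(s, "/", tr))
      rownames(data) <- channels
      out[[s]][[as.integer(sub("trial", "", tr))]] <-
        erp_epoch(data, rate = rate, t = t_axis)
    }
  }
  rhdf5::h5closeAll()
  out
}

#' Read and validate a YAML run configuration
#'
#' The configuration must provide a `seed` and may override generator
#' parameters (`generator:`), cohort layout (`cohort: n_per_group`,
#' `n_blocks`), model outcomes (`models: outcomes`) and power settings
#' (`power:`). Units are embedded in field names (ms, mm, uV, Hz) to prevent
#' unit drift. The structure round-trips read -> write -> read identically.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A run-configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed))
    stop("run config must set `seed` before any compute", call. = FALSE)
  defaults <- list(
    cohort = list(n_per_group = c(ASD = 4, CON = 4, MHC = 4), n_blocks = 4L),
    generator = list(),
    models = list(outcomes = c("sepr", "bps", "mmn_amp", "p3a_amp")),
    power = NULL,
    stages = c("simulate", "preprocess", "models")
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config$cohort$n_per_group <- unlist(config$cohort$n_per_group)
  unknown <- setdiff(names(config$generator),
                     names(generator_params()))
  if (length(unknown))
    stop("unknown generator parameter(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(config, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  config <- unclass(config)
  # yaml drops names of atomic vectors; maps survive as lists
  if (!is.null(config$cohort$n_per_group))
    config$cohort$n_per_group <- as.list(config$cohort$n_per_group)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> preprocess/extract -> fit-models (and optionally the
#' power simulation) and writes all artifacts plus a JSON manifest of seeds,
#' package version and file hashes to `out_dir`. Any stage failure halts
#' with the stage name; a partial manifest is still written.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("oddpupil")),
    seed = config$seed, stages = list(), files = list()
  )
  log_counts <- list()
  finish <- function() {
    manifest$files <- manifest_hashes(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }
  run_stage <- function(name, expr) {
    value <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      finish()
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <- "ok"
    value
  }

  params <- do.call(generator_params, config$generator)
  table <- NULL
  if ("simulate" %in% config$stages || "preprocess" %in% config$stages) {
    cohort <- run_stage("simulate", simulate_cohort(
      params, n_per_group = config$cohort$n_per_group,
      seed = config$seed, n_blocks = config$cohort$n_blocks))
    run_stage("write-samples", {
      write_samples(cohort_pupil_samples(cohort),
                    file.path(out_dir, "pupil_samples.tsv"))
      sched <- do.call(rbind, lapply(cohort, function(r)
        cbind(subject_id = r$subject_id, r$schedule$trials)))
      data.table::fwrite(sched, file.path(out_dir, "schedule.tsv"), sep = "\t")
    })
  }
  if ("preprocess" %in% config$stages) {
    table <- run_stage("preprocess", cohort_trial_table(cohort))
    log_counts$trials_total <- nrow(table)
    log_counts$pupil_included_pct <- round(100 * mean(table$pupil_included), 1)
    log_counts$eeg_included_pct <- round(100 * mean(table$eeg_included), 1)
    data.table::fwrite(table, file.path(out_dir, "trial_features.csv"))
  }
  if ("models" %in% config$stages && !is.null(table)) {
    run_stage("models", {
      rows <- list(); r2s <- list(); cons <- list()
      for (oc in config$models$outcomes) {
        res <- fit_lmm(table, oc)
        rows[[oc]] <- cbind(outcome = oc, res$fixed)
        r2s[[oc]] <- data.frame(outcome = oc, mR2 = res$r2[["mR2"]],
                                cR2 = res$r2[["cR2"]])
        for (fac in c("stimulus", "manipulation")) {
          frame <- model.frame(res$fit)
          if (!fac %in% names(frame) || nlevels(frame[[fac]]) < 2L) next
          lv <- rev(levels(frame[[fac]]))[1:2]
          mc <- marginal_contrast(res, fac, lv)
          cons[[paste(oc, fac)]] <- data.frame(
            outcome = oc, factor = fac,
            contrast = paste(lv, collapse = " - "), delta = mc$delta,
            se = mc$se, ci_lower = mc$ci95[1], ci_upper = mc$ci95[2])
        }
      }
      data.table::fwrite(do.call(rbind, rows),
                         file.path(out_dir, "model_fixed_effects.csv"))
      data.table::fwrite(do.call(rbind, r2s),
                         file.path(out_dir, "model_r2.csv"))
      if (length(cons))
        data.table::fwrite(do.call(rbind, cons),
                           file.path(out_dir, "model_contrasts.csv"))
    })
  }
  if (!is.null(config$power)) {
    run_stage("power", {
      pc <- do.call(power_config,
                    modifyList(list(seed = config$seed), config$power))
      pr <- simulate_power(pc)
      jsonlite::write_json(
        list(power_pct = 100 * pr$power, ci95_pct = 100 * pr$ci95,
             reps = pr$reps_used),
        file.path(out_dir, "power.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  manifest$log <- log_counts
  finish()
}

manifest_hashes <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  if (!length(files)) return(list())
  hashes <- tools::md5sum(file.path(out_dir, files))
  as.list(setNames(unname(hashes), files))
}
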