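#' Run the full survey-analysis pipeline
#'
#' Orchestrates validate -> weights -> matrices -> descriptives ->
#' regression from one configuration, writing tidy CSV artifacts, a run
#' log, and a JSON manifest with a content hash for every output file.
#' Runs are bit-reproducible under a fixed config and seed.
#'
#' The configuration is a list (or path to a YAML file) with elements:
#' \describe{
#'   \item{simulate}{named list of [generator_config()] arguments; mutually
#'     exclusive with `input`.}
#'   \item{input}{list with `participants`, `contacts`, `supplementary`
#'     CSV paths, optional `dialect` (YAML path), `population` (CSV with
#'     columns `stratum`, `band`, `N` on the 14-band matrix scheme) and
#'     `margins` (YAML: per-variable named target shares).}
#'   \item{seed}{integer; seeds the generator in simulate mode.}
#'   \item{out_dir}{output directory.}
#'   \item{stages}{character subset of `validate`, `weights`, `matrices`,
#'     `descriptives`, `regression` (default all). Stages that need
#'     weights are auto-disabled with a warning when `weights` is off.}
#' }
#'
#' @param config list or YAML path as described above.
#' @return invisibly, the manifest: a data frame of `file`, `md5`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("validate", "weights", "matrices",
                                 "descriptives", "regression")
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }

  if (!("weights" %in% stages)) {
    dependent <- intersect(stages, c("matrices", "descriptives",
                                     "regression"))
    if (length(dependent)) {
      warning("stage(s) ", paste(dependent, collapse = ", "),
              " need weights; auto-disabled", call. = FALSE)
      say("auto-disabled (no weights stage): ",
          paste(dependent, collapse = ", "))
      stages <- setdiff(stages, dependent)
    }
  }

  ## -- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(config$seed)) args$seed <- config$seed
    gen <- generate_survey(do.call(generator_config, args))
    survey <- gen$survey
    populations <- gen$ground_truth$populations
    margins <- gen$ground_truth$weights_target_margins
    say("simulated survey: ", nrow(survey$participants), " participants, ",
        nrow(survey$contacts), " diary contacts, seed ",
        gen$ground_truth$config$seed)
    write_survey(survey, out_dir, prefix = "simulated_")
    gt_long <- as.data.frame(as.table(gen$ground_truth$true_matrix),
                             stringsAsFactors = FALSE)
    names(gt_long) <- c("band_i", "band_j", "true_c")
    utils::write.csv(gt_long, file.path(out_dir, "ground_truth_matrix.csv"),
                     row.names = FALSE)
  } else if (!is.null(config$input)) {
    inp <- config$input
    dialect <- if (!is.null(inp$dialect)) read_dialect(inp$dialect)
               else default_dialect()
    survey <- load_survey(inp$participants, inp$contacts, inp$supplementary,
                          dialect)
    say("loaded survey: ", nrow(survey$participants), " participants, ",
        nrow(survey$contacts), " diary contacts")
    populations <- NULL
    if (!is.null(inp$population)) {
      ptab <- utils::read.csv(inp$population, stringsAsFactors = FALSE)
      scheme <- standard_scheme("matrix")
      populations <- lapply(split(ptab, ptab$stratum), function(d) {
        population_table(scheme, d$N[match(scheme$labels, d$band)],
                         d$stratum[1L])
      })
      if (!"all" %in% names(populations) &&
          all(c("urban", "rural") %in% names(populations))) {
        populations$all <- combine_populations(populations$urban,
                                               populations$rural)
      }
    }
    margins <- NULL
    if (!is.null(inp$margins)) {
      mg <- yaml::read_yaml(inp$margins)
      margins <- lapply(names(mg), function(v) {
        margin_spec(v, unlist(mg[[v]]))
      })
    }
  } else {
    stop("config needs either a simulate block or input paths",
         call. = FALSE)
  }

  ## -- stages -----------------------------------------------------------
  if ("validate" %in% stages) {
    design <- sampling_design(total_target =
                                config$total_target %||%
                                nrow(survey$participants))
    report <- validate_survey(survey, design)
    say("validate: ", nrow(report$errors), " errors, ",
        nrow(report$warnings), " warnings")
    findings <- rbind(
      cbind(severity = rep("error", nrow(report$errors)), report$errors),
      cbind(severity = rep("warning", nrow(report$warnings)),
            report$warnings))
    utils::write.csv(findings,
                     file.path(out_dir, "validation_findings.csv"),
                     row.names = FALSE)
    utils::write.csv(report$quota_table,
                     file.path(out_dir, "quota_table.csv"),
                     row.names = FALSE)
    if (nrow(report$errors)) {
      stop("validation failed with ", nrow(report$errors),
           " error(s); see ", file.path(out_dir, "validation_findings.csv"),
           call. = FALSE)
    }
  }

  weights <- NULL
  if ("weights" %in% stages) {
    if (is.null(margins)) {
      stop("weights stage needs margins (config input$margins or simulate ",
           "mode)", call. = FALSE)
    }
    weights <- rake_weights(survey, margins)
    say("weights: converged = ", weights$converged, ", iterations = ",
        weights$iterations_used, ", max margin error = ",
        format(weights$max_margin_error, digits = 3))
    utils::write.csv(data.frame(participant_id = names(weights$weights),
                                weight = unname(weights$weights)),
                     file.path(out_dir, "weights.csv"), row.names = FALSE)
  }

  if ("matrices" %in% stages) {
    if (is.null(populations)) {
      stop("matrices stage needs population tables", call. = FALSE)
    }
    long <- list()
    for (stratum in intersect(c("urban", "rural", "all"),
                              names(populations))) {
      mats <- setting_stratified_matrices(
        survey, weights, population = populations[[stratum]],
        stratum = stratum)
      long[[stratum]] <- matrices_to_long(mats, populations[[stratum]])
      for (nm in names(mats)) {
        utils::write.csv(mats[[nm]]$values,
                         file.path(out_dir, paste0("matrix_", stratum, "_",
                                                   nm, ".csv")))
      }
    }
    utils::write.csv(do.call(rbind, long),
                     file.path(out_dir, "matrices_long.csv"),
                     row.names = FALSE)
    say("matrices: ", length(long), " strata x ",
        length(SETTING_MATRIX_LABELS) + 1L, " settings")
  }

  if ("descriptives" %in% stages) {
    ps <- participant_summaries(survey)
    utils::write.csv(ps, file.path(out_dir, "participant_summaries.csv"),
                     row.names = FALSE)
    w <- if (is.null(weights)) rep(1, nrow(survey$participants))
         else weights$weights
    med <- weighted_quantile(ps$degree_total, w, c(0.25, 0.5, 0.75))
    say("descriptives: weighted median degree ", med[2L],
        " (IQR ", med[1L], "-", med[3L], ")")
    sp <- setting_proportions(survey, weights, groupby = "age_band")
    utils::write.csv(sp$proportions,
                     file.path(out_dir, "setting_proportions_age.csv"))
    spo <- setting_proportions(survey, weights)
    utils::write.csv(spo$proportions,
                     file.path(out_dir, "setting_proportions.csv"))
    dm <- distance_mobility_tables(survey, weights)
    utils::write.csv(dm$distance, file.path(out_dir, "distance.csv"),
                     row.names = FALSE)
    if (!is.null(dm$mobility)) {
      utils::write.csv(dm$mobility, file.path(out_dir, "mobility.csv"),
                       row.names = FALSE)
    }
    rc <- reporting_method_comparison(survey)
    if (rc$applicable) {
      utils::write.csv(data.frame(
        comparison = c("age_distribution", "physical_proportion"),
        statistic = c(rc$age_test$statistic, rc$physical_test$statistic),
        df = c(rc$age_test$df, rc$physical_test$df),
        p = c(rc$age_test$p, rc$physical_test$p)),
        file.path(out_dir, "reporting_comparison.csv"), row.names = FALSE)
    }
  }

  if ("regression" %in% stages) {
    for (resp in c("degree_total", "contact_hours")) {
      fit <- fit_nb_model(survey, weights, response = resp)
      tab <- nb_summary_table(fit)
      say("regression (", resp, "): dispersion ",
          format(fit$dispersion, digits = 4))
      utils::write.csv(tab, file.path(out_dir,
                                      paste0("regression_", resp, ".csv")),
                       row.names = FALSE)
    }
  }

  ## -- manifest ---------------------------------------------------------
  close(log_con)
  on.exit(NULL)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
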