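#' Pipeline run configuration
#'
#' Collects every tunable of the four analysis stages (hrv, dose, assemble,
#' fit) plus the paths and the mandatory seed. Can be loaded from a YAML
#' file with [read_pipeline_config()].
#'
#' @param study_dir Directory with `manifest.csv`, `rr/`, `exposure/`.
#' @param out_dir Output directory for stage results.
#' @param seed Integer seed controlling every stochastic stage.
#' @param cleaning [cleaning_rules()].
#' @param spectral [spectral_params()].
#' @param noise [noise_dose_params()].
#' @param sampler [sampler_config()] (its own seed field is overridden by
#'   `seed`).
#' @param suites Model suites to fit, subset of
#'   `c("pm25", "noise", "joint")`.
#' @param window_s,max_lags,min_beats Segmentation settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study_dir, out_dir, seed = 1L,
                            cleaning = cleaning_rules(),
                            spectral = spectral_params(),
                            noise = noise_dose_params(),
                            sampler = sampler_config(),
                            suites = c("pm25", "noise", "joint"),
                            window_s = 300, max_lags = 8L,
                            min_beats = 100L) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            all(suites %in% c("pm25", "noise", "joint")))
  sampler$seed <- as.integer(seed)
  structure(
    list(study_dir = study_dir, out_dir = out_dir, seed = as.integer(seed),
         cleaning = cleaning, spectral = spectral, noise = noise,
         sampler = sampler, suites = suites, window_s = window_s,
         max_lags = as.integer(max_lags), min_beats = as.integer(min_beats)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys `study_dir`, `out_dir`, `seed`, `suites` plus optional
#' nested blocks `cleaning`, `spectral`, `noise`, `sampler` whose entries
#' override the corresponding constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  pipeline_config(
    study_dir = cfg$study_dir, out_dir = cfg$out_dir,
    seed = cfg$seed %||% 1L,
    cleaning = build(cleaning_rules, cfg$cleaning),
    spectral = build(spectral_params, cfg$spectral),
    noise = build(noise_dose_params, cfg$noise),
    sampler = build(sampler_config, cfg$sampler),
    suites = cfg$suites %||% c("pm25", "noise", "joint"),
    window_s = cfg$window_s %||% 300,
    max_lags = cfg$max_lags %||% 8L,
    min_beats = cfg$min_beats %||% 100L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  # stable digest of the configuration: serialise to canonical JSON and
  # md5 the bytes
  drop <- c("study_dir", "out_dir")
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  plain <- strip(unclass(config)[setdiff(names(config), drop)])
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_csv <- function(df, path, hash) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stage_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Run the analysis pipeline
#'
#' Executes the stages in order `hrv` (per-segment HRV metrics from the RR
#' recordings) -> `dose` (cumulative doses per bout) -> `assemble` (paired
#' delta outcomes joined with doses and confounders, plus descriptive and
#' correlation reports) -> `fit` (Bayesian model suites). Each stage reads
#' only prior-stage outputs from `out_dir`, so a subset of stages can be
#' re-run. Every output CSV carries a `# config_hash:` header line; a
#' provenance JSON records the configuration hash, seed, package version
#' and per-stage row counts. A stage failure writes a `FAILED` marker file
#' and aborts downstream stages, retaining partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("hrv", "dose", "assemble", "fit")`, executed
#'   in canonical order.
#' @return Invisibly, a list with the paths of the written outputs and the
#'   provenance record.
#' @export
run_pipeline <- function(config,
                         stages = c("hrv", "dose", "assemble", "fit")) {
  stopifnot(inherits(config, "pipeline_config"))
  order <- c("hrv", "dose", "assemble", "fit")
  stages <- order[order %in% stages]
  stopifnot(length(stages) >= 1)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  counts <- list()
  current <- ""

  run <- function() {
    if ("hrv" %in% stages) {
      current <<- "hrv"
      man <- read_study_manifest(config$study_dir)
      metrics <- dplyr::bind_rows(lapply(seq_len(nrow(man)), function(i) {
        m <- man[i, ]
        series <- read_rr_csv(m$rr_file, participant = m$participant,
                              day = m$day, period = m$period, rest = m$rest)
        compute_hrv_table(series, rules = config$cleaning,
                          spec = config$spectral, window_s = config$window_s,
                          max_lags = config$max_lags,
                          min_beats = config$min_beats)
      }))
      write_stage_csv(metrics, file.path(out, "metrics.csv"), hash)
      counts$metrics <<- nrow(metrics)
    }
    if ("dose" %in% stages) {
      current <<- "dose"
      man <- read_study_manifest(config$study_dir)
      bouts <- dplyr::distinct(man, .data$participant, .data$day,
                               .data$period, .data$exposure_file,
                               .data$distance_km, .data$duration_h,
                               .data$mask)
      doses <- dplyr::bind_rows(lapply(seq_len(nrow(bouts)), function(i) {
        b <- bouts[i, ]
        log <- read_exposure_csv(b$exposure_file, participant = b$participant,
                                 day = b$day, period = b$period)
        dplyr::bind_cols(summarize_doses(log, config$noise),
                         b[c("distance_km", "duration_h", "mask")])
      }))
      write_stage_csv(doses, file.path(out, "doses.csv"), hash)
      counts$doses <<- nrow(doses)
    }
    if ("assemble" %in% stages) {
      current <<- "assemble"
      metrics <- read_stage_csv(file.path(out, "metrics.csv"))
      doses <- read_stage_csv(file.path(out, "doses.csv"))
      doses$mask <- as.logical(doses$mask)
      deltas <- pair_rest_periods(metrics)
      rows <- assemble_analysis_table(deltas, doses, doses)
      write_stage_csv(rows, file.path(out, "analysis.csv"), hash)
      write_stage_csv(descriptive_report(rows, OUTCOMES),
                      file.path(out, "descriptive_deltas.csv"), hash)
      write_stage_csv(
        descriptive_report(doses, c("distance_km", "duration_h", "cum_pm25",
                                    "cum_pm10", "noise_dose")),
        file.path(out, "descriptive_exposure.csv"), hash
      )
      corr <- correlation_report(rows, OUTCOMES)
      corr_df <- tibble::as_tibble(corr$r, rownames = "variable")
      write_stage_csv(corr_df, file.path(out, "correlations.csv"), hash)
      counts$analysis_rows <<- nrow(rows)
    }
    if ("fit" %in% stages) {
      current <<- "fit"
      rows <- read_stage_csv(file.path(out, "analysis.csv"))
      reports <- lapply(config$suites, function(s) {
        run_model_suite(rows, suite = s, config = config$sampler)$report
      })
      report <- dplyr::bind_rows(reports)
      write_stage_csv(report, file.path(out, "fit_report.csv"), hash)
      counts$fit_rows <<- nrow(report)
    }
  }

  tryCatch(run(), error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", current,
                       conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(e)
  })

  prov <- list(
    config_hash = unname(hash),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("velohrv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    row_counts = counts
  )
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = out, provenance = prov))
}

#' Generate and write a synthetic study (simulate stage)
#'
#' Thin wrapper around [gen_study()] that writes the study directory
#' consumed by [run_pipeline()].
#'
#' @inheritParams gen_study
#' @param study_dir Output directory.
#' @return The `velohrv_study`, invisibly.
#' @export
simulate_study <- function(study_dir, truth = study_truth(), seed = 1L,
                           n_participants = 4L, n_days = 5L,
                           dropout = 0.05, ectopy_rate = 0,
                           baseline = rr_gen_params()) {
  study <- gen_study(truth = truth, n_participants = n_participants,
                     n_days = n_days, baseline = baseline,
                     dropout = dropout, ectopy_rate = ectopy_rate,
                     seed = seed, out_dir = study_dir)
  invisible(study)
}
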