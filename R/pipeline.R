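# Pipeline orchestration: simulate -> analyze -> summarize, with a run
# manifest so a rerun under the same config and seed reproduces every
# output stream bit-for-bit.

#' Default synthetic cohort composition
#'
#' Per-type neuron counts of the recorded population the simulator emulates
#' (8 TL2, 5 TL3, 14 CL1a, 10 TB1, 8 CPU1, 4 CPU2), with the qualitative
#' response-class mix observed among them: most TL2 neurons tonically
#' inhibited by near-unpolarized light, a couple excited, one unresponsive;
#' one TL3 inhibited; and so on.
#'
#' @return named list `cell_type -> character vector of variants` (one
#'   element per neuron).
#' @export
default_cohort <- function() {
  list(
    TL2 = c(rep("inhibited-low-DoP", 5), rep("excited-low-DoP", 2),
            "no-change"),
    TL3 = c("inhibited-low-DoP", rep("no-change", 4)),
    CL1a = rep("phasic-onset", 14),
    TB1 = rep("no-rebound", 10),
    CPU1 = c(rep("no-change", 6), rep("inhibited-low-DoP", 2)),
    CPU2 = rep("default", 4))
}

# deterministic per-neuron substream: neuron i of a run seeded s draws from
# seed (s * 1009 + i) mod 2^31-1, so adding a neuron never perturbs the
# streams of existing ones
neuron_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
}

#' Simulate a cohort of recordings
#'
#' One recording per neuron, each from its cell-type preset (magnitudes
#' jittered per neuron) under the shared stimulus protocol.
#'
#' @param cohort named list `cell_type -> variants` (see
#'   [default_cohort()]).
#' @param protocol a [protocol_spec()].
#' @param seed integer run seed; each neuron gets a derived substream.
#' @param baseline baseline firing rate passed to the presets, spikes/s.
#' @return list of [recording()]s.
#' @export
simulate_cohort <- function(cohort = default_cohort(),
                            protocol = protocol_spec(), seed = 1,
                            baseline = 20) {
  recs <- list()
  i <- 0L
  for (ct in names(cohort)) {
    for (j in seq_along(cohort[[ct]])) {
      i <- i + 1L
      s <- neuron_seed(seed, i)
      model <- make_celltype_preset(ct, cohort[[ct]][j], seed = s,
                                    baseline = baseline)
      recs[[i]] <- simulate_recording(model, protocol, seed = s,
                                      neuron_id = sprintf("%s-%02d", ct, j),
                                      cell_type = ct)
    }
  }
  recs
}

# sham version of an epoch, shifted into the stimulus-free window that
# precedes its background window; NULL when no such window exists
sham_epoch <- function(rec, epoch, cfg) {
  if (!length(epoch$rotations)) return(NULL)
  starts <- vapply(epoch$rotations, `[[`, 0, "t_start")
  ends <- starts + vapply(epoch$rotations, rotation_duration, 0)
  shift <- (epoch$t_on - cfg$ba_window) - max(ends)
  offs <- vapply(rec$epochs, `[[`, 0, "t_off")
  prev_off <- offs[offs <= epoch$t_on + 1e-9]
  floor_t <- if (length(prev_off)) max(0, max(prev_off)) else 0
  if (min(starts) + shift < floor_t - 1e-9) return(NULL)
  rots <- lapply(epoch$rotations, function(rot)
    polarizer_rotation(rot$t_start + shift, rot$direction, rot$start_angle,
                       rot$speed, rot$sweep))
  stimulus_epoch(epoch$t_on + shift, epoch$t_off + shift, 0, rots,
                 label = paste0(epoch$label, "-sham"))
}

#' Analyze every epoch of one recording
#'
#' Runs [analyze_response()] on each stimulus epoch and, when
#' `cfg$control_source = "pre_stimulus"`, the sham-rotation no-stimulus
#' control on the window preceding each background window. Epochs that
#' violate the protocol (missing a rotation direction) are skipped and
#' reported, not fatal.
#'
#' @param rec a [recording()].
#' @param cfg an [analysis_config()].
#' @return list with `responses` (data frame, one row per epoch),
#'   `controls` (data frame of control metric values) and `skipped`
#'   (character log of skipped epochs/controls).
#' @export
analyze_recording <- function(rec, cfg = analysis_config()) {
  responses <- list()
  controls <- list()
  skipped <- character(0)
  for (ep in rec$epochs) {
    tr <- tryCatch(analyze_response(rec, ep, cfg),
                   polspike_protocol_error = function(e) e)
    if (inherits(tr, "condition")) {
      skipped <- c(skipped, sprintf("%s: %s", rec$spike_train$neuron_id,
                                    conditionMessage(tr)))
      next
    }
    responses[[length(responses) + 1L]] <- summary(tr)
    if (cfg$control_source == "pre_stimulus") {
      sham <- sham_epoch(rec, ep, cfg)
      if (is.null(sham)) {
        skipped <- c(skipped, sprintf("%s/%s: control skipped (no free window)",
                                      rec$spike_train$neuron_id, ep$label))
      } else {
        sb <- bin_response(rec, sham, cfg)
        if (sb$n_total == 0L) {
          skipped <- c(skipped, sprintf("%s/%s: control skipped (silent window)",
                                        rec$spike_train$neuron_id, ep$label))
        } else {
          cm <- axial_mean(sb$spike_angles)
          controls[[length(controls) + 1L]] <- data.frame(
            neuron_id = rec$spike_train$neuron_id,
            cell_type = rec$spike_train$cell_type,
            dop = ep$dop, r = cm$r, A = response_amplitude(sb),
            n_spikes = sb$n_total)
        }
      }
    }
  }
  resp_df <- if (length(responses)) do.call(rbind, responses) else NULL
  if (cfg$control_source == "lowest_dop" && !is.null(resp_df)) {
    low <- resp_df[resp_df$dop == min(resp_df$dop), , drop = FALSE]
    controls <- list(low[, c("neuron_id", "cell_type", "dop", "r", "A",
                             "n_spikes")])
  }
  list(responses = resp_df,
       controls = if (length(controls)) do.call(rbind, controls) else NULL,
       skipped = skipped)
}

#' Summarize pooled responses: regressions, tallies, thresholds
#'
#' Per cell type: regressions of A, r and mean rate on DoP (with the
#' Lilliefors-guided model selection), and the DoP threshold for reliable
#' AoP coding for metric r and metric A against the cell type's own
#' no-stimulus controls (pooled controls are used as a fallback when a type
#' has fewer than three).
#'
#' @param responses data frame of per-response rows.
#' @param controls data frame of control values with columns `cell_type`,
#'   `r`, `A`.
#' @param cfg an [analysis_config()].
#' @return list with `regressions` (data frame), `tally` (data frame) and
#'   `thresholds` (list of `threshold_result`s keyed `celltype.metric`).
#' @export
summarize_results <- function(responses, controls, cfg = analysis_config()) {
  stopifnot(is.data.frame(responses))
  types <- sort(unique(responses$cell_type))
  regs <- list()
  for (ct in types) for (v in c("A", "r", "mean_rate")) {
    rg <- fit_dop_regression(responses, v, ct, cfg)
    regs[[length(regs) + 1L]] <- data.frame(
      cell_type = ct, response_var = v,
      model_form = rg$model_form, slope = rg$slope,
      intercept = rg$intercept, r_squared = rg$r_squared,
      slope_p = rg$slope_p, resid_normal_p = rg$resid_normal_p,
      n_points = rg$n_points, n_neurons = length(rg$neurons_used))
  }
  thresholds <- list()
  if (!is.null(controls) && nrow(controls)) {
    for (ct in types) for (metric in c("r", "A")) {
      ctrl <- controls[[metric]][controls$cell_type == ct]
      pooled <- FALSE
      if (sum(is.finite(ctrl)) < 3L) { ctrl <- controls[[metric]]; pooled <- TRUE }
      th <- tryCatch(
        estimate_threshold(responses, ctrl, ct, metric, cfg),
        polspike_insufficient_controls = function(e) NULL)
      if (!is.null(th)) {
        th$pooled_controls <- pooled
        thresholds[[paste(ct, metric, sep = ".")]] <- th
      }
    }
  }
  list(regressions = do.call(rbind, regs),
       tally = significance_tally(responses, cfg),
       thresholds = thresholds)
}

# FNV-1a over the canonical JSON of the resolved configuration
config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

default_pipeline_config <- function() {
  list(seed = 1,
       simulate = list(cohort = default_cohort(), baseline = 20,
                       protocol = list()),
       input_dir = NULL,
       analysis = list())
}

#' Run the full pipeline: simulate (or load), analyze, summarize
#'
#' Executes the stages in order and writes every stage output plus a run
#' manifest to `out_dir`: `recordings/` (when simulating),
#' `responses.csv`, `controls.csv`, `regressions.csv`, `tally.csv`,
#' `thresholds.json`, `skipped.log` and `manifest.json`. Outputs are pure
#' functions of (inputs, config, seed); rerunning with the same manifest
#' reproduces them exactly.
#'
#' @param config a named list, or the path of a YAML/JSON file, with keys
#'   `seed`, `analysis` (fields of [analysis_config()]), and either
#'   `simulate` (`cohort`, `baseline`, `protocol` fields of
#'   [protocol_spec()]) or `input_dir` (directory of recordings on disk).
#'   Unknown keys are an error.
#' @param out_dir output directory, created if needed.
#' @param verbose print stage progress.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config)) config <- list()
  }
  defaults <- default_pipeline_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  cfgall <- defaults
  for (k in names(config)) {
    if (k == "simulate") {
      bad2 <- setdiff(names(config$simulate), names(defaults$simulate))
      if (length(bad2))
        stop(sprintf("unknown config key(s): simulate.%s",
                     paste(bad2, collapse = ", simulate.")))
      # sub-blocks replace the defaults wholesale (a user cohort is the
      # whole cohort, not a patch of the default one)
      for (k2 in names(config$simulate))
        cfgall$simulate[[k2]] <- config$simulate[[k2]]
    } else cfgall[[k]] <- config[[k]]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  cfg <- do.call(analysis_config, as.list(cfgall$analysis))

  if (!is.null(cfgall$input_dir)) {
    stems <- sub("_spikes\\.csv$", "",
                 list.files(cfgall$input_dir, pattern = "_spikes\\.csv$",
                            full.names = TRUE))
    say("loading %d recordings from %s", length(stems), cfgall$input_dir)
    recs <- lapply(stems, read_recording)
    inputs <- basename(stems)
  } else {
    sim <- cfgall$simulate
    protocol <- do.call(protocol_spec, as.list(sim$protocol))
    cohort <- sim$cohort
    say("simulating %d neurons (seed %d)",
        sum(lengths(cohort)), cfgall$seed)
    recs <- simulate_cohort(cohort, protocol, seed = cfgall$seed,
                            baseline = sim$baseline)
    rec_dir <- file.path(out_dir, "recordings")
    for (rec in recs)
      write_recording(rec, file.path(rec_dir, rec$spike_train$neuron_id))
    inputs <- vapply(recs, function(r) r$spike_train$neuron_id, "")
  }

  say("analyzing %d recordings", length(recs))
  stage1 <- lapply(recs, analyze_recording, cfg = cfg)
  responses <- do.call(rbind, lapply(stage1, `[[`, "responses"))
  controls <- do.call(rbind, lapply(stage1, `[[`, "controls"))
  skipped <- unlist(lapply(stage1, `[[`, "skipped"))

  say("summarizing %d responses", NROW(responses))
  summ <- summarize_results(responses, controls, cfg)

  utils::write.csv(responses, file.path(out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(controls, file.path(out_dir, "controls.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$regressions, file.path(out_dir, "regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$tally, file.path(out_dir, "tally.csv"),
                   row.names = FALSE)
  thr <- lapply(summ$thresholds, function(t)
    list(cell_type = t$cell_type, metric = t$metric,
         threshold_dop = t$threshold_dop, nostim_mean = t$nostim_mean,
         nostim_upper = t$nostim_upper, pooled_controls = t$pooled_controls,
         per_dop_pass = t$per_dop_pass))
  jsonlite::write_json(thr, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(skipped, file.path(out_dir, "skipped.log"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("polspike")),
    config = cfgall[setdiff(names(cfgall), "input_dir")],
    config_hash = config_hash(cfgall), seed = cfgall$seed,
    inputs = inputs,
    rows = list(responses = NROW(responses), controls = NROW(controls),
                regressions = NROW(summ$regressions),
                thresholds = length(summ$thresholds)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: outputs in %s", out_dir)
  invisible(manifest)
}
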