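#' Default pipeline configuration
#'
#' Stage toggles and parameters for [run_pipeline()].  Analysis parameters
#' default to the standard settings used throughout the package (fs 500 Hz,
#' 0.1-195 Hz band-pass with 50 Hz notches, -0.5..2 s epochs, ERSP 2-140 Hz,
#' cluster permutation at p < 0.01 with a > 500 pixel gate and 1000
#' permutations, 99.9% GC bounds from 1000 permutations, DCM on 2-45 Hz);
#' the demo problem sizes (trials, contacts, permutations, subjects) are
#' deliberately small so a full run completes in minutes.
#'
#' @param seed master seed.
#' @param out_dir output directory for artifacts and the report.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("dyadflow_run_")) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    stages = list(synth = TRUE, preprocess = TRUE, ersp = TRUE,
                  clusterstats = TRUE, association = TRUE, coherence = TRUE,
                  specgc = TRUE, dcm = TRUE),
    synth = list(n_trials_per_condition = 30, fs = 500, n_contacts = 8,
                 effect_band = c(13, 30), effect_window = c(1, 2),
                 effect_gain_db = 3),
    preprocess = list(z_thresh = 6, max_width_s = 0.25),
    ersp = list(freq_range = c(4, 45), window_s = 0.512, time_step = 0.02,
                freq_step = 1),
    clusterstats = list(n_perm = 500, alpha_sample = 0.01, min_size = 30),
    association = list(n_patients = 40, band = c(13, 30)),
    coherence = list(freq_range = c(4, 45), time_step = 0.02, freq_step = 1),
    specgc = list(m_max = 12, n_perm = 200, level = 0.999),
    dcm = list(band = c(2, 45), freq_step = 1, n_subjects = 4,
               generator_id = 2, max_iter = 32)
  ), class = "run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic dyadic LFP
#' data: generation, spike-trial rejection, ERSP with neutral subtraction,
#' cluster permutation statistics, power/rating association, time-varying
#' coherence, spectral Granger causality with permutation bounds, and DCM
#' with random-effects BMS.  Any stage failure aborts downstream stages and
#' yields a partial report.  Identical config + seed give identical artifact
#' hashes.
#'
#' @param config a [default_run_config()] (possibly modified) or a YAML file
#'   path with the same structure.
#' @return An object of class `run_report`: per-stage parameter echo,
#'   summaries, artifact hashes and warnings.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) {
    config <- utils::modifyList(default_run_config(), yaml::read_yaml(config))
    class(config) <- "run_config"
  }
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, started = format(Sys.time()),
                 stages = list())
  state <- new.env(parent = emptyenv())
  stage_defs <- list(
    synth = stage_synth, preprocess = stage_preprocess, ersp = stage_ersp,
    clusterstats = stage_clusterstats, association = stage_association,
    coherence = stage_coherence, specgc = stage_specgc, dcm = stage_dcm)
  for (nm in names(stage_defs)) {
    if (!isTRUE(config$stages[[nm]])) next
    res <- tryCatch(
      stage_defs[[nm]](config, state),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$artifact)) {
      path <- file.path(config$out_dir, paste0(nm, ".rds"))
      res$md5 <- as.character(save_artifact(res$artifact, path))
      res$artifact <- NULL
    }
    res$params <- config[[nm]]
    report$stages[[nm]] <- res
    if (!is.null(res$error)) {
      report$aborted_after <- nm
      break
    }
  }
  report$finished <- format(Sys.time())
  class(report) <- "run_report"
  jsonlite::write_json(
    report_to_json(report),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(format_report_md(report),
             file.path(config$out_dir, "report.md"))
  report
}

validate_run_config <- function(config) {
  errs <- character(0)
  if (!is.numeric(config$seed)) errs <- c(errs, "seed must be numeric")
  s <- config$synth
  if (s$n_trials_per_condition < 1) errs <- c(errs, "synth: n_trials >= 1")
  if (s$effect_band[2] >= s$fs / 2) errs <- c(errs, "synth: band beyond Nyquist")
  if (config$clusterstats$n_perm < 100)
    errs <- c(errs, "clusterstats: n_perm >= 100")
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

stage_synth <- function(config, state) {
  s <- config$synth
  pd <- paradigm_spec(n_trials_per_condition = s$n_trials_per_condition,
                      fs = s$fs)
  eff <- list(burst_effect("negative", s$effect_band, s$effect_window,
                           s$effect_gain_db))
  state$paradigm <- pd
  state$epochs <- simulate_ersp_dataset(pd, eff, n_channels = s$n_contacts,
                                        seed = derive_seed(config$seed, 1))
  state$var_epochs <- simulate_var(
    coupling_spec(matrix(c(0.4, 0.35, 0, 0.4), 2, 2)), pd,
    seed = derive_seed(config$seed, 2))
  list(summary = list(n_trials = dim(state$epochs$data)[1],
                      n_contacts = s$n_contacts),
       artifact = state$epochs)
}

stage_preprocess <- function(config, state) {
  p <- config$preprocess
  state$epochs <- reject_spike_trials(state$epochs, p$z_thresh, p$max_width_s)
  list(summary = list(kept = sum(state$epochs$kept),
                      rejected = sum(!state$epochs$kept)))
}

stage_ersp <- function(config, state) {
  e <- config$ersp
  maps <- list()
  for (ch in seq_len(dim(state$epochs$data)[2])) {
    m <- compute_ersp(state$epochs, ch, freq_range = e$freq_range,
                      window_s = e$window_s, time_step = e$time_step,
                      freq_step = e$freq_step)
    maps[[ch]] <- list(pos = subtract_neutral(m$positive, m$neutral),
                       neg = subtract_neutral(m$negative, m$neutral))
  }
  state$ersp_maps <- maps
  list(summary = list(n_maps = 2 * length(maps),
                      grid = dim(maps[[1]]$pos$values)),
       artifact = maps)
}

stage_clusterstats <- function(config, state) {
  cs <- config$clusterstats
  res <- paired_cluster_permutation(
    lapply(state$ersp_maps, `[[`, "neg"),
    lapply(state$ersp_maps, `[[`, "pos"),
    n_perm = cs$n_perm, alpha_sample = cs$alpha_sample,
    min_size = cs$min_size, seed = derive_seed(config$seed, 3))
  state$clusters <- res
  list(summary = list(
    n_clusters = length(res$clusters),
    top = if (length(res$clusters))
      list(p = res$clusters[[1]]$p_cluster,
           pixels = res$clusters[[1]]$pixel_count,
           mass = res$clusters[[1]]$mass) else NULL),
    artifact = res)
}

stage_association <- function(config, state) {
  a <- config$association
  tab <- simulate_association_study(a$n_patients, band = a$band,
                                    seed = derive_seed(config$seed, 4))
  tab$power_db <- tab$band_power_db
  res <- correlate_with_ratings(tab)
  state$association <- res
  list(summary = res[c("r", "p", "n")], artifact = tab)
}

stage_coherence <- function(config, state) {
  co <- config$coherence
  map <- time_varying_coherence(state$var_epochs, c(1, 2),
                                time_step = co$time_step,
                                freq_step = co$freq_step,
                                freq_range = co$freq_range)
  state$coherence <- map
  pk <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  list(summary = list(max_coherence = max(map$values),
                      at_hz = map$freqs[pk[1]]),
       artifact = map)
}

stage_specgc <- function(config, state) {
  g <- config$specgc
  sel <- select_order_aic(state$var_epochs, m_max = g$m_max)
  gc <- permutation_ci(state$var_epochs, order = sel$order,
                       n_perm = g$n_perm, level = g$level,
                       seed = derive_seed(config$seed, 5))
  state$gc <- gc
  list(summary = list(
    order = sel$order,
    sig_bins_xy = sum(gc$gc_xy > gc$ci_xy),
    sig_bins_yx = sum(gc$gc_yx > gc$ci_yx),
    peak_xy_hz = gc$freqs[which.max(gc$gc_xy)]),
    artifact = gc)
}

stage_dcm <- function(config, state) {
  d <- config$dcm
  rec <- model_recovery(d$generator_id, d$n_subjects,
                        seed = derive_seed(config$seed, 6),
                        band = d$band, freq_step = d$freq_step,
                        max_iter = d$max_iter)
  state$bms <- rec$bms
  list(summary = list(generator = d$generator_id, winner = rec$winner,
                      exceedance = rec$bms$exceedance),
       artifact = rec)
}

report_to_json <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

format_report_md <- function(report) {
  out <- c("# dyadflow pipeline report", "",
           paste0("seed: ", report$seed),
           paste0("started: ", report$started,
                  " | finished: ", report$finished), "")
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    out <- c(out, paste0("## ", nm))
    if (!is.null(st$error)) {
      out <- c(out, paste0("FAILED: ", st$error))
    } else {
      for (k in names(st$summary))
        out <- c(out, paste0("- ", k, ": ",
                             paste(format(unlist(st$summary[[k]])),
                                   collapse = " ")))
      if (!is.null(st$md5)) out <- c(out, paste0("- artifact md5: ", st$md5))
    }
    out <- c(out, "")
  }
  if (!is.null(report$aborted_after))
    out <- c(out, paste0("Aborted after stage: ", report$aborted_after))
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
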