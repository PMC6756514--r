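#' Default analysis parameters
#'
#' Named constants for every tunable the pipeline uses; any config value
#' overrides them per run.
#'
#' @return Named list of defaults: sLFO band 0.008-0.07 Hz, tracking step
#'   0.5 s, range 7 s (4 s with band up to 0.12 Hz for rBTT runs),
#'   correlation threshold 0.3, 30-s Kaiser (beta 4) window resampled to
#'   0.02 s, center half-width 2.5 s.
#' @export
slfo_defaults <- function() {
  list(band = c(0.008, 0.07), step_s = 0.5, range_s = 7,
       corr_threshold = 0.3, rbtt_range_s = 4, rbtt_band = c(0.008, 0.12),
       window_s = 30, kaiser_beta = 4, resample_dt = 0.02,
       center_halfwidth_s = 2.5, te1_ms = 11.2, te2_ms = 32.78)
}

.known_stages <- c("synth", "preprocess", "lagmap", "deperfusion",
                   "rbtt", "multiecho", "regions")

#' Run the analysis pipeline from a declarative config
#'
#' Executes the requested stages in order on a shared state, writing each
#' stage's outputs (NIfTI volumes and maps, tab-separated tables) to
#' `out_dir` together with a YAML log of every parameter actually used. The
#' run is a pure function of (inputs, config, seed): repeated runs produce
#' identical outputs.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Top-level keys: `stages` (character vector), `seed`, optional `input`
#'   (paths: `volume`, `volume_echo2`, `motion`, `events`, `te1_ms`,
#'   `te2_ms`) and per-stage parameter blocks (`synth`, `preprocess`,
#'   `lagmap`, `deperfusion`, `rbtt`, `multiecho`, `regions`) overriding
#'   [slfo_defaults()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the final pipeline state (volumes, lag structure,
#'   traces, and the parameter log).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages
  if (length(stages) == 0) stop("config error: empty stage list")
  bad <- setdiff(stages, .known_stages)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  def <- slfo_defaults()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  st <- list(log = list(seed = seed, stages = stages))
  path <- function(f) file.path(out_dir, f)
  prm <- function(stage, name, fallback) {
    v <- config[[stage]][[name]]
    if (is.null(v)) fallback else v
  }

  for (stage in stages) {
    switch(stage,
      synth = {
        args <- config$synth
        args$rng_seed <- if (is.null(args$rng_seed)) seed else args$rng_seed
        spec <- do.call(synth_spec, lapply(args, function(v)
          if (is.list(v)) unlist(v) else v))
        sim <- simulate_bold(spec)
        st$sim <- sim
        st$vol <- sim$volume
        st$motion <- sim$motion
        st$events <- sim$events
        if (spec$dual_echo) {
          st$me <- sim$me
          write_volume(sim$me$S1, path("bold_echo1.nii"))
          write_volume(sim$me$S2, path("bold_echo2.nii"))
        } else write_volume(sim$volume, path("bold.nii"))
        write_motion(sim$motion, path("motion.tsv"))
        if (!is.null(sim$events)) write_events(sim$events, path("events.tsv"))
        write_map(sim$truth$delay_field, path("truth_delay_field.nii"))
        utils::write.table(
          data.frame(time = frame_times(sim$volume), slfo = sim$truth$w,
                     vrel = sim$truth$vrel),
          path("truth_series.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
        st$log$synth <- list(rng_seed = spec$rng_seed, grid = spec$grid,
                             n_frames = spec$n_frames,
                             frame_interval_s = spec$frame_interval_s,
                             band = spec$band, dual_echo = spec$dual_echo)
      },
      preprocess = {
        st <- .stage_load_input(st, config)
        band <- prm("preprocess", "band", def$band)
        repair <- isTRUE(prm("preprocess", "repair", TRUE))
        motion24 <- isTRUE(prm("preprocess", "motion24", TRUE))
        if (repair) {
          rep <- detect_spikes(st$vol, st$motion)
          utils::write.table(rep, path("repair_report.tsv"), sep = "\t",
                             row.names = FALSE, quote = FALSE)
          st$vol <- repair_frames(st$vol, rep)
          st$log$preprocess$flagged_frames <- rep$frame
        }
        if (motion24 && !is.null(st$motion))
          st$vol <- regress_out(st$vol, motion_design(st$motion))
        write_volume(st$vol, path("preprocessed.nii"))
        st$log$preprocess$band <- band
        st$log$preprocess$motion24 <- motion24
      },
      lagmap = {
        st <- .stage_load_input(st, config)
        band <- prm("lagmap", "band", def$band)
        step <- prm("lagmap", "step_s", def$step_s)
        range_s <- prm("lagmap", "range_s", def$range_s)
        rthresh <- prm("lagmap", "corr_threshold", def$corr_threshold)
        st$vol_pct <- percent_change(st$vol)
        st$vol_bp <- bandpass(st$vol_pct, band[1], band[2])
        ls <- track_lags(st$vol_bp, rthresh, step, range_s)
        ls <- fill_holes(ls, st$vol_bp, rthresh)
        st$ls <- ls
        write_map(ls$lag_map, path("lag_map.nii"))
        memb <- array(NA_real_, dim(ls$lag_map))
        for (b in seq_along(ls$lags)) {
          idx <- which(ls$mask)[ls$bins[[b]]]
          memb[idx] <- b
        }
        write_map(memb, path("lag_bins.nii"))
        seeds <- data.frame(time = frame_times(st$vol), ls$seed_series,
                            check.names = FALSE)
        utils::write.table(seeds, path("seed_series.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        st$log$lagmap <- list(band = band, step_s = step, range_s = range_s,
                              corr_threshold = rthresh,
                              n_bins = length(ls$lags),
                              tracked = sum(!is.na(ls$lag_map)))
      },
      deperfusion = {
        if (is.null(st$ls)) stop("stage 'deperfusion' requires 'lagmap'")
        band <- prm("deperfusion", "band", def$band)
        st$vol_clean <- deperfusion(st$vol_pct, st$ls, band)
        write_volume(st$vol_clean, path("deperfusioned.nii"))
        st$log$deperfusion <- list(band = band)
      },
      rbtt = {
        st <- .stage_load_input(st, config)
        band <- prm("rbtt", "band", def$rbtt_band)
        range_s <- prm("rbtt", "range_s", def$rbtt_range_s)
        window_s <- prm("rbtt", "window_s", def$window_s)
        kb <- prm("rbtt", "kaiser_beta", def$kaiser_beta)
        rdt <- prm("rbtt", "resample_dt", def$resample_dt)
        if (is.null(st$vol_pct)) st$vol_pct <- percent_change(st$vol)
        vol_bp <- bandpass(st$vol_pct, band[1], band[2])
        ls4 <- track_lags(vol_bp, prm("rbtt", "corr_threshold",
                                      def$corr_threshold),
                          def$step_s, range_s)
        st$ls_rbtt <- ls4
        tr <- rbtt_trace(ls4, range_s = range_s, events = st$events,
                         window_s = window_s, kaiser_beta = kb,
                         resample_dt = rdt)
        st$rbtt <- tr
        utils::write.table(tr, path("rbtt_global.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        st$log$rbtt <- list(band = band, range_s = range_s,
                            window_s = window_s, kaiser_beta = kb,
                            resample_dt = rdt, n_pairs = nrow(attr(tr, "pairs")))
      },
      multiecho = {
        st <- .stage_load_input(st, config)
        if (is.null(st$me)) stop("stage 'multiecho' requires dual-echo input")
        df <- me_decompose(st$me)
        st$decay <- df
        write_volume(ts_volume(replace(df$t2s, is.na(df$t2s), NaN),
                               df$frame_interval_s, mask = df$mask),
                     path("t2s.nii"))
        write_volume(ts_volume(replace(df$s0, is.na(df$s0), NaN),
                               df$frame_interval_s, mask = df$mask),
                     path("s0.nii"))
        write_volume(ts_volume(df$valid + 0, df$frame_interval_s,
                               mask = df$mask), path("t2s_valid.nii"))
        st$log$multiecho <- list(te1_ms = st$me$te1_ms, te2_ms = st$me$te2_ms,
                                 invalid_samples = sum(!df$valid))
      },
      regions = {
        if (is.null(st$ls)) stop("stage 'regions' requires 'lagmap'")
        hw <- prm("regions", "center_halfwidth_s", def$center_halfwidth_s)
        rg <- partition_regions(st$ls, hw)
        st$regions <- rg
        for (nm in c("inlet", "center", "outlet"))
          write_map(rg[[nm]] + 0, path(paste0("region_", nm, ".nii")))
        rs <- regional_series(st$vol_pct, rg)
        utils::write.table(rs, path("regional_series.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        sm <- regional_summary(st$vol_pct, rg)
        utils::write.table(sm, path("regional_summary.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        st$log$regions <- list(center_halfwidth_s = hw)
      })
  }
  yaml::write_yaml(st$log, file.path(out_dir, "pipeline_log.yaml"))
  invisible(st)
}

# Load external inputs into the state if not already provided by `synth`.
.stage_load_input <- function(st, config) {
  if (!is.null(st$vol)) return(st)
  inp <- config$input
  if (is.null(inp$volume)) stop("no input volume: run 'synth' or set input$volume")
  st$vol <- read_volume(inp$volume)
  if (!is.null(inp$volume_echo2)) {
    def <- slfo_defaults()
    te1 <- if (is.null(inp$te1_ms)) def$te1_ms else inp$te1_ms
    te2 <- if (is.null(inp$te2_ms)) def$te2_ms else inp$te2_ms
    st$me <- me_pair(st$vol, read_volume(inp$volume_echo2), te1, te2)
    st$vol <- st$me$S2
  }
  if (!is.null(inp$motion)) st$motion <- read_motion(inp$motion)
  if (!is.null(inp$events)) st$events <- read_events(inp$events)
  st
}
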