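SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session container
#'
#' Persists a simulated (or assembled) session as a versioned plain-text
#' directory: `manifest.json` with the schema version, rates and channel
#' roles; `lfp.csv` with one column per channel; one `values` / `positions`
#' CSV pair per dendrite under `imaging/`; and the ground-truth sidecar
#' tables under `truth/` when available. Values are written with 15
#' significant digits, so a round trip is lossless to numerical noise.
#'
#' @param session list with `lfp`, `dendrites`, and optionally `truth`,
#'   `cfg` (as produced by [simulate_session()])
#' @param path directory to create
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "imaging"), showWarnings = FALSE)
  lfp <- session$lfp
  manifest <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    lfp_rate = lfp$rate, roles = lfp$roles, start_time = lfp$start_time,
    dendrite_ids = vapply(session$dendrites, function(d) d$dendrite_id, numeric(1)),
    imaging_rate = if (length(session$dendrites) > 0) session$dendrites[[1]]$frame_rate else NA,
    seed = session$cfg$seed %||% NA
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  lfp_dt <- data.table::as.data.table(lfp$data)
  data.table::setnames(lfp_dt, paste0("ch", seq_along(lfp$roles)))
  data.table::fwrite(lfp_dt, file.path(path, "lfp.csv"))
  for (d in session$dendrites) {
    base <- file.path(path, "imaging", sprintf("dendrite_%03d", d$dendrite_id))
    data.table::fwrite(data.table::as.data.table(d$values),
                       paste0(base, "_values.csv"), col.names = FALSE)
    data.table::fwrite(data.table::data.table(
      position_um = d$positions), paste0(base, "_positions.csv"))
    jsonlite::write_json(
      list(dendrite_id = d$dendrite_id, cell_id = d$cell_id,
           frame_rate = d$frame_rate, is_dff = d$is_dff),
      paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(session$truth)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    data.table::fwrite(session$truth$events, file.path(path, "truth", "events.csv"))
    data.table::fwrite(truth_table(session$truth),
                       file.path(path, "truth", "ground_truth.csv"))
  }
  invisible(path)
}

#' Read a session container
#'
#' @param path directory written by [write_session()]
#' @return list with `lfp`, `dendrites`, and `truth` (events table or
#'   `NULL`); errors on a missing `/lfp` payload or an unknown schema
#'   version
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("read_session: no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, SESSION_SCHEMA_VERSION)) {
    stop(sprintf("read_session: unknown schema version '%s' (expected '%s')",
                 manifest$schema_version, SESSION_SCHEMA_VERSION))
  }
  lfp <- NULL
  lfp_path <- file.path(path, "lfp.csv")
  if (file.exists(lfp_path)) {
    data <- as.matrix(data.table::fread(lfp_path))
    dimnames(data) <- NULL
    lfp <- list(data = data, rate = manifest$lfp_rate, roles = manifest$roles,
                start_time = manifest$start_time)
    class(lfp) <- "swr_lfp"
  } else if (!is.null(manifest$lfp_rate) && length(manifest$dendrite_ids) == 0) {
    stop("read_session: container has no /lfp payload (lfp.csv missing)")
  }
  dendrites <- lapply(manifest$dendrite_ids, function(id) {
    base <- file.path(path, "imaging", sprintf("dendrite_%03d", id))
    meta <- jsonlite::read_json(paste0(base, "_meta.json"), simplifyVector = TRUE)
    values <- as.matrix(data.table::fread(paste0(base, "_values.csv"),
                                          header = FALSE))
    dimnames(values) <- NULL
    img <- list(values = values,
                positions = data.table::fread(paste0(base, "_positions.csv"))$position_um,
                frame_rate = meta$frame_rate, dendrite_id = meta$dendrite_id,
                cell_id = meta$cell_id, is_dff = meta$is_dff,
                soma_trace = values[1, ])
    class(img) <- "swr_dendrite"
    img
  })
  truth_path <- file.path(path, "truth", "events.csv")
  truth <- if (file.exists(truth_path)) {
    as.data.frame(data.table::fread(truth_path))
  } else NULL
  list(lfp = lfp, dendrites = dendrites, truth = truth)
}

#' Run the full SPW-R / dendritic-spike analysis pipeline
#'
#' Executes, in order: session simulation (or loading), ripple detection,
#' calcium transient detection, coincidence matching and mode
#' classification, three-group event classification, spatial threshold /
#' hot-spot analysis, and doublet supralinearity. Every stage writes its
#' table under `out_dir` and contributes a section to the returned
#' report; re-running with an identical configuration reproduces
#' identical outputs. A stage failure aborts with the stage name; tables
#' already written are retained.
#'
#' @param config list (or path to a YAML file) with elements `simulate`
#'   (arguments to [sim_config()]), optional `stages` (character subset
#'   of simulate, ripples, transients, modes, groups, spatial,
#'   supralinearity), optional `input` (session directory to load instead
#'   of simulating), and `out_dir`
#' @return the run report (named list of stage sections), invisibly
#'   written as `report.json` under `out_dir`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  all_stages <- c("simulate", "ripples", "transients", "modes", "groups",
                  "spatial", "supralinearity")
  stages <- config$stages %||% all_stages
  out_dir <- config$out_dir %||% "swrdspike_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("run_pipeline: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  env <- new.env()

  run_stage("simulate", function() {
    if (!is.null(config$input)) {
      ses <- read_session(config$input)
      env$cfg <- do.call(sim_config, config$simulate %||% list())
      env$truth <- NULL
      env$lfp <- ses$lfp
      env$images_raw <- ses$dendrites
    } else {
      env$cfg <- do.call(sim_config, config$simulate %||% list())
      ses <- simulate_session(env$cfg)
      env$truth <- ses$truth
      env$lfp <- ses$lfp
      env$images_raw <- ses$dendrites
    }
    report$simulate <<- list(
      seed = env$cfg$seed, duration_s = env$cfg$duration,
      n_dendrites = length(env$images_raw),
      n_scheduled = if (!is.null(env$truth)) nrow(env$truth$events) else NA)
  })

  run_stage("ripples", function() {
    if (is.null(env$lfp)) stop("needs the simulate stage (no LFP present)")
    ev <- detect_ripples(env$lfp)
    env$ripples <- ev[!ev$rejected, , drop = FALSE]
    data.table::fwrite(ev, file.path(out_dir, "ripple_events.csv"))
    report$ripples <<- list(
      n_detected = nrow(ev), n_rejected = sum(ev$rejected),
      n_singlets = sum(ev$kind == "singlet" & !ev$rejected),
      n_doublets = sum(ev$kind == "doublet" & !ev$rejected),
      doublet_fraction = mean(ev$kind[!ev$rejected] == "doublet"))
  })

  run_stage("transients", function() {
    if (is.null(env$images_raw)) stop("needs the simulate stage (no imaging present)")
    env$images <- lapply(env$images_raw, function(img) {
      if (isTRUE(img$is_dff)) img else compute_dff(img)
    })
    resp <- do.call(rbind, lapply(env$images, detect_responses))
    resp$response_id <- seq_len(nrow(resp))
    env$responses <- resp
    data.table::fwrite(resp, file.path(out_dir, "ca_responses.csv"))
    report$transients <<- list(n_responses = nrow(resp))
  })

  run_stage("modes", function() {
    if (is.null(env$responses) || is.null(env$ripples)) {
      stop("needs the ripples and transients stages")
    }
    matched <- match_events(env$responses, env$ripples)
    matched <- classify_responses(matched, env$images)
    env$matched <- matched
    data.table::fwrite(
      matched[, c("response_id", "dendrite_id", "mode", "matched_event_id",
                  "jitter_ms", "slope", "distal_proximal_ratio")],
      file.path(out_dir, "dendritic_events.csv"))
    ratios <- activation_ratios(matched, nrow(env$ripples), length(env$images))
    env$ratios <- ratios
    report$modes <<- c(list(
      n_matched = sum(!is.na(matched$matched_event_id)),
      mean_jitter_ms = mean(matched$jitter_ms[matched$mode == "local_dspike"],
                            na.rm = TRUE)), ratios)
  })

  run_stage("groups", function() {
    if (is.null(env$ripples) || is.null(env$matched)) {
      stop("needs the ripples and modes stages")
    }
    feats <- build_event_features(env$ripples, env$matched)
    env$features <- feats
    usable <- feats[is.finite(feats$ca_area_dffs) & feats$ca_area_dffs > 0, ]
    if (nrow(usable) >= 20 && sum(usable$kind != "doublet") >= 20) {
      # the low/high boundary is fit on singlet areas; doublets are
      # already separated by the detector kind
      split <- two_gaussian_split(
        log(usable$ca_area_dffs[usable$kind != "doublet"]))
      km <- kmeans_two_step(usable)
      cons <- consensus_groups(usable, split, km)
      usable$group <- cons$group
      usable$six_param_score <- six_param_distance(usable)
      gs <- tryCatch(gap_statistic(log(usable$ca_area_dffs)),
                     error = function(e) NULL)
      data.table::fwrite(usable, file.path(out_dir, "event_groups.csv"))
      report$groups <<- list(
        n_events = nrow(usable),
        counts = as.list(table(usable$group)),
        histogram_boundary = split$boundary,
        kmeans_agreement = cons$agreement,
        gap_p_equal_var = if (!is.null(gs)) gs$p_equal_var else NA,
        gap_p_welch = if (!is.null(gs)) gs$p_welch else NA)
      env$groups <- usable
    } else {
      report$groups <<- list(n_events = nrow(usable),
                             note = "too few calcium-coupled events for grouping")
    }
  })

  run_stage("spatial", function() {
    if (is.null(env$matched)) stop("needs the modes stage")
    ds <- env$matched[env$matched$mode == "local_dspike", , drop = FALSE]
    rows <- list()
    hot_rows <- list()
    for (d in unique(ds$dendrite_id)) {
      img <- env$images[[d]]
      sub <- ds[ds$dendrite_id == d, , drop = FALSE]
      amps <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        per_position_amplitudes(img, sub[i, ])
      }))
      profile <- colMeans(amps)
      est <- estimate_spatial_threshold(img$positions, profile)
      fit <- if (is.finite(est$threshold_um)) {
        proximal_linear_fit(img$positions, profile, est$threshold_um)
      } else NULL
      rows[[length(rows) + 1]] <- data.frame(
        dendrite_id = d, threshold_um = est$threshold_um, fit_method = est$method,
        proximal_slope = fit$slope %||% NA_real_,
        proximal_intercept = fit$intercept %||% NA_real_)
      for (i in seq_len(nrow(sub))) {
        hs <- detect_hotspots(img, sub[i, ])
        if (nrow(hs) == 0) next
        om <- onset_map(img, sub[i, ])
        for (j in seq_len(nrow(hs))) {
          ps <- propagation_stats(om, img$positions, hs$center_um[j])
          hot_rows[[length(hot_rows) + 1]] <- data.frame(
            dendrite_id = d, response_id = sub$response_id[i],
            center_um = hs$center_um[j], fwhm_um = hs$fwhm_um[j],
            lead_ms = ps$onset_lead_ms,
            v_centripetal = ps$speed_centripetal,
            v_centrifugal = ps$speed_centrifugal)
        }
      }
    }
    thr_tab <- if (length(rows) > 0) do.call(rbind, rows) else NULL
    hot_tab <- if (length(hot_rows) > 0) do.call(rbind, hot_rows) else NULL
    if (!is.null(thr_tab)) data.table::fwrite(thr_tab, file.path(out_dir, "spatial_thresholds.csv"))
    if (!is.null(hot_tab)) data.table::fwrite(hot_tab, file.path(out_dir, "hotspots.csv"))
    report$spatial <<- list(
      mean_threshold_um = if (!is.null(thr_tab)) mean(thr_tab$threshold_um, na.rm = TRUE) else NA,
      n_hotspots = if (!is.null(hot_tab)) nrow(hot_tab) else 0,
      mean_fwhm_um = if (!is.null(hot_tab)) mean(hot_tab$fwhm_um, na.rm = TRUE) else NA,
      mean_lead_ms = if (!is.null(hot_tab)) mean(hot_tab$lead_ms, na.rm = TRUE) else NA)
  })

  run_stage("supralinearity", function() {
    if (is.null(env$features)) stop("needs the groups stage")
    report$supralinearity <<- if (is.null(env$groups)) {
      list(note = "no group labels available (too few calcium-coupled events)")
    } else {
      summarize_supralinearity(env$groups, env$ripples, env$matched,
                               env$images, out_dir)
    }
  })

  report$config <- list(seed = env$cfg$seed %||% NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  report
}

#' Assemble per-event features for classification
#'
#' Joins the accepted ripple complexes with the calcium area of their
#' matched dendritic responses (the largest-area response when several
#' dendrites responded); events with no calcium response are kept with
#' `NA` area and excluded from clustering downstream.
#'
#' @param ripples accepted ripple event table
#' @param matched matched responses
#' @return data.frame of event features
#' @export
build_event_features <- function(ripples, matched) {
  ca <- rep(NA_real_, nrow(ripples))
  for (i in seq_len(nrow(ripples))) {
    sel <- which(matched$matched_event_id == ripples$event_id[i])
    if (length(sel) > 0) ca[i] <- max(matched$area_dffs[sel])
  }
  data.frame(event_id = ripples$event_id, kind = ripples$kind,
             duration_ms = ripples$duration_ms,
             peak_to_peak_uv = ripples$peak_to_peak_uv,
             area_uvs = ripples$area_uvs, power_uv2s = ripples$power_uv2s,
             frequency_hz = ripples$frequency_hz, ca_area_dffs = ca,
             stringsAsFactors = FALSE)
}

#' Doublet supralinearity summary over a session
#'
#' On the dendrite with the most matched dendritic spikes, extracts
#' ripple-aligned transients per group, forms the high+high and high+low
#' mathematical sums at the dataset's mean doublet delay (recomputed per
#' run, not hard-coded), computes the supralinearity ratios, per-doublet
#' gains by template subtraction, their temporal dependence, and regional
#' group statistics.
#'
#' @param groups event feature table with consensus `group` labels
#' @param ripples accepted ripple event table (for time zeros and doublet
#'   delays)
#' @param matched classified responses
#' @param images list of dF/F dendrite images
#' @param out_dir where per-doublet gains are written (`NULL` to skip)
#' @return named list of summary quantities
#' @export
summarize_supralinearity <- function(groups, ripples, matched, images,
                                     out_dir = NULL) {
  ds <- matched[matched$mode == "local_dspike" & !is.na(matched$matched_event_id), ]
  if (nrow(ds) == 0) return(list(note = "no dendritic spikes matched"))
  d <- as.integer(names(which.max(table(ds$dendrite_id))))
  img <- images[[d]]
  rate <- img$frame_rate
  ev_of_group <- function(g) {
    ids <- intersect(groups$event_id[groups$group == g],
                     ds$matched_event_id[ds$dendrite_id == d])
    ripples[match(ids, ripples$event_id), , drop = FALSE]
  }
  highs <- ev_of_group("high_ripple")
  lows <- ev_of_group("low_ripple")
  doublets <- ev_of_group("doublet")
  if (nrow(highs) < 2 || nrow(doublets) < 2) {
    return(list(note = "too few doublets or high-ripple events for summation"))
  }
  # align doublets at the first sub-event's own peak
  doublet_tz <- doublets$t1_s + (doublets$t2_s - doublets$t1_s) / 2
  delays_ms <- (doublets$t21_s - doublets$t1_s) * 1000
  mean_delay <- mean(delays_ms, na.rm = TRUE)

  avg_high <- group_average_transient(
    extract_aligned_transients(img, highs$t_zero_s)$traces)
  aligned_doublet <- extract_aligned_transients(img, doublet_tz)
  avg_doublet <- group_average_transient(aligned_doublet$traces)
  sum_hh <- math_sum(avg_high$mean, avg_high$mean, mean_delay, rate)
  r_hh <- supralinearity_ratio(avg_doublet$mean, sum_hh, rate)
  r_hl <- NULL
  if (nrow(lows) >= 2) {
    avg_low <- group_average_transient(
      extract_aligned_transients(img, lows$t_zero_s)$traces)
    sum_hl <- math_sum(avg_high$mean, avg_low$mean, mean_delay, rate)
    r_hl <- supralinearity_ratio(avg_doublet$mean, sum_hl, rate)
  }
  gains <- estimate_doublet_gains(aligned_doublet$traces, avg_high$mean, rate)
  td <- temporal_dependence(gains, delays_ms)
  if (!is.null(out_dir)) {
    data.table::fwrite(data.frame(event_id = doublets$event_id,
                                  delay_ms = delays_ms, gain = gains),
                       file.path(out_dir, "doublet_gains.csv"))
  }
  list(dendrite_id = d, n_doublets = nrow(doublets), n_high = nrow(highs),
       mean_delay_ms = mean_delay,
       ratio_high_high_pct = r_hh$ratio_percent %||% NA,
       gain_high_high = r_hh$gain %||% NA,
       ratio_high_low_pct = if (!is.null(r_hl)) r_hl$ratio_percent else NA,
       mean_doublet_gain = mean(gains, na.rm = TRUE),
       gain_rank_correlation = if (!is.null(td)) td$rank_correlation else NA)
}
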