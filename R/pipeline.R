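# Configuration-driven end-to-end runs. A run executes
# behavior -> (optional extraction from rendered video) -> classify ->
# tuning -> kinetics -> network, and writes per-neuron tables, ensemble
# counts and a machine-readable manifest.
#
# A single top-level seed fans out to per-module child seeds (see
# child_seed()): slot 1 = behavior, 2 = dF/F, 3 = video rendering,
# 4 = classification, so modules can be re-run in isolation reproducibly.

default_run_config <- function() {
  list(
    seed = 1L,
    simulation = list(),            # args to sim_config()
    input = list(dff_csv = NULL, session_dir = NULL),
    route = "direct",               # "direct" dF/F or "video" (render + ARS)
    extraction = list(alpha = 1, convention = "relative",
                      video_dim = c(128, 128), soma_radius = 4,
                      neuropil_gain = 1, noise_sd = 0.03),
    classify = list(k = 1000L, upper_pct = 99.17, lower_pct = 0.83,
                    social_events = c("mouse", "new", "old")),
    tuning = list(beta = 0.5),
    kinetics = list(cues = c("new", "old"), window_s = 4),
    network = list(method = "zhang")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' With no input files the run is synthetic: a session and dF/F matrix are
#' simulated from `config$simulation`; with `route = "video"` the dF/F matrix
#' is additionally rendered to a fluorescence video and re-extracted through
#' ARS before analysis. Alternatively `config$input$dff_csv` +
#' `config$input$session_dir` analyze existing data.
#'
#' @param config nested list (see `socens:::default_run_config()` for the
#'   shape and defaults) or path to a JSON/YAML file.
#' @param outdir output directory; created. `NULL` skips file output.
#' @return invisible list with all intermediate objects: `session`, `dff`,
#'   `labels`, `tuning`, `kinetics`, `network_social`, `network_nonsocial`,
#'   `ensemble_counts`, `manifest`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_run_config(), config)
  seed <- as.integer(cfg$seed)

  if (!is.null(cfg$input$dff_csv)) {
    if (!file.exists(cfg$input$dff_csv))
      stop("input file not found: ", cfg$input$dff_csv)
    dff <- read_dff_csv(cfg$input$dff_csv)
    session <- read_session_csv(cfg$input$session_dir)
    truth <- NULL
  } else {
    sim <- do.call(sim_config, c(cfg$simulation, list(seed = seed)))
    session <- simulate_behavior(sim, seed = child_seed(seed, 1))
    simd <- simulate_dff(sim, session, seed = seed)
    dff <- simd$dff
    truth <- simd$truth
    if (identical(cfg$route, "video")) {
      ex <- cfg$extraction
      layout <- soma_layout(nrow(dff$C), dim = ex$video_dim,
                            radius = ex$soma_radius, seed = seed)
      rv <- render_video(dff, layout, neuropil_gain = ex$neuropil_gain,
                         noise_sd = ex$noise_sd, seed = seed)
      rois <- roi_set(rv$masks, dim = ex$video_dim)
      dff <- video_to_dff(rv$video, rois, alpha = ex$alpha,
                          convention = ex$convention,
                          timestamps = dff$timestamps)
    }
  }

  b_social <- social_vector(session, cfg$classify$social_events)
  labels <- classify_neurons(dff, b_social, k = cfg$classify$k,
                             upper_pct = cfg$classify$upper_pct,
                             lower_pct = cfg$classify$lower_pct,
                             seed = child_seed(seed, 4))
  tun <- tuning_profile(dff, session, beta = cfg$tuning$beta)
  kin <- kinetics_table(dff, session, cues = cfg$kinetics$cues,
                        window_s = cfg$kinetics$window_s)
  net_soc <- state_network(dff, b_social, method = cfg$network$method)
  net_non <- state_network(dff, 1L - b_social, method = cfg$network$method)

  n <- nrow(dff$C)
  counts <- c(
    SAN = sum(labels$label == "SAN"), SIN = sum(labels$label == "SIN"),
    Other = sum(labels$label == "Other"),
    CageN = sum(tun$ean_cage), ON = sum(tun$ean_object),
    MN = sum(tun$ean_mouse), NewN = sum(tun$ean_new), OldN = sum(tun$ean_old),
    NewPN = sum(tun$preferred == "NewPN"),
    OldPN = sum(tun$preferred == "OldPN"))
  ratios <- data.frame(group = names(counts), count = as.integer(counts),
                       fraction = as.numeric(counts) / n)

  master <- cbind(labels, tun[, setdiff(names(tun), "neuron")])
  manifest <- list(package = "socens",
                   version = as.character(utils::packageVersion("socens")),
                   r_version = R.version.string,
                   seed = seed, config = cfg,
                   n_neurons = n, n_frames = ncol(dff$C),
                   timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(master, file.path(outdir, "neurons.csv"))
    data.table::fwrite(ratios, file.path(outdir, "ensemble_counts.csv"))
    data.table::fwrite(kin, file.path(outdir, "kinetics.csv"))
    write_session_csv(session, file.path(outdir, "session"))
    write_dff_csv(dff, file.path(outdir, "dff.csv"))
    data.table::fwrite(as.data.frame(net_soc$W),
                       file.path(outdir, "network_social.csv"))
    cfg_json <- file.path(outdir, "config.json")
    jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    manifest$config_md5 <- unname(tools::md5sum(cfg_json))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }

  invisible(list(session = session, dff = dff, truth = truth,
                 labels = labels, tuning = tun, kinetics = kin,
                 network_social = net_soc, network_nonsocial = net_non,
                 ensemble_counts = ratios, manifest = manifest))
}
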