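# FNV-1a hash of a deparsed R object; stable fingerprint for manifests
.config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default demonstration pipeline configuration
#'
#' A small synthetic world sized so the full pipeline (simulation, network,
#' space, similarity, dyadic fit) completes in minutes on one CPU.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
demo_config <- function(out_dir = tempfile("micetrans_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    world = list(n_mice = 25, grid_side = 10, n_loggers = 25, n_nights = 60,
                 n_asv = 120, n_genera = 12, detection_rate = 12,
                 samples_per_mouse = 1, balanced_phenotypes = TRUE),
    bandwidth = 1.5,
    min_detections = 10,
    mcmc = list(profile = "reduced"),
    run_importance = FALSE
  )
}

#' Run the full pipeline
#'
#' Executes simulate -> network -> space -> similarity -> dyadic fit (and
#' optionally leave-one-genus-out importance) from a single configuration,
#' writing stage outputs and a run manifest under \code{config$out_dir}.
#' Stage outputs are pure functions of (config, seed); rerunning with the
#' same configuration reproduces the same manifest hash.
#'
#' @param config a configuration list (see [demo_config()]), or the path of
#'   a JSON file containing one.
#' @return the run manifest (invisibly written to \code{manifest.json}).
#' @export
run_all <- function(config = demo_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  t_start <- Sys.time()
  stages <- list()
  log_stage <- function(name, t0, files, rows) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    stages[[name]] <<- list(outputs = files, rows = rows)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  t0 <- Sys.time()
  wc <- do.call(world_config, c(config$world, list(seed = config$seed)))
  world <- simulate_world(wc)
  det <- simulate_detections(world)
  mic <- simulate_microbiota(world)
  files <- write_world(world, det, mic, out)
  log_stage("simulate", t0, basename(files), nrow(det))

  t0 <- Sys.time()
  filt <- filter_detections(det)
  sri <- build_network(filt, quiet = TRUE)
  tl <- attr(sri, "tallies")
  write.csv(tl, file.path(out, "network.csv"), row.names = FALSE)
  log_stage("network", t0, "network.csv", nrow(tl))

  t0 <- Sys.time()
  grid <- ud_grid(wc$grid_side)
  uds <- estimate_uds(filt, world$loggers, grid,
                      bandwidth = config$bandwidth,
                      min_detections = config$min_detections)
  ov <- overlap_matrix(uds)
  profiles <- lapply(uds, function(u) {
    habitat_profile(core_range(u, 0.75), .habitat_survey_long(world))
  })
  hab <- habitat_similarity_matrix(profiles)
  write.csv(.long_pairs(ov, "overlap"), file.path(out, "overlap.csv"),
            row.names = FALSE)
  write.csv(.long_pairs(hab, "habitat_similarity"),
            file.path(out, "habitat_similarity.csv"), row.names = FALSE)
  log_stage("space", t0, c("overlap.csv", "habitat_similarity.csv"), nrow(ov))

  t0 <- Sys.time()
  resp <- similarity_matrix(mic$counts, "jaccard")
  dy <- build_dyads(mic$metadata, resp, sri, ov, hab)
  write.csv(dy, file.path(out, "dyads.csv"), row.names = FALSE)
  log_stage("similarity", t0, "dyads.csv", nrow(dy))

  t0 <- Sys.time()
  prof <- do.call(mcmc_profile, as.list(config$mcmc))
  spec <- dyadic_spec("beta", mcmc = prof, seed = config$seed)
  fit <- fit_dyadic(dy, spec)
  write.csv(fit$summary, file.path(out, "posterior_summary.csv"),
            row.names = FALSE)
  log_stage("fit", t0, "posterior_summary.csv", nrow(fit$summary))

  if (isTRUE(config$run_importance)) {
    t0 <- Sys.time()
    imp <- genus_importance(mic$counts, world$asvs$genus, mic$metadata,
                            sri, ov, hab, spec)
    write.csv(imp$records, file.path(out, "importance.csv"),
              row.names = FALSE)
    log_stage("importance", t0, "importance.csv", nrow(imp$records))
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL # path-independent fingerprint
  manifest <- list(
    config_hash = .config_hash(cfg_for_hash),
    seed = config$seed,
    version = as.character(utils::packageVersion("micetrans")),
    stages = stages,
    converged = fit$converged,
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 1)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# long-format habitat survey from a synthetic world's raster
.habitat_survey_long <- function(world) {
  do.call(rbind, lapply(.cover_types, function(t) {
    data.frame(cell_x = world$habitat$cell_x, cell_y = world$habitat$cell_y,
               cover_type = t, percent = world$habitat[[t]] * 100,
               stringsAsFactors = FALSE)
  }))
}

.long_pairs <- function(m, name) {
  ids <- rownames(m)
  cmb <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(id_a = ids[cmb[, 1L]], id_b = ids[cmb[, 2L]],
                    value = m[cmb], stringsAsFactors = FALSE)
  names(out)[3L] <- name
  out
}
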