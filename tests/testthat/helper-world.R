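# Shared fixtures built in code.

# A scripted detection table: rows of (mouse, logger, "YYYY-mm-dd HH:MM:SS")
script_detections <- function(...) {
  rows <- list(...)
  data.frame(
    tag_id = vapply(rows, `[[`, "", 1L),
    logger_id = vapply(rows, `[[`, "", 2L),
    timestamp = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# Random small detection scripts for oracle comparisons
random_script <- function(n_mice = 5, n_loggers = 3, n_nights = 8,
                          rate = 3, seed = 1) {
  set.seed(seed)
  out <- list()
  for (m in seq_len(n_mice)) {
    for (d in seq_len(n_nights)) {
      k <- rpois(1, rate)
      if (k == 0) next
      secs <- runif(k, 0, 16 * 3600 - 1)
      t0 <- as.POSIXct(sprintf("2019-03-%02d 16:00:00", d), tz = "UTC")
      out[[length(out) + 1L]] <- data.frame(
        tag_id = paste0("m", m),
        logger_id = paste0("L", sample(n_loggers, k, replace = TRUE)),
        timestamp = t0 + secs,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# Independent brute-force oracle: enumerate every night and classify it for
# every pair, straight from the tally definition.
oracle_network <- function(filtered, alive, window_h = 12,
                           mode = "any_logger") {
  ids <- sort(alive$id)
  nights <- seq(min(alive$first), max(alive$last), by = 1)
  n <- length(ids)
  mat <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- ids[i]; b <- ids[j]
      aw <- alive[alive$id == a, ]; bw <- alive[alive$id == b, ]
      x <- y_ab <- y_a <- y_b <- 0L
      for (nt in as.list(nights)) {
        if (nt < max(aw$first, bw$first) || nt > min(aw$last, bw$last)) next
        da <- filtered[filtered$tag_id == a & filtered$night == nt, ]
        db <- filtered[filtered$tag_id == b & filtered$night == nt, ]
        oa <- nrow(da) > 0; ob <- nrow(db) > 0
        if (!oa && !ob) next
        if (oa && !ob) { y_a <- y_a + 1L; next }
        if (!oa && ob) { y_b <- y_b + 1L; next }
        assoc <- FALSE; same_logger <- FALSE
        for (r in seq_len(nrow(da))) for (s in seq_len(nrow(db))) {
          if (da$logger_id[r] == db$logger_id[s]) {
            same_logger <- TRUE
            if (abs(da$tsec[r] - db$tsec[s]) <= window_h * 3600) assoc <- TRUE
          }
        }
        if (assoc) x <- x + 1L
        else if (mode == "any_logger" || same_logger) y_ab <- y_ab + 1L
      }
      mat[i, j] <- mat[j, i] <- adjusted_sri(x, y_ab, y_a, y_b)
    }
  }
  mat
}

# Small synthetic pipeline stack used by several files (cheap: ~2 s)
make_stack <- function(cfg) {
  w <- simulate_world(cfg)
  det <- simulate_detections(w)
  mic <- simulate_microbiota(w)
  filt <- filter_detections(det)
  sri <- build_network(filt, quiet = TRUE)
  grid <- ud_grid(cfg$grid_side)
  uds <- suppressMessages(estimate_uds(filt, w$loggers, grid, bandwidth = 1.5))
  ov <- overlap_matrix(uds)
  survey <- micetrans:::.habitat_survey_long(w)
  prof <- lapply(uds, function(u) habitat_profile(core_range(u), survey))
  hab <- habitat_similarity_matrix(prof)
  list(world = w, det = det, mic = mic, filt = filt, sri = sri,
       uds = uds, ov = ov, hab = hab, survey = survey)
}

tiny_cfg <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_mice = 18, grid_side = 8, n_loggers = 16, n_nights = 40,
         n_asv = 60, n_genera = 8, detection_rate = 8,
         samples_per_mouse = 1, balanced_phenotypes = TRUE, seed = seed),
    list(...))
  do.call(world_config, args)
}

quick_mcmc <- function() mcmc_profile("reduced", warmup = 150L, iter = 350L)
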