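#' Configuration of a synthetic study population
#'
#' Defaults emulate a 10-month RFID study of a wild wood-mouse population:
#' ~150 mice tracked at 60 fixed loggers over 300 nights on a 160 m square
#' grid (16 x 16 cells of 10 m), individualized microbiotas of ~180 ASVs
#' per sample drawn from a pool of 1,455 ASVs across 188 genera, and
#' route-specific transmission (social for strict anaerobes, spatial for
#' aerotolerant spore formers, with a habitat-filtered fraction).
#'
#' @param n_mice number of individuals.
#' @param grid_side study grid side length, in cells (1 cell = 10 m).
#' @param n_loggers number of fixed loggers placed on a regular sub-grid.
#' @param n_nights study length in nights.
#' @param n_asv,n_genera microbial pool sizes (\code{n_genera <= n_asv}).
#' @param route_effects named numeric \code{c(social=, spatial=, habitat=)}
#'   — non-negative transmission effect sizes (free parameters chosen for
#'   testability, not field estimates).
#' @param baseline_prevalence per-ASV baseline carriage probability p0.
#' @param detection_rate expected logger visits per mouse per night (only
#'   visits to an active logger are recorded).
#' @param logger_duty fraction of logger-nights a logger is recording
#'   (emulates rotating logger coverage of the study grid).
#' @param meeting_rate nightly social-meeting rate for a bonded pair with
#'   average sociability; meetings produce synchronized co-detections at a
#'   shared logger and are the social signal in the network.
#' @param sociability_sd log-scale spread of per-mouse sociability; a
#'   bonded pair's meeting rate scales with the product of sociabilities,
#'   so this controls how much network structure is independent of space.
#' @param social_range kernel scale of social affinity in a latent social
#'   space (units of one latent mouse-spacing). Mice are placed in a latent
#'   plane independent of geography; pairs close in it meet often and -
#'   crucially - share social partners, giving the network the transitive,
#'   non-modular structure real co-detection networks show, decorrelated
#'   from home-range overlap.
#' @param bond_range geographic gate (grid cells) on meetings: socially
#'   affine pairs can only meet if their ranges are within reach.
#' @param turnover per-sampling-occasion retention probability rho of a
#'   carried ASV.
#' @param samples_per_mouse sampling occasions per mouse.
#' @param habitat_filtered_frac fraction of ASVs whose baseline prevalence
#'   is filtered by a preferred ground-cover type.
#' @param full_span_frac fraction of mice alive for the whole study.
#' @param aero_prob,spore_prob per-genus phenotype probabilities.
#' @param route_scope \code{"all"} applies the route effect to every ASV
#'   through its assigned route; \code{"archetype_only"} applies effects
#'   only to the archetype phenotypes (social boost for strict-anaerobe
#'   non-spore-formers, spatial boost for aerotolerant spore formers),
#'   leaving mixed-phenotype ASVs at baseline prevalence — the cleanest
#'   route-separation world for validation studies.
#' @param balanced_phenotypes if TRUE, assign genera to the four
#'   aerotolerance x sporulation cells in strict rotation (guarantees every
#'   phenotype cell is occupied at small genus counts).
#' @param start_date Date of the first night.
#' @param seed master seed; stage-specific sub-streams are derived from it
#'   so changing microbiota parameters does not perturb detections.
#' @return validated list of class \code{world_config}.
#' @export
world_config <- function(n_mice = 150, grid_side = 16, n_loggers = 60,
                         n_nights = 300, n_asv = 1455, n_genera = 188,
                         route_effects = c(social = 4, spatial = 4, habitat = 1),
                         baseline_prevalence = 0.12, detection_rate = 0.2,
                         logger_duty = 0.25, turnover = 0.9,
                         samples_per_mouse = 2,
                         habitat_filtered_frac = 0.3, full_span_frac = 0.7,
                         aero_prob = 0.5, spore_prob = 0.5,
                         route_scope = c("all", "archetype_only"),
                         balanced_phenotypes = FALSE, meeting_rate = 0.5,
                         sociability_sd = 1, social_range = 1, bond_range = 3,
                         start_date = as.Date("2019-02-01"), seed = 1) {
  cfg <- list(n_mice = n_mice, grid_side = grid_side, n_loggers = n_loggers,
              n_nights = n_nights, n_asv = n_asv, n_genera = n_genera,
              route_effects = route_effects,
              baseline_prevalence = baseline_prevalence,
              detection_rate = detection_rate, logger_duty = logger_duty,
              turnover = turnover,
              samples_per_mouse = samples_per_mouse,
              habitat_filtered_frac = habitat_filtered_frac,
              full_span_frac = full_span_frac, aero_prob = aero_prob,
              spore_prob = spore_prob,
              balanced_phenotypes = balanced_phenotypes,
              route_scope = match.arg(route_scope),
              meeting_rate = meeting_rate, sociability_sd = sociability_sd,
              social_range = social_range, bond_range = bond_range,
              start_date = as.Date(start_date), seed = as.integer(seed))
  if (meeting_rate < 0 || sociability_sd < 0 || social_range <= 0 ||
      bond_range <= 0) {
    stop("invalid social-process parameters")
  }
  if (logger_duty <= 0 || logger_duty > 1) stop("logger_duty must be in (0, 1]")
  probs <- c(baseline_prevalence, turnover, habitat_filtered_frac,
             full_span_frac, aero_prob, spore_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_mice, grid_side, n_loggers, n_nights, n_asv, n_genera,
              samples_per_mouse)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (n_genera > n_asv) stop("n_genera must not exceed n_asv")
  if (any(route_effects < 0) ||
      !all(c("social", "spatial", "habitat") %in% names(route_effects))) {
    stop("route_effects must be non-negative and named social/spatial/habitat")
  }
  if (detection_rate < 0) stop("detection_rate must be non-negative")
  structure(cfg, class = "world_config")
}

# keyed sub-stream seed per simulation stage (kept below 2^31)
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 7919) %% 2147483647L)
}

.cover_types <- c("open_ground", "dogs_mercury", "bluebell", "bramble",
                  "grass", "sedge", "nightshade", "wild_garlic", "currant")

# closed-form Bhattacharyya coefficient of two isotropic bivariate normals
.bc_gauss <- function(dx, dy, s1, s2) {
  sg <- s1^2 + s2^2
  (2 * s1 * s2 / sg) * exp(-(dx^2 + dy^2) / (4 * sg))
}

#' Simulate a synthetic world
#'
#' Generates the roster (sex, age class, alive window, home-range centre
#' and scale), logger coordinates, a spatially smoothed habitat raster,
#' phenotype-labelled ASV annotations with route assignment (strict
#' anaerobe non-spore-formers transmit socially, aerotolerant spore formers
#' spatially, mixed phenotypes at random), and the generative ground-truth
#' association and overlap matrices. Deterministic for a fixed seed.
#'
#' @param config a [world_config()].
#' @return list of class \code{synthetic_world}.
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(.stage_seed(config$seed, 1L))
  n <- config$n_mice
  gs <- config$grid_side

  roster <- data.frame(
    id = sprintf("M%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_class = sample(c("adult", "juvenile"), n, replace = TRUE,
                       prob = c(0.7, 0.3)),
    centre_x = runif(n, 0, gs),
    centre_y = runif(n, 0, gs),
    range_scale = rlnorm(n, log(1.5), 0.3),
    sociability = rlnorm(n, -config$sociability_sd^2 / 2,
                         config$sociability_sd), # mean 1
    # latent social-space coordinates, independent of geography; scaled so
    # one unit is roughly one mouse-spacing at any population size
    social_x = runif(n, 0, sqrt(n)),
    social_y = runif(n, 0, sqrt(n)),
    stringsAsFactors = FALSE
  )
  full <- runif(n) < config$full_span_frac
  len <- ifelse(full, config$n_nights,
                pmax(1L, round(runif(n, 0.3, 0.9) * config$n_nights)))
  first <- ifelse(len >= config$n_nights, 1L,
                  1L + floor(runif(n) * (config$n_nights - len + 1)))
  roster$first_night <- as.integer(first)
  roster$last_night <- as.integer(pmin(first + len - 1, config$n_nights))

  # loggers on a regular sub-grid
  k <- ceiling(sqrt(config$n_loggers))
  sp <- gs / k
  coords <- expand.grid(x = (seq_len(k) - 0.5) * sp,
                        y = (seq_len(k) - 0.5) * sp)
  coords <- coords[seq_len(config$n_loggers), ]
  loggers <- data.frame(logger_id = sprintf("L%02d", seq_len(config$n_loggers)),
                        x = coords$x, y = coords$y,
                        stringsAsFactors = FALSE)

  # habitat raster: gamma random fields smoothed over space, normalized
  ncell <- gs * gs
  cells <- expand.grid(cell_x = seq_len(gs), cell_y = seq_len(gs))
  dmat <- as.matrix(stats::dist(cells))
  W <- exp(-dmat^2 / (2 * 2^2))
  fields <- sapply(.cover_types, function(t) {
    as.numeric(W %*% rgamma(ncell, shape = 1))
  })
  habitat <- fields / rowSums(fields)
  habitat_df <- data.frame(cells, habitat, check.names = FALSE)

  # genera and phenotypes
  ng <- config$n_genera
  gw <- rlnorm(ng, 0, 1.2)
  extra <- config$n_asv - ng
  sizes <- rep(1L, ng)
  if (extra > 0) {
    add <- as.integer(rmultinom(1L, extra, gw))
    sizes <- sizes + add
  }
  genus_names <- sprintf("g%03d", seq_len(ng))
  if (config$balanced_phenotypes) {
    cell <- (seq_len(ng) - 1L) %% 4L
    aero <- as.integer(cell %in% c(1L, 3L))
    spore <- as.integer(cell %in% c(2L, 3L))
  } else {
    aero <- rbinom(ng, 1L, config$aero_prob)
    spore <- rbinom(ng, 1L, config$spore_prob)
  }
  genera <- data.frame(genus = genus_names, aerotolerant = aero,
                       spore_forming = spore, n_asv = sizes,
                       stringsAsFactors = FALSE)

  asv_genus <- rep(genus_names, times = sizes)
  asv_aero <- rep(aero, times = sizes)
  asv_spore <- rep(spore, times = sizes)
  route <- ifelse(asv_aero == 0L & asv_spore == 0L, "social",
                  ifelse(asv_aero == 1L & asv_spore == 1L, "spatial", NA))
  nmix <- sum(is.na(route))
  if (nmix > 0) route[is.na(route)] <- sample(c("social", "spatial"), nmix,
                                              replace = TRUE)
  asvs <- data.frame(
    asv_id = sprintf("ASV%04d", seq_len(config$n_asv)),
    genus = asv_genus, aerotolerant = asv_aero, spore_forming = asv_spore,
    route = route,
    habitat_filtered = runif(config$n_asv) < config$habitat_filtered_frac,
    preferred_cover = sample(.cover_types, config$n_asv, replace = TRUE),
    seed_mouse = sample(roster$id, config$n_asv, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # generative ground-truth association and overlap
  dx <- outer(roster$centre_x, roster$centre_x, `-`)
  dy <- outer(roster$centre_y, roster$centre_y, `-`)
  s2 <- outer(roster$range_scale^2, roster$range_scale^2, `+`)
  ov <- .bc_gauss(dx, dy,
                  matrix(roster$range_scale, n, n),
                  matrix(roster$range_scale, n, n, byrow = TRUE))
  lam <- .meeting_rates(roster, config)
  K <- .logger_kernels(roster, loggers)
  co_ind <- config$detection_rate^2 * tcrossprod(K)
  duty <- config$logger_duty
  p_assoc <- 1 - exp(-duty * (lam + co_ind))
  p_obs <- 1 - exp(-duty * config$detection_rate)
  p_any <- 1 - (1 - p_obs)^2
  assoc <- pmin(p_assoc / p_any, 1)
  diag(assoc) <- 0; diag(ov) <- 1
  dimnames(assoc) <- dimnames(ov) <- list(roster$id, roster$id)

  structure(list(config = config, roster = roster, loggers = loggers,
                 habitat = habitat_df, genera = genera, asvs = asvs,
                 truth = list(association = assoc, overlap = ov)),
            class = "synthetic_world")
}

# pairwise nightly meeting rates: sociability products, closeness in the
# latent social plane, and a geographic reach gate
.meeting_rates <- function(roster, config) {
  dz2 <- outer(roster$social_x, roster$social_x, `-`)^2 +
    outer(roster$social_y, roster$social_y, `-`)^2
  dg2 <- outer(roster$centre_x, roster$centre_x, `-`)^2 +
    outer(roster$centre_y, roster$centre_y, `-`)^2
  lam <- config$meeting_rate *
    outer(roster$sociability, roster$sociability) *
    exp(-dz2 / (2 * config$social_range^2)) *
    exp(-dg2 / (2 * config$bond_range^2))
  diag(lam) <- 0
  lam
}

# per-mouse logger visit distribution: Gaussian kernel of distance from the
# home-range centre, normalized over loggers
.logger_kernels <- function(roster, loggers) {
  K <- matrix(0, nrow(roster), nrow(loggers),
              dimnames = list(roster$id, loggers$logger_id))
  for (i in seq_len(nrow(roster))) {
    d2 <- (loggers$x - roster$centre_x[i])^2 +
      (loggers$y - roster$centre_y[i])^2
    k <- exp(-d2 / (2 * roster$range_scale[i]^2))
    if (sum(k) == 0) k <- rep(1, length(k))
    K[i, ] <- k / sum(k)
  }
  K
}

#' Simulate logger detections from a synthetic world
#'
#' Each mouse-night emits a Poisson number of independent visits (mean
#' \code{detection_rate}) to loggers chosen with probability proportional
#' to a Gaussian kernel of distance from the mouse's home-range centre. On
#' top of this, socially affiliated pairs hold Poisson-distributed nightly
#' meetings (rate = meeting_rate x sociability product x range-proximity
#' gate) that produce a synchronized pair of detections at a shared logger
#' within 30 minutes. Loggers record on a duty cycle
#' (\code{logger_duty}); visits to inactive logger-nights are lost.
#' Timestamps are uniform within the nightly 16:00-08:00 activity window,
#' and only nights inside both mice's alive windows occur.
#'
#' @param world a [simulate_world()] result.
#' @return data.frame \code{tag_id, logger_id, timestamp} (POSIXct, UTC).
#' @export
simulate_detections <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  set.seed(.stage_seed(cfg$seed, 2L))
  roster <- world$roster
  n <- nrow(roster)
  nl <- nrow(world$loggers)
  K <- .logger_kernels(roster, world$loggers)
  # logger duty cycle: which logger-nights record at all
  active <- matrix(runif(nl * cfg$n_nights) < cfg$logger_duty,
                   nl, cfg$n_nights)
  out <- list()
  # independent foraging visits
  for (i in seq_len(n)) {
    m <- roster[i, ]
    nights <- m$first_night:m$last_night
    cnt <- rpois(length(nights), cfg$detection_rate)
    tot <- sum(cnt)
    if (tot == 0L) next
    nt <- rep(nights, cnt)
    lg <- sample.int(nl, tot, replace = TRUE, prob = K[i, ])
    keep <- active[cbind(lg, nt)]
    if (!any(keep)) next
    nt <- nt[keep]; lg <- lg[keep]
    t0 <- as.POSIXct(paste(cfg$start_date + nt - 1L, "16:00:00"), tz = "UTC")
    out[[length(out) + 1L]] <- data.frame(
      tag_id = m$id, logger_id = world$loggers$logger_id[lg],
      timestamp = t0 + runif(length(nt), 0, 16 * 3600 - 1801),
      stringsAsFactors = FALSE)
  }
  # social meetings: synchronized co-visits of affine pairs; detection_rate
  # of zero means recording is off entirely, so meetings are unrecorded too
  if (cfg$meeting_rate > 0 && cfg$detection_rate > 0 && n > 1L) {
    lam <- .meeting_rates(roster, cfg)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (lam[i, j] < 1e-8) next
        lo <- max(roster$first_night[i], roster$first_night[j])
        hi <- min(roster$last_night[i], roster$last_night[j])
        if (lo > hi) next
        tot <- rpois(1L, lam[i, j] * (hi - lo + 1))
        if (tot == 0L) next
        nt <- sample(lo:hi, tot, replace = TRUE)
        pk <- K[i, ] * K[j, ]
        if (sum(pk) == 0) next
        lg <- sample.int(nl, tot, replace = TRUE, prob = pk)
        keep <- active[cbind(lg, nt)]
        if (!any(keep)) next
        nt <- nt[keep]; lg <- lg[keep]
        t0 <- as.POSIXct(paste(cfg$start_date + nt - 1L, "16:00:00"),
                         tz = "UTC") + runif(length(nt), 0, 16 * 3600 - 1801)
        out[[length(out) + 1L]] <- data.frame(
          tag_id = rep(c(roster$id[i], roster$id[j]), each = length(nt)),
          logger_id = rep(world$loggers$logger_id[lg], 2L),
          timestamp = c(t0, t0 + runif(length(nt), 60, 1800)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(), logger_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  det <- do.call(rbind, out)
  rownames(det) <- NULL
  det[order(det$timestamp, det$tag_id), , drop = FALSE]
}

# habitat exposure weights: each mouse's share of each cover type,
# weighted by its true (Gaussian) utilization over grid cells
.habitat_exposure <- function(world) {
  gs <- world$config$grid_side
  cx <- world$habitat$cell_x - 0.5
  cy <- world$habitat$cell_y - 0.5
  hab <- as.matrix(world$habitat[, .cover_types])
  n <- nrow(world$roster)
  expo <- matrix(0, n, length(.cover_types),
                 dimnames = list(world$roster$id, .cover_types))
  for (i in seq_len(n)) {
    m <- world$roster[i, ]
    w <- exp(-((cx - m$centre_x)^2 + (cy - m$centre_y)^2) /
               (2 * m$range_scale^2))
    w <- w / sum(w)
    expo[i, ] <- as.numeric(t(hab) %*% w)
  }
  expo
}

#' Ground-truth per-mouse carriage probability of each ASV
#'
#' For a socially transmitted ASV seeded in mouse \code{s},
#' \code{P(i carries) = 1 - (1 - p0_i) * exp(-beta_soc * SRI(i, s))};
#' spatially transmitted ASVs use home-range overlap with the seed mouse.
#' For habitat-filtered ASVs the baseline is modulated by the mouse's
#' relative exposure to the ASV's preferred cover type:
#' \code{p0_i = p0 * w_i^beta_hab} with \code{w_i} rescaled to mean 1, so
#' \code{beta_hab = 0} disables the habitat route. The seed mouse is
#' treated as having association/overlap 1 with itself. Carriage
#' probability is therefore monotone non-decreasing in SRI and in overlap.
#'
#' @param world a [simulate_world()] result.
#' @param association,overlap matrices indexed by the roster ids (ground
#'   truth or estimates).
#' @return \code{n_mice x n_asv} probability matrix.
#' @export
presence_probability <- function(world, association = world$truth$association,
                                 overlap = world$truth$overlap) {
  cfg <- world$config
  ids <- world$roster$id
  if (!identical(rownames(association), ids) ||
      !identical(rownames(overlap), ids)) {
    stop("association/overlap matrices must be indexed by the world roster")
  }
  p0 <- cfg$baseline_prevalence
  bh <- cfg$route_effects[["habitat"]]
  expo <- .habitat_exposure(world)
  expo <- sweep(expo, 2L, colMeans(expo), `/`) # rescale each type to mean 1
  n <- length(ids); na <- nrow(world$asvs)
  P <- matrix(0, n, na, dimnames = list(ids, world$asvs$asv_id))
  archetype_only <- identical(cfg$route_scope, "archetype_only")
  for (a in seq_len(na)) {
    asv <- world$asvs[a, ]
    base <- rep(p0, n)
    if (asv$habitat_filtered && bh > 0) {
      base <- pmin(0.95, p0 * expo[, asv$preferred_cover]^bh)
    }
    beta <- cfg$route_effects[[if (asv$route == "social") "social" else "spatial"]]
    if (archetype_only &&
        asv$aerotolerant + asv$spore_forming == 1L) {
      beta <- 0 # mixed phenotype: baseline only in the archetype world
    }
    s <- asv$seed_mouse
    link <- if (asv$route == "social") association[, s] else overlap[, s]
    link[ids == s] <- 1
    P[, a] <- 1 - (1 - base) * exp(-beta * link)
  }
  P
}

#' Simulate microbiota count data from a synthetic world
#'
#' Colonization follows [presence_probability()] on the supplied
#' association and overlap matrices. Each mouse is sampled on
#' \code{samples_per_mouse} occasions spaced through its alive window;
#' between occasions a carried ASV is retained with probability
#' \code{turnover} (rho) and an absent ASV is newly acquired with
#' probability \code{(1 - rho) * p0_i}, so \code{rho = 1} freezes an
#' individual's presence set. Read counts are multinomial draws at a
#' log-normal depth over log-normal relative abundances of present ASVs.
#'
#' @inheritParams presence_probability
#' @return list with \code{counts} (samples x ASV integer matrix) and
#'   \code{metadata} (sample_id, individual, date, sex, age_class, plate,
#'   extraction_row, extraction_col, read_depth).
#' @export
simulate_microbiota <- function(world, association = world$truth$association,
                                overlap = world$truth$overlap) {
  cfg <- world$config
  P <- presence_probability(world, association, overlap)
  set.seed(.stage_seed(cfg$seed, 3L))
  rho <- cfg$turnover
  expo_used <- any(world$asvs$habitat_filtered) && cfg$route_effects[["habitat"]] > 0
  base <- matrix(cfg$baseline_prevalence, nrow(P), ncol(P))
  if (expo_used) {
    expo <- .habitat_exposure(world)
    expo <- sweep(expo, 2L, colMeans(expo), `/`)
    hf <- which(world$asvs$habitat_filtered)
    for (a in hf) {
      base[, a] <- pmin(0.95, cfg$baseline_prevalence *
                          expo[, world$asvs$preferred_cover[a]]^cfg$route_effects[["habitat"]])
    }
  }

  n <- nrow(world$roster)
  K <- cfg$samples_per_mouse
  counts <- list(); meta <- list()
  sidx <- 0L
  for (i in seq_len(n)) {
    m <- world$roster[i, ]
    pres <- runif(ncol(P)) < P[i, ]
    span <- m$last_night - m$first_night
    for (o in seq_len(K)) {
      if (o > 1L) {
        keep <- pres & (runif(ncol(P)) < rho)
        gain <- !pres & (runif(ncol(P)) < (1 - rho) * base[i, ])
        pres <- keep | gain
      }
      sidx <- sidx + 1L
      night <- m$first_night + round((o - 0.5) / K * span)
      depth <- round(min(5e5, max(5e3, rlnorm(1, log(48000), 0.6))))
      cvec <- integer(ncol(P))
      if (any(pres)) {
        rel <- rlnorm(sum(pres), 0, 1)
        cvec[pres] <- as.integer(rmultinom(1L, depth, rel / sum(rel)))
      }
      counts[[sidx]] <- cvec
      meta[[sidx]] <- data.frame(
        sample_id = sprintf("S%04d", sidx), individual = m$id,
        date = cfg$start_date + night - 1L, sex = m$sex,
        age_class = m$age_class, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts)
  metadata <- do.call(rbind, meta)
  rownames(counts) <- metadata$sample_id
  colnames(counts) <- world$asvs$asv_id
  # lab covariates: randomized extraction order over 96-well plates
  ord <- sample.int(nrow(metadata))
  pos <- order(ord)
  metadata$plate <- sprintf("P%02d", (pos - 1L) %/% 96L + 1L)
  within <- (pos - 1L) %% 96L
  metadata$extraction_row <- within %% 8L + 1L
  metadata$extraction_col <- within %/% 8L + 1L
  metadata$read_depth <- as.integer(rowSums(counts))
  list(counts = counts, metadata = metadata)
}

#' Write a synthetic world's data files to a directory
#'
#' Writes the detections CSV (\code{tag_id,logger_id,timestamp} ISO-8601),
#' counts TSV (samples x ASVs, integer), sample metadata TSV, genus
#' phenotype TSV, habitat CSV (long format,
#' \code{cell_x,cell_y,cover_type,percent}) and a ground-truth JSON.
#'
#' @param world a [simulate_world()] result.
#' @param detections a [simulate_detections()] result.
#' @param microbiota a [simulate_microbiota()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, detections, microbiota, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, c("detections.csv", "counts.tsv", "metadata.tsv",
                        "phenotypes.tsv", "habitat.csv", "truth.json"))
  det <- detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(det, f[1L], row.names = FALSE, quote = FALSE)
  write.table(data.frame(sample_id = rownames(microbiota$counts),
                         microbiota$counts, check.names = FALSE),
              f[2L], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(microbiota$metadata, f[3L], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(world$genera[, c("genus", "aerotolerant", "spore_forming")],
              f[4L], sep = "\t", row.names = FALSE, quote = FALSE)
  hab <- do.call(rbind, lapply(.cover_types, function(t) {
    data.frame(cell_x = world$habitat$cell_x, cell_y = world$habitat$cell_y,
               cover_type = t, percent = world$habitat[[t]] * 100)
  }))
  write.csv(hab, f[5L], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(association = world$truth$association, overlap = world$truth$overlap,
         asv_routes = world$asvs[, c("asv_id", "genus", "route")]),
    f[6L], digits = NA)
  invisible(f)
}
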