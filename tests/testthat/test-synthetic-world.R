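test_that("world_config validates its inputs", {
  expect_s3_class(world_config(), "world_config")
  expect_error(world_config(turnover = 1.5), "\\[0, 1\\]")
  expect_error(world_config(n_mice = 0), "counts")
  expect_error(world_config(n_genera = 50, n_asv = 10), "n_genera")
  expect_error(world_config(route_effects = c(social = -1, spatial = 1,
                                              habitat = 0)), "route_effects")
})

test_that("simulate_world is deterministic and respects bounds", {
  cfg <- tiny_cfg(seed = 7)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1, w2)
  w3 <- simulate_world(tiny_cfg(seed = 8))
  expect_false(identical(w1$roster, w3$roster))

  cfg2 <- world_config(n_mice = 2, grid_side = 4, n_loggers = 4,
                       n_nights = 10, n_asv = 10, n_genera = 3, seed = 1)
  w <- simulate_world(cfg2)
  expect_equal(nrow(w$roster), 2L)
  expect_true(all(w$roster$centre_x >= 0 & w$roster$centre_x <= 4))
  expect_true(all(w$roster$centre_y >= 0 & w$roster$centre_y <= 4))
  expect_true(all(w$roster$first_night >= 1 &
                    w$roster$last_night <= cfg2$n_nights))
})

test_that("phenotype-deterministic route assignment and habitat composition", {
  w <- simulate_world(tiny_cfg(seed = 2))
  an_nsf <- w$asvs$aerotolerant == 0 & w$asvs$spore_forming == 0
  ae_sf <- w$asvs$aerotolerant == 1 & w$asvs$spore_forming == 1
  expect_true(all(w$asvs$route[an_nsf] == "social"))
  expect_true(all(w$asvs$route[ae_sf] == "spatial"))
  expect_true(all(w$asvs$route %in% c("social", "spatial")))
  # habitat composition sums to 1 per cell
  comp <- as.matrix(w$habitat[, !(names(w$habitat) %in% c("cell_x", "cell_y"))])
  expect_equal(rowSums(comp), rep(1, nrow(comp)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # ground-truth matrices aligned to roster and within range
  expect_equal(rownames(w$truth$association), w$roster$id)
  expect_true(all(w$truth$overlap >= 0 & w$truth$overlap <= 1 + 1e-12))
})

test_that("simulate_detections: empty at rate 0, window and alive constraints", {
  cfg0 <- tiny_cfg(seed = 3, detection_rate = 0)
  w0 <- simulate_world(cfg0)
  expect_equal(nrow(simulate_detections(w0)), 0L)

  w <- simulate_world(tiny_cfg(seed = 3))
  det <- simulate_detections(w)
  hrs <- as.integer(format(det$timestamp, "%H", tz = "UTC"))
  expect_true(all(hrs >= 16 | hrs < 8))
  f <- filter_detections(det)
  night_idx <- as.integer(f$night - w$config$start_date) + 1L
  first <- setNames(w$roster$first_night, w$roster$id)
  last <- setNames(w$roster$last_night, w$roster$id)
  expect_true(all(night_idx >= first[f$tag_id] &
                    night_idx <= last[f$tag_id]))
})

test_that("co-located mice co-occur more than mice at opposite corners", {
  cfg <- world_config(n_mice = 4, grid_side = 10, n_loggers = 25,
                      n_nights = 200, n_asv = 8, n_genera = 2,
                      detection_rate = 6, full_span_frac = 1, seed = 5)
  w <- simulate_world(cfg)
  # script the geometry: mice 1,2 share a centre; mice 3,4 at opposite corners
  w$roster$centre_x <- c(5, 5, 0.5, 9.5)
  w$roster$centre_y <- c(5, 5, 0.5, 9.5)
  w$roster$range_scale <- rep(1.2, 4)
  w$roster$first_night <- 1L
  w$roster$last_night <- cfg$n_nights
  det <- simulate_detections(w)
  f <- filter_detections(det)
  co_freq <- function(a, b) {
    ta <- unique(f[f$tag_id == a, c("night", "logger_id")])
    tb <- unique(f[f$tag_id == b, c("night", "logger_id")])
    nrow(merge(ta, tb, by = c("night", "logger_id"))) /
      length(union(unique(ta$night), unique(tb$night)))
  }
  expect_gt(co_freq(w$roster$id[1], w$roster$id[2]),
            co_freq(w$roster$id[3], w$roster$id[4]))
})

test_that("presence probability is monotone in SRI and overlap", {
  w <- simulate_world(tiny_cfg(seed = 4))
  soc <- which(w$asvs$route == "social" & !w$asvs$habitat_filtered)[1L]
  spa <- which(w$asvs$route == "spatial" & !w$asvs$habitat_filtered)[1L]
  ids <- w$roster$id
  grid_vals <- seq(0, 1, by = 0.1)
  for (a_idx in c(soc, spa)) {
    seedm <- w$asvs$seed_mouse[a_idx]
    other <- setdiff(ids, seedm)[1L]
    probe <- function(v) {
      assoc <- w$truth$association
      ovl <- w$truth$overlap
      assoc[other, seedm] <- assoc[seedm, other] <- v
      ovl[other, seedm] <- ovl[seedm, other] <- v
      presence_probability(w, assoc, ovl)[other, a_idx]
    }
    pv <- vapply(grid_vals, probe, numeric(1))
    expect_true(all(diff(pv) >= -1e-12))
    expect_true(all(pv >= 0 & pv <= 1))
  }
})

test_that("simulate_microbiota: turnover freezes presence at rho = 1; counts are consistent", {
  cfg <- tiny_cfg(seed = 6, samples_per_mouse = 3, turnover = 1)
  w <- simulate_world(cfg)
  mic <- simulate_microbiota(w)
  pres <- mic$counts > 0
  for (id in unique(mic$metadata$individual)) {
    rows <- which(mic$metadata$individual == id)
    base <- pres[rows[1L], ]
    for (r in rows[-1L]) expect_identical(unname(pres[r, ]), unname(base))
  }
  expect_equal(unname(rowSums(mic$counts)),
               as.numeric(mic$metadata$read_depth))
  expect_true(all(mic$metadata$read_depth >= 5e3 &
                    mic$metadata$read_depth <= 5e5))
  # deterministic for fixed seed
  mic2 <- simulate_microbiota(simulate_world(cfg))
  expect_identical(mic, mic2)
  # dimension mismatch rejected
  expect_error(simulate_microbiota(w, w$truth$association[1:3, 1:3]),
               "roster")
})

test_that("null route effects leave Jaccard uncorrelated with SRI", {
  rs <- vapply(1:10, function(s) {
    cfg <- world_config(n_mice = 40, grid_side = 10, n_loggers = 25,
                        n_nights = 30, n_asv = 150, n_genera = 10,
                        detection_rate = 5, samples_per_mouse = 1,
                        route_effects = c(social = 0, spatial = 0, habitat = 0),
                        seed = 1000 + s)
    w <- simulate_world(cfg)
    mic <- simulate_microbiota(w)
    jac <- similarity_matrix(mic$counts, "jaccard")
    s2i <- setNames(mic$metadata$individual, mic$metadata$sample_id)
    lt <- which(lower.tri(jac), arr.ind = TRUE)
    sri_v <- w$truth$association[cbind(s2i[rownames(jac)[lt[, 1]]],
                                       s2i[rownames(jac)[lt[, 2]]])]
    cor(jac[lt], sri_v)
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.1)
})

test_that("strong social effect separates top- and bottom-decile SRI pairs on anaerobes", {
  cfg <- world_config(n_mice = 30, grid_side = 10, n_loggers = 25,
                      n_nights = 30, n_asv = 150, n_genera = 12,
                      detection_rate = 5, samples_per_mouse = 1,
                      balanced_phenotypes = TRUE,
                      route_effects = c(social = 5, spatial = 0, habitat = 0),
                      seed = 42)
  w <- simulate_world(cfg)
  mic <- simulate_microbiota(w)
  anaer <- w$asvs$aerotolerant == 0 & w$asvs$spore_forming == 0
  jac <- similarity_matrix(mic$counts[, anaer], "jaccard")
  s2i <- setNames(mic$metadata$individual, mic$metadata$sample_id)
  lt <- which(lower.tri(jac), arr.ind = TRUE)
  sri_v <- w$truth$association[cbind(s2i[rownames(jac)[lt[, 1]]],
                                     s2i[rownames(jac)[lt[, 2]]])]
  jv <- jac[lt]
  qs <- quantile(sri_v, c(0.1, 0.9))
  expect_gt(mean(jv[sri_v >= qs[2]]), mean(jv[sri_v <= qs[1]]))
})

test_that("write_world emits the documented plain-text files", {
  w <- simulate_world(tiny_cfg(seed = 9))
  det <- simulate_detections(w)
  mic <- simulate_microbiota(w)
  dir <- file.path(tempdir(), "mt_world")
  files <- write_world(w, det, mic, dir)
  expect_true(all(file.exists(files)))
  det2 <- read.csv(files[1L])
  expect_equal(names(det2), c("tag_id", "logger_id", "timestamp"))
  cnt <- read.delim(files[2L], check.names = FALSE)
  expect_equal(nrow(cnt), nrow(mic$counts))
  unlink(dir, recursive = TRUE)
})
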