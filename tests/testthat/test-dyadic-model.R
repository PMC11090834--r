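# metadata for k mice with one or two samples each
mk_metadata <- function(k, reps = 1) {
  n <- k * reps
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    individual = rep(sprintf("M%02d", seq_len(k)), each = reps),
    date = as.Date("2019-03-01") + seq_len(n),
    sex = rep(c("F", "M"), length.out = n),
    age_class = rep(c("adult", "juvenile"), length.out = n),
    plate = rep(c("P1", "P2"), length.out = n),
    extraction_row = ((seq_len(n) - 1) %% 8) + 1,
    extraction_col = ((seq_len(n) - 1) %/% 8) + 1,
    read_depth = 40000 + 100 * seq_len(n),
    stringsAsFactors = FALSE
  )
}

sym_named <- function(ids, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

test_that("build_dyads combinatorics and covariates", {
  md <- mk_metadata(3, reps = 1)
  md$individual <- c("A", "A", "B")  # A1, A2 (mouse A), B1 (mouse B)
  ids <- c("A", "B")
  resp <- sym_named(md$sample_id, 1)
  sri <- sym_named(ids, 2); ov <- sym_named(ids, 3); hab <- sym_named(ids, 4)
  d <- build_dyads(md, resp, sri, ov, hab)
  expect_equal(nrow(d), 2L) # A1-B1 and A2-B1 only
  expect_true(all(d$indiv_a != d$indiv_b))

  # k samples, one per each of k mice -> k(k-1)/2 rows
  md7 <- mk_metadata(7)
  resp7 <- sym_named(md7$sample_id, 5)
  m7 <- sym_named(sprintf("M%02d", 1:7), 6)
  d7 <- build_dyads(md7, resp7, m7, m7, m7)
  expect_equal(nrow(d7), choose(7, 2))

  r <- d7[d7$sample_a == "S001" & d7$sample_b == "S002", ]
  expect_equal(r$time_interval_days, 1)
  expect_equal(r$sex_similarity, 0L)
  expect_equal(r$sex_combo, "FM")
  expect_equal(r$extraction_distance, 1)
  expect_equal(r$read_depth_difference, 100)
  expect_equal(r$plate_similarity, 0L)
  expect_equal(r$response, resp7["S001", "S002"])
  expect_equal(r$sri, m7["M01", "M02"])

  # samples lacking predictors are dropped with a message
  md_bad <- md7
  md_bad$individual[7] <- "MXX"
  expect_message(db <- build_dyads(md_bad, resp7, m7, m7, m7), "dropping 1")
  expect_equal(nrow(db), choose(6, 2))
})

test_that("fit_dyadic recovers known slopes and covers the truth (small scale)", {
  set.seed(31)
  md <- mk_metadata(20)
  ids <- unique(md$individual)
  sri <- sym_named(ids, 7); ov <- sym_named(ids, 8); hab <- sym_named(ids, 9)
  d <- build_dyads(md, sym_named(md$sample_id, 10), sri, ov, hab)
  truth <- c(b0 = qlogis(0.3), sri = 0.9)
  eta <- truth["b0"] + truth["sri"] * d$sri +
    rnorm(length(ids), 0, 0.15)[match(d$indiv_a, ids)] +
    rnorm(length(ids), 0, 0.15)[match(d$indiv_b, ids)]
  phi <- 40
  mu <- plogis(eta)
  d$response <- pmin(1 - 1e-6, pmax(1e-6, rbeta(nrow(d), mu * phi, (1 - mu) * phi)))
  fit <- suppressMessages(
    fit_dyadic(d, dyadic_spec(covariates = character(), mcmc = quick_mcmc(),
                              seed = 100)))
  s <- fit$summary["b_sri", ]
  expect_gt(s$ci_high, s$ci_low)
  expect_true(s$ci_low < truth["sri"] && truth["sri"] < s$ci_high)
  expect_gt(s$ci_low, 0) # strong effect detected
  expect_true(all(c("b_intercept", "sd_individual", "phi") %in%
                    fit$summary$term))
})

test_that("beta likelihood rejects boundary responses unless transformed", {
  md <- mk_metadata(6)
  ids <- unique(md$individual)
  m <- sym_named(ids, 2)
  d <- build_dyads(md, sym_named(md$sample_id, 3), m, m, m)
  d$response[1] <- 0 # boundary: fit_dyadic must auto-transform
  fit <- suppressMessages(
    fit_dyadic(d, dyadic_spec(covariates = character(),
                              mcmc = mcmc_profile("reduced", warmup = 50L,
                                                  iter = 100L), seed = 1)))
  expect_s3_class(fit, "mt_fit")
  # internal fitter refuses raw boundary values
  expect_error(micetrans:::.fit_glmm(c(0, 0.5, 0.7), cbind(intercept = 1,
                                                           x = 1:3),
                                     list(), "beta"),
               "smithson_verkuilen")
})

test_that("all-identical responses do not crash and are flagged or degenerate", {
  md <- mk_metadata(8)
  ids <- unique(md$individual)
  m <- sym_named(ids, 2)
  resp <- sym_named(md$sample_id, 3)
  resp[] <- 0.3; diag(resp) <- 1
  d <- build_dyads(md, resp, m, m, m)
  fit <- suppressMessages(
    fit_dyadic(d, dyadic_spec(covariates = character(),
                              mcmc = mcmc_profile("reduced", warmup = 50L,
                                                  iter = 100L), seed = 2)))
  expect_s3_class(fit, "mt_fit")
  expect_true(is.finite(fit$summary["phi", "mean"]))
})

test_that("predict_expected closed forms", {
  expect_equal(predict_expected(c(intercept = 0)), 0.5)
  expect_equal(predict_expected(c(intercept = 1.2, sri = 0)), plogis(1.2))
  v <- predict_expected(c(intercept = qlogis(0.29), sri = 0.41), c(sri = 1))
  expect_equal(v, plogis(qlogis(0.29) + 0.41))
  expect_error(predict_expected(c(intercept = 0), c(nope = 1)), "unknown")
})

test_that("conditional_effect matches predict_expected on a one-point grid and tracks monotone truth", {
  set.seed(77)
  md <- mk_metadata(16)
  ids <- unique(md$individual)
  sri <- sym_named(ids, 4); ov <- sym_named(ids, 5); hab <- sym_named(ids, 6)
  d <- build_dyads(md, sym_named(md$sample_id, 7), sri, ov, hab)
  eta <- -1 + 1.5 * d$sri
  mu <- plogis(eta); phi <- 60
  d$response <- pmin(1 - 1e-6, pmax(1e-6, rbeta(nrow(d), mu * phi, (1 - mu) * phi)))
  fit <- suppressMessages(
    fit_dyadic(d, dyadic_spec(covariates = character(), mcmc = quick_mcmc(),
                              seed = 5)))
  ce <- conditional_effect(fit, "sri", seq(0, 1, by = 0.25))
  expect_true(all(diff(ce$mean) > 0)) # monotone positive truth
  expect_true(all(ce$ci_low <= ce$mean & ce$mean <= ce$ci_high))
  # one-point grid equals the draw-averaged expectation at that point
  pt <- conditional_effect(fit, "sri", 0.4)
  dr <- fit$draws
  xm <- fit$data_means; xm["sri"] <- 0.4
  mu_draws <- plogis(dr[, "b_intercept"] +
                       as.numeric(dr[, paste0("b_", names(xm))] %*% xm))
  expect_equal(pt$mean, mean(mu_draws), tolerance = 1e-9)
  expect_error(conditional_effect(fit, "nothere", 0.5), "unknown")
})

test_that("sex-combination interaction: derived slopes and empty-level error", {
  set.seed(41)
  md <- mk_metadata(18)
  ids <- unique(md$individual)
  sri <- sym_named(ids, 3); ov <- sym_named(ids, 4); hab <- sym_named(ids, 5)
  d <- build_dyads(md, sym_named(md$sample_id, 6), sri, ov, hab)
  # FF-only social effect
  eta <- -0.5 + ifelse(d$sex_combo == "FF", 2.2, 0) * d$sri
  mu <- plogis(eta); phi <- 60
  d$response <- pmin(1 - 1e-6, pmax(1e-6, rbeta(nrow(d), mu * phi, (1 - mu) * phi)))
  fit <- suppressMessages(
    fit_interaction(d, dyadic_spec(covariates = character(),
                                   mcmc = quick_mcmc(), seed = 9)))
  cs <- fit$category_slopes
  expect_setequal(cs$category, c("FF", "FM", "MM"))
  ff <- cs[cs$category == "FF", ]
  expect_gt(ff$ci_low, 0)

  d_noff <- d[d$sex_combo != "FF", ]
  expect_error(suppressMessages(
    fit_interaction(d_noff, dyadic_spec(covariates = character(), seed = 1))),
    "FF")
})

test_that("relabelling sample_a/sample_b leaves the posterior unchanged", {
  set.seed(55)
  md <- mk_metadata(12)
  ids <- unique(md$individual)
  d <- build_dyads(md, sym_named(md$sample_id, 3),
                   sym_named(ids, 21), sym_named(ids, 22), sym_named(ids, 23))
  mu <- plogis(-0.6 + 0.8 * d$sri)
  d$response <- pmin(1 - 1e-6,
                     pmax(1e-6, rbeta(nrow(d), mu * 40, (1 - mu) * 40)))
  spec <- dyadic_spec(covariates = character(), mcmc = quick_mcmc(), seed = 3)
  f1 <- suppressMessages(fit_dyadic(d, spec))
  d2 <- d
  d2[, c("sample_a", "sample_b")] <- d[, c("sample_b", "sample_a")]
  d2[, c("indiv_a", "indiv_b")] <- d[, c("indiv_b", "indiv_a")]
  f2 <- suppressMessages(fit_dyadic(d2, spec))
  # identical up to MCMC error (floating summation order differs, so the
  # chains are not bitwise-reproducible under the relabelling)
  fe <- grep("^b_", f1$summary$term, value = TRUE)
  expect_lt(max(abs(f1$summary[fe, "mean"] - f2$summary[fe, "mean"])), 0.1)
})
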