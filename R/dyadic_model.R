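.default_covariates <- c("age_similarity", "sex_similarity",
                         "time_interval_days", "extraction_distance",
                         "read_depth_difference", "plate_similarity")

#' Assemble the dyadic dataset
#'
#' One row per unordered pair of microbiota samples from two different
#' individuals. Predictors (social association, spatial overlap, habitat
#' similarity) are looked up at the individual level; covariates are
#' computed from the sample metadata: age-class similarity (same = 1), sex
#' similarity (same = 1) and sex combination (FF/FM/MM), absolute date
#' difference in days, Euclidean extraction-position distance, absolute
#' read-depth difference and same-plate indicator. Samples whose individual
#' is missing from any predictor matrix are dropped with a logged count.
#'
#' @param metadata data.frame with columns \code{sample_id, individual,
#'   date, sex, age_class, plate, extraction_row, extraction_col,
#'   read_depth}.
#' @param response symmetric sample-by-sample similarity matrix (row/col
#'   names = sample ids).
#' @param sri,overlap,habitat symmetric individual-by-individual predictor
#'   matrices.
#' @return data.frame of class \code{dyadic_data}.
#' @export
build_dyads <- function(metadata, response, sri, overlap, habitat) {
  need <- c("sample_id", "individual", "date", "sex", "age_class", "plate",
            "extraction_row", "extraction_col", "read_depth")
  stopifnot(all(need %in% names(metadata)))
  md <- metadata
  ok <- md$individual %in% rownames(sri) &
    md$individual %in% rownames(overlap) &
    md$individual %in% rownames(habitat) &
    md$sample_id %in% rownames(response)
  if (any(!ok)) {
    message(sprintf("dropping %d samples lacking individual-level predictors",
                    sum(!ok)))
    md <- md[ok, , drop = FALSE]
  }
  ns <- nrow(md)
  if (ns < 2L) stop("fewer than two usable samples")
  cmb <- combn(ns, 2L)
  i <- cmb[1L, ]; j <- cmb[2L, ]
  keep <- md$individual[i] != md$individual[j] # exclude self-comparisons
  i <- i[keep]; j <- j[keep]
  ia <- md$individual[i]; ib <- md$individual[j]
  d <- data.frame(
    sample_a = md$sample_id[i], sample_b = md$sample_id[j],
    indiv_a = ia, indiv_b = ib,
    response = response[cbind(md$sample_id[i], md$sample_id[j])],
    sri = sri[cbind(ia, ib)],
    spatial_overlap = overlap[cbind(ia, ib)],
    habitat_similarity = habitat[cbind(ia, ib)],
    age_similarity = as.integer(md$age_class[i] == md$age_class[j]),
    sex_similarity = as.integer(md$sex[i] == md$sex[j]),
    sex_combo = ifelse(md$sex[i] == "F" & md$sex[j] == "F", "FF",
                       ifelse(md$sex[i] == "M" & md$sex[j] == "M", "MM", "FM")),
    time_interval_days = abs(as.numeric(md$date[i] - md$date[j])),
    extraction_distance = sqrt((md$extraction_row[i] - md$extraction_row[j])^2 +
                                 (md$extraction_col[i] - md$extraction_col[j])^2),
    read_depth_difference = abs(md$read_depth[i] - md$read_depth[j]),
    plate_similarity = as.integer(md$plate[i] == md$plate[j]),
    stringsAsFactors = FALSE
  )
  class(d) <- c("dyadic_data", "data.frame")
  d
}

#' Specification of a dyadic mixed model
#'
#' @param likelihood \code{"beta"} (logit link; Jaccard or Bray-Curtis
#'   similarity responses), \code{"poisson"} (log link; shared-taxon
#'   counts) or \code{"gaussian"}.
#' @param predictors fixed-effect columns of the dyadic dataset.
#' @param covariates additional fixed-effect columns.
#' @param sex_interaction include a sex-combination (FF/FM/MM) by social
#'   association interaction.
#' @param mcmc an [mcmc_profile()].
#' @param seed integer seed for the sampler.
#' @return list of class \code{dyadic_spec}.
#' @export
dyadic_spec <- function(likelihood = c("beta", "poisson", "gaussian"),
                        predictors = c("sri", "spatial_overlap",
                                       "habitat_similarity"),
                        covariates = .default_covariates,
                        sex_interaction = FALSE,
                        mcmc = mcmc_profile("reduced"), seed = 1L) {
  likelihood <- match.arg(likelihood)
  structure(list(likelihood = likelihood, predictors = predictors,
                 covariates = covariates, sex_interaction = sex_interaction,
                 mcmc = mcmc, seed = as.integer(seed)),
            class = "dyadic_spec")
}

# membership block helper
.mm_block <- function(a, b, name) {
  lev <- sort(unique(c(a, b)))
  list(idx = cbind(match(a, lev), match(b, lev)) - 1L,
       q = length(lev), L = NULL, name = name, levels = lev, center = FALSE, cp = TRUE)
}

#' Fit a dyadic Bayesian GLMM with multi-membership random intercepts
#'
#' Linear predictor \code{eta = b0 + X beta + u[sample_a] + u[sample_b] +
#' v[indiv_a] + v[indiv_b]} with \code{u}, \code{v} zero-mean normal
#' random intercepts shared across both pair members. For the beta
#' likelihood \code{y ~ Beta(mu * phi, (1 - mu) * phi)} with
#' \code{mu = plogis(eta)}; boundary responses (exact 0/1) are shrunk with
#' [smithson_verkuilen()] over the dyad count. Sampling is by the built-in
#' Hamiltonian Monte Carlo sampler; the fit carries split-Rhat, bulk ESS
#' and divergence diagnostics, and \code{converged = FALSE} flags any fit
#' with Rhat >= 1.05, bulk ESS < 10\% of draws or more than 10 post-warmup
#' divergences.
#'
#' @param dyads a [build_dyads()] result (or compatible data.frame).
#' @param spec a [dyadic_spec()].
#' @return an object of class \code{mt_fit} (see [ci_width()],
#'   [predict_expected()], [conditional_effect()]).
#' @export
fit_dyadic <- function(dyads, spec = dyadic_spec()) {
  stopifnot(inherits(spec, "dyadic_spec"))
  y <- dyads$response
  if (spec$likelihood == "beta" && (any(y <= 0) || any(y >= 1))) {
    y <- smithson_verkuilen(y, nrow(dyads))
  }
  terms <- c(spec$predictors, spec$covariates)
  missing_t <- setdiff(terms, names(dyads))
  if (length(missing_t)) stop("dyadic data lacks columns: ",
                              paste(missing_t, collapse = ", "))
  X <- cbind(intercept = 1, as.matrix(dyads[, terms, drop = FALSE]))
  if (spec$sex_interaction) {
    lev <- c("FF", "FM", "MM")
    cnt <- table(factor(dyads$sex_combo, levels = lev))
    if (any(cnt == 0L)) {
      stop("sex combination level(s) with no dyads: ",
           paste(names(cnt)[cnt == 0L], collapse = ", "))
    }
    fm <- as.integer(dyads$sex_combo == "FM")
    mm <- as.integer(dyads$sex_combo == "MM")
    X <- cbind(X, sex_comboFM = fm, sex_comboMM = mm,
               `sri:sex_comboFM` = dyads$sri * fm,
               `sri:sex_comboMM` = dyads$sri * mm)
  }
  # with exactly one sample per individual the two membership structures
  # coincide; keep only the individual effect to avoid a non-identified split
  one_to_one <- !anyDuplicated(unique(data.frame(
    s = c(dyads$sample_a, dyads$sample_b),
    i = c(dyads$indiv_a, dyads$indiv_b)))$i)
  nest <- list()
  if (one_to_one) {
    message("one sample per individual: sample and individual random ",
            "effects coincide; fitting a single individual effect")
    blocks <- list(.mm_block(dyads$indiv_a, dyads$indiv_b, "individual"))
  } else {
    blocks <- list(.mm_block(dyads$sample_a, dyads$sample_b, "sample"),
                   .mm_block(dyads$indiv_a, dyads$indiv_b, "individual"))
    # sample -> individual map lets the sampler redraw the u/v split from
    # its exact conditional (the likelihood sees only their sum)
    s2i <- unique(data.frame(s = c(dyads$sample_a, dyads$sample_b),
                             i = c(dyads$indiv_a, dyads$indiv_b)))
    map <- match(s2i$i[match(blocks[[1L]]$levels, s2i$s)],
                 blocks[[2L]]$levels) - 1L
    nest <- list(child = 0L, parent = 1L, map = map)
  }
  fit <- .fit_glmm(y, X, blocks, spec$likelihood, spec$mcmc, spec$seed,
                   nest = nest)
  fit$spec <- spec
  dm <- colMeans(X)[-1L]
  fit$data_means <- dm[paste0("b_", names(dm)) %in% colnames(fit$draws)]
  if (spec$sex_interaction) {
    dr <- fit$draws
    slopes <- list(FF = dr[, "b_sri"],
                   FM = dr[, "b_sri"] + dr[, "b_sri:sex_comboFM"],
                   MM = dr[, "b_sri"] + dr[, "b_sri:sex_comboMM"])
    fit$category_slopes <- do.call(rbind, lapply(names(slopes), function(k) {
      x <- slopes[[k]]
      data.frame(category = k, mean = mean(x),
                 ci_low = unname(quantile(x, 0.025)),
                 ci_high = unname(quantile(x, 0.975)))
    }))
  }
  fit
}

#' Fit the sex-combination by social-association interaction model
#'
#' Convenience wrapper around [fit_dyadic()] with
#' \code{sex_interaction = TRUE}; the returned fit carries a
#' \code{category_slopes} table of the derived per-category social slopes
#' (FF, FM, MM) with 95\% CIs.
#'
#' @inheritParams fit_dyadic
#' @export
fit_interaction <- function(dyads, spec = dyadic_spec()) {
  spec$sex_interaction <- TRUE
  fit_dyadic(dyads, spec)
}

.coef_vector <- function(object) {
  if (inherits(object, "mt_fit")) {
    s <- object$summary[grep("^b_", object$summary$term), ]
    setNames(s$mean, sub("^b_", "", s$term))
  } else {
    nm <- sub("^b_", "", names(object))
    nm[nm %in% c("(Intercept)", "Intercept")] <- "intercept"
    setNames(as.numeric(object), nm)
  }
}

#' Expected response at given predictor values
#'
#' Computes \code{invlink(b0 + sum(beta_k * x_k))} with unspecified
#' predictors held at 0 (their reference values). For a beta fit the link
#' is the logit, so e.g. \code{predict_expected(c(intercept = qlogis(0.29),
#' sri = 0.41), c(sri = 1))} gives the expected similarity of a pair always
#' seen together.
#'
#' @param object an \code{mt_fit} or a named coefficient vector on the
#'   linear-predictor scale (name \code{intercept} for the intercept).
#' @param at named numeric vector of predictor values.
#' @param link \code{"logit"}, \code{"log"} or \code{"identity"}; taken
#'   from the fit's likelihood when available.
#' @return expected response (scalar).
#' @export
predict_expected <- function(object, at = numeric(), link = NULL) {
  cf <- .coef_vector(object)
  if (is.null(link)) {
    link <- if (inherits(object, "mt_fit")) {
      switch(object$likelihood, beta = "logit", poisson = "log", "identity")
    } else "logit"
  }
  eta <- if ("intercept" %in% names(cf)) cf[["intercept"]] else 0
  for (nm in names(at)) {
    if (!nm %in% names(cf)) stop("unknown predictor: ", nm)
    eta <- eta + cf[[nm]] * at[[nm]]
  }
  switch(link, logit = plogis(eta), log = exp(eta), identity = eta)
}

#' Conditional effect curve of one predictor
#'
#' Posterior mean and 95\% percentile band of the expected response over a
#' grid of one predictor, with all other fixed effects held at their sample
#' means and random effects at zero.
#'
#' @param fit an \code{mt_fit} from [fit_dyadic()].
#' @param predictor name of a fixed-effect column.
#' @param grid numeric vector of predictor values.
#' @return data.frame \code{value, mean, ci_low, ci_high}.
#' @export
conditional_effect <- function(fit, predictor, grid) {
  stopifnot(inherits(fit, "mt_fit"))
  if (!predictor %in% names(fit$data_means)) {
    stop("unknown predictor: ", predictor)
  }
  bn <- grep("^b_", colnames(fit$draws), value = TRUE)
  dr <- fit$draws[, bn, drop = FALSE]
  colnames(dr) <- sub("^b_", "", bn)
  xm <- fit$data_means
  invlink <- switch(fit$likelihood, beta = plogis, poisson = exp, identity)
  out <- lapply(grid, function(g) {
    xv <- xm
    xv[predictor] <- g
    eta <- dr[, "intercept"] + as.numeric(dr[, names(xv), drop = FALSE] %*% xv)
    mu <- invlink(eta)
    data.frame(value = g, mean = mean(mu),
               ci_low = unname(quantile(mu, 0.025)),
               ci_high = unname(quantile(mu, 0.975)))
  })
  do.call(rbind, out)
}
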