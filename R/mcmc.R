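#' MCMC run profiles
#'
#' The \code{"full"} profile mirrors a production run (4 chains, 1,000
#' warmup + 4,000 sampling iterations, target acceptance 0.98); the
#' \code{"reduced"} profile (2 chains, 300 + 700) is intended for tests and
#' simulation studies.
#'
#' @param profile \code{"reduced"} or \code{"full"}.
#' @param chains,warmup,iter,target_accept,max_steps,traj_len overrides.
#' @return list of class \code{mcmc_profile}.
#' @export
mcmc_profile <- function(profile = c("reduced", "full"), chains = NULL,
                         warmup = NULL, iter = NULL, target_accept = NULL,
                         max_steps = NULL, traj_len = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "full") {
    list(chains = 4L, warmup = 1000L, iter = 4000L, target_accept = 0.98,
         max_steps = 128L, traj_len = 2)
  } else {
    list(chains = 2L, warmup = 300L, iter = 700L, target_accept = 0.9,
         max_steps = 32L, traj_len = 2)
  }
  for (nm in names(def)) {
    v <- get(nm)
    if (!is.null(v)) def[[nm]] <- v
  }
  if (def$chains < 2L) stop("at least 2 chains are required for diagnostics")
  structure(def, class = "mcmc_profile")
}

# ---- convergence diagnostics (split-Rhat and bulk ESS on ----
# ---- rank-normalized draws, following standard practice)  ----

.rank_normalize <- function(x) {
  s <- length(x)
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (s + 1 / 4))
}

.split_chains <- function(draws, chain) {
  out <- list()
  for (c in unique(chain)) {
    x <- draws[chain == c]
    h <- floor(length(x) / 2)
    out[[length(out) + 1L]] <- x[seq_len(h)]
    out[[length(out) + 1L]] <- x[(h + 1L):(2L * h)]
  }
  do.call(cbind, out)
}

#' Split-Rhat for one parameter
#'
#' @param draws numeric vector of posterior draws.
#' @param chain integer chain index per draw.
#' @return potential scale reduction factor (rank-normalized, split chains);
#'   \code{NA} for constant draws.
#' @export
rhat <- function(draws, chain) {
  if (sd(draws) == 0) return(NA_real_)
  m <- .split_chains(.rank_normalize(draws), chain)
  n <- nrow(m)
  mu <- colMeans(m)
  B <- n * var(mu)
  W <- mean(apply(m, 2L, var))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size for one parameter
#'
#' Rank-normalized split-chain ESS with Geyer's initial monotone positive
#' sequence estimator of the autocorrelation time.
#'
#' @inheritParams rhat
#' @return effective sample size (capped at the number of draws).
#' @export
ess_bulk <- function(draws, chain) {
  if (sd(draws) == 0) return(NA_real_)
  m <- .split_chains(.rank_normalize(draws), chain)
  n <- nrow(m); nc <- ncol(m)
  acov <- apply(m, 2L, function(x) {
    a <- stats::acf(x, lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  W <- mean(apply(m, 2L, var))
  mu <- colMeans(m)
  B <- if (nc > 1L) n * var(mu) else 0
  var_plus <- W * (n - 1) / n + B / n
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- rho[1L]
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    p <- rho[t] + rho[t + 1L]
    if (p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
    t <- t + 2L
  }
  min(n * nc, n * nc / max(tau, 1e-12))
}

# ---- core fitting machinery -------------------------------------------

# Fit a GLMM by HMC. blocks: list of list(idx = n x m integer matrix of
# 0-based membership indices (-1 absent), q, L = optional lower Cholesky,
# name). Returns an object of class "mt_fit".
.fit_glmm <- function(y, X, blocks, likelihood = c("beta", "poisson", "gaussian"),
                      mcmc = mcmc_profile("reduced"), seed = 1L,
                      nest = list()) {
  likelihood <- match.arg(likelihood)
  lik <- match(likelihood, c("beta", "poisson", "gaussian")) - 1L
  if (likelihood == "beta" && (any(y <= 0) || any(y >= 1))) {
    stop("beta likelihood requires responses strictly inside (0, 1); ",
         "apply smithson_verkuilen() first")
  }
  if (likelihood == "poisson" && any(y < 0)) stop("poisson requires y >= 0")
  p <- ncol(X)
  has_int <- colnames(X)[1L] %in% c("(Intercept)", "intercept")
  # standardize columns for sampler health; draws are back-transformed so
  # reported coefficients (and the intercept) stay on the original scale
  X <- as.matrix(X)
  xscale <- apply(X, 2L, sd)
  const_col <- !is.finite(xscale) | xscale < 1e-12
  xscale[const_col] <- 1
  xcenter <- colMeans(X)
  dropped_terms <- character()
  if (has_int) {
    xscale[1L] <- 1
    xcenter[1L] <- 0
    if (any(const_col[-1L])) {
      dropped_terms <- colnames(X)[-1L][const_col[-1L]]
      message("dropping constant covariate(s): ",
              paste(dropped_terms, collapse = ", "))
      keep <- !(colnames(X) %in% dropped_terms)
      X <- X[, keep, drop = FALSE]
      xscale <- xscale[keep]
      xcenter <- xcenter[keep]
      p <- ncol(X)
    }
  } else {
    xcenter[] <- 0
  }
  X <- sweep(sweep(X, 2L, xcenter, `-`), 2L, xscale, `/`)
  B <- length(blocks)
  totq <- sum(vapply(blocks, function(b) as.integer(b$q), integer(1)))
  n_aux <- if (likelihood == "poisson") 0L else 1L
  P <- p + totq + B + n_aux

  set.seed(seed)
  inits <- matrix(rnorm(P * mcmc$chains, 0, 0.05), P, mcmc$chains)
  if (has_int) {
    b0 <- switch(likelihood,
                 beta = qlogis(mean(pmin(0.999, pmax(0.001, y)))),
                 poisson = log(mean(y) + 0.1),
                 gaussian = mean(y))
    inits[1L, ] <- inits[1L, ] + b0
  }
  if (n_aux == 1L) {
    aux0 <- if (likelihood == "beta") log(10) else log(max(sd(y), 1e-3))
    inits[P, ] <- inits[P, ] + aux0
  }
  if (B > 0L) {
    # log-sd params start small so effects begin near zero
    inits[p + totq + seq_len(B), ] <- inits[p + totq + seq_len(B), ] + log(0.3)
  }

  res <- .hmc_run(as.numeric(y), as.matrix(X), blocks, lik, has_int, inits,
                  mcmc$warmup, mcmc$iter, mcmc$target_accept, mcmc$max_steps,
                  mcmc$traj_len, nest)
  par_names <- c(
    paste0("b_", gsub("[()]", "", colnames(X))),
    unlist(lapply(blocks, function(b) paste0("z_", b$name, "[", seq_len(b$q), "]"))),
    if (B > 0L) paste0("sd_", vapply(blocks, function(b) b$name, character(1))),
    if (n_aux == 1L) {
      if (likelihood == "beta") "log_phi" else "log_sigma"
    }
  )
  draws <- res$draws
  colnames(draws) <- par_names
  draws[, seq_len(p)] <- sweep(draws[, seq_len(p), drop = FALSE], 2L,
                               xscale, `/`)
  if (has_int && p > 1L) {
    draws[, 1L] <- draws[, 1L] -
      draws[, 2:p, drop = FALSE] %*% xcenter[2:p]
  }
  # natural-scale sd / phi columns for reporting
  sd_cols <- grep("^sd_", par_names)
  draws[, sd_cols] <- exp(draws[, sd_cols])
  if (n_aux == 1L) {
    draws[, P] <- exp(draws[, P])
    colnames(draws)[P] <- if (likelihood == "beta") "phi" else "sigma"
  }
  chain <- res$chain

  report <- c(grep("^b_", colnames(draws), value = TRUE),
              colnames(draws)[sd_cols],
              if (n_aux == 1L) colnames(draws)[P])
  summ <- do.call(rbind, lapply(report, function(nm) {
    x <- draws[, nm]
    data.frame(term = nm, mean = mean(x),
               ci_low = unname(quantile(x, 0.025)),
               ci_high = unname(quantile(x, 0.975)),
               rhat = rhat(x, chain), ess_bulk = ess_bulk(x, chain),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- summ$term
  ndraws <- nrow(draws)
  div <- sum(res$divergences)
  rh <- summ$rhat[is.finite(summ$rhat)]
  es <- summ$ess_bulk[is.finite(summ$ess_bulk)]
  converged <- length(rh) > 0 && all(rh < 1.05) &&
    all(es >= 0.1 * ndraws) && div <= 10
  structure(list(draws = draws, chain = chain, summary = summ,
                 likelihood = likelihood,
                 diagnostics = list(divergences = div,
                                    div_nonfinite = sum(res$div_nonfinite),
                                    div_energy = sum(res$div_energy),
                                    max_rhat = if (length(rh)) max(rh) else NA,
                                    min_ess = if (length(es)) min(es) else NA,
                                    n_draws = ndraws,
                                    step_size = res$step_size,
                                    accept_stat = res$accept_stat),
                 converged = converged, mcmc = mcmc, seed = seed,
                 dropped_terms = dropped_terms),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s GLMM fit (HMC): %d draws, %d chains%s\n",
              x$likelihood, x$diagnostics$n_draws, length(unique(x$chain)),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  fe <- x$summary[grep("^b_|^sd_|^phi$|^sigma$", x$summary$term), ]
  print(format(fe, digits = 3), row.names = FALSE)
  invisible(x)
}

#' 95% credible-interval width of a coefficient
#'
#' @param fit an \code{mt_fit}.
#' @param term coefficient name (e.g. \code{"b_sri"}).
#' @return numeric CI width.
#' @export
ci_width <- function(fit, term) {
  s <- fit$summary[fit$summary$term == term, ]
  if (nrow(s) == 0L) stop("unknown term: ", term)
  s$ci_high - s$ci_low
}
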