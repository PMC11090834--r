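#' Raw leave-one-genus-out importance
#'
#' \code{((CIw_excl - CIw_incl) / CIw_incl) / sqrt(n_asv)}: the relative
#' increase in an effect's 95\% credible-interval width when the genus is
#' excluded, normalized by the square root of the number of ASVs the genus
#' contributes.
#'
#' @param ciw_incl,ciw_excl baseline and genus-excluded CI widths (> 0).
#' @param n_asv number of ASVs in the genus (>= 1).
#' @return numeric raw importance (vectorized).
#' @export
raw_importance <- function(ciw_incl, ciw_excl, n_asv) {
  if (any(ciw_incl <= 0) || any(ciw_excl <= 0)) stop("CI widths must be > 0")
  if (any(n_asv < 1)) stop("n_asv must be >= 1")
  ((ciw_excl - ciw_incl) / ciw_incl) / sqrt(n_asv)
}

.effect_terms <- c(social = "b_sri", spatial = "b_spatial_overlap",
                   habitat = "b_habitat_similarity")

.jaccard_dyads <- function(counts, metadata, sri, overlap, habitat,
                           keep = rep(TRUE, ncol(counts))) {
  resp <- similarity_matrix(counts[, keep, drop = FALSE], "jaccard")
  build_dyads(metadata, resp, sri, overlap, habitat)
}

#' Importance of one genus for the social, spatial and habitat effects
#'
#' Drops all ASVs of the genus, recomputes the Jaccard response over the
#' reduced ASV universe, refits the dyadic model with the identical
#' specification and seed, and returns the raw importance per effect.
#'
#' @param counts samples x ASV abundance matrix.
#' @param asv_genus genus label per ASV (column order of \code{counts}).
#' @param metadata,sri,overlap,habitat as in [build_dyads()].
#' @param baseline baseline \code{mt_fit} on the full Jaccard response.
#' @param genus genus to drop.
#' @param spec the [dyadic_spec()] used for the baseline fit.
#' @return data.frame with one row per effect: \code{genus, effect,
#'   ciw_incl, ciw_excl, n_asv, raw, converged}.
#' @export
loo_importance <- function(counts, asv_genus, metadata, sri, overlap, habitat,
                           baseline, genus, spec = dyadic_spec()) {
  stopifnot(length(asv_genus) == ncol(counts))
  drop <- asv_genus == genus
  if (!any(drop)) stop("genus not present in the table: ", genus)
  if (all(drop)) stop("cannot drop the entire community (genus = all ASVs)")
  dy <- .jaccard_dyads(counts, metadata, sri, overlap, habitat, keep = !drop)
  refit <- fit_dyadic(dy, spec)
  out <- lapply(names(.effect_terms), function(e) {
    term <- .effect_terms[[e]]
    data.frame(genus = genus, effect = e,
               ciw_incl = ci_width(baseline, term),
               ciw_excl = ci_width(refit, term),
               n_asv = sum(drop),
               raw = raw_importance(ci_width(baseline, term),
                                    ci_width(refit, term), sum(drop)),
               converged = refit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Leave-one-genus-out importance scores for all genera
#'
#' Fits the baseline dyadic beta regression on the full Jaccard response,
#' then drops each genus in turn and refits with the identical spec and
#' seed, so CI-width changes reflect the data change rather than sampler
#' variation. Non-converged refits are flagged (and should be excluded from
#' downstream phenotype regressions).
#'
#' @inheritParams loo_importance
#' @param genera genera to evaluate (default: all in \code{asv_genus}).
#' @return list with \code{records} (rows per genus x effect, including
#'   min-max \code{scaled} scores per effect) and \code{baseline} fit.
#' @export
genus_importance <- function(counts, asv_genus, metadata, sri, overlap,
                             habitat, spec = dyadic_spec(), genera = NULL) {
  if (is.null(genera)) genera <- sort(unique(asv_genus))
  dy <- .jaccard_dyads(counts, metadata, sri, overlap, habitat)
  baseline <- fit_dyadic(dy, spec)
  recs <- lapply(genera, function(g) {
    loo_importance(counts, asv_genus, metadata, sri, overlap, habitat,
                   baseline, g, spec)
  })
  records <- do.call(rbind, recs)
  records <- scale_importance(records)
  list(records = records, baseline = baseline)
}

#' Min-max scale raw importance to \code{[0, 1]} within each effect
#'
#' @param records data.frame with columns \code{effect} and \code{raw}
#'   (and optionally \code{converged}; non-converged rows get NA).
#' @return the records with a \code{scaled} column added/replaced.
#' @export
scale_importance <- function(records) {
  records$scaled <- NA_real_
  ok <- if ("converged" %in% names(records)) records$converged else
    rep(TRUE, nrow(records))
  for (e in unique(records$effect)) {
    idx <- which(records$effect == e & ok)
    if (length(idx) < 2L) next
    r <- records$raw[idx]
    rng <- range(r)
    if (diff(rng) == 0) {
      warning("constant raw importance for effect ", e, "; scaled set to 0")
      records$scaled[idx] <- 0
    } else {
      records$scaled[idx] <- (r - rng[1L]) / diff(rng)
    }
  }
  records
}

#' Phylogenetic correlation matrix from a tree over genera
#'
#' Shared-path-length variance-covariance of the tips, scaled to unit
#' diagonal (a correlation matrix). A star phylogeny yields the identity.
#'
#' @param tree an \code{ape::phylo} object (or path to a newick file) whose
#'   tips cover the modelled genera.
#' @param genera optional character vector; the matrix is subset (and
#'   ordered) to these tips, erroring on missing ones.
#' @return positive semidefinite correlation matrix.
#' @export
phylo_cov <- function(tree, genera = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  V <- ape::vcv(tree)
  if (!is.null(genera)) {
    miss <- setdiff(genera, rownames(V))
    if (length(miss)) stop("tree lacks tips for genera: ",
                           paste(miss, collapse = ", "))
    V <- V[genera, genera, drop = FALSE]
  }
  d <- diag(V)
  d[d <= 0] <- 1
  C <- V / sqrt(outer(d, d))
  diag(C) <- 1
  C
}

#' Taxonomy-based fallback correlation matrix
#'
#' When no tree is available: same family -> 0.5, same phylum -> 0.25,
#' otherwise 0.05, with unit diagonal. A coarse but positive-definite
#' stand-in for shared ancestry.
#'
#' @param taxonomy data.frame \code{genus, family, phylum}.
#' @return correlation matrix over the genera.
#' @export
taxonomic_cov <- function(taxonomy) {
  g <- taxonomy$genus
  C <- matrix(0.05, length(g), length(g), dimnames = list(g, g))
  same_p <- outer(taxonomy$phylum, taxonomy$phylum, `==`)
  same_f <- outer(taxonomy$family, taxonomy$family, `==`)
  C[same_p] <- 0.25
  C[same_f] <- 0.5
  diag(C) <- 1
  C
}

#' Phenotype regression on importance scores
#'
#' Bayesian Gaussian regression of per-genus importance scores on
#' aerotolerance and sporulation phenotypes, with a genus-level random
#' effect \code{b ~ N(0, sigma^2 C)} whose correlation \code{C} encodes
#' phylogenetic relatedness (identity when \code{C = NULL}). With
#' \code{factorization = "four_level"} the phenotype enters as the four
#' aerotolerance x sporulation combinations and the fit carries post hoc
#' contrasts of each category against the pooled mean of the other three.
#'
#' @param scores data.frame \code{genus, effect, scaled} (one effect).
#' @param pheno data.frame \code{genus, aerotolerant, spore_forming}.
#' @param C optional correlation matrix over genera (see [phylo_cov()]).
#' @param factorization \code{"two_binary_plus_interaction"} or
#'   \code{"four_level"}.
#' @param mcmc an [mcmc_profile()].
#' @param seed sampler seed.
#' @return \code{mt_fit}, with a \code{contrasts} table for
#'   \code{four_level}.
#' @export
phenotype_regression <- function(scores, pheno, C = NULL,
                                 factorization = c("two_binary_plus_interaction",
                                                   "four_level"),
                                 mcmc = mcmc_profile("reduced"), seed = 1L) {
  factorization <- match.arg(factorization)
  stopifnot(length(unique(scores$effect)) == 1L)
  d <- merge(scores, pheno, by = "genus")
  d <- d[complete.cases(d[, c("scaled", "aerotolerant", "spore_forming")]), ]
  n <- nrow(d)
  if (n < 4L) stop("too few genera with scores and phenotypes")
  cell <- paste0(ifelse(d$aerotolerant == 1, "AE", "AN"), "_",
                 ifelse(d$spore_forming == 1, "SF", "NSF"))
  if (factorization == "four_level") {
    tab <- table(factor(cell, levels = c("AN_NSF", "AE_NSF", "AN_SF", "AE_SF")))
    if (any(tab < 2L)) {
      stop("four_level factorization needs >= 2 genera per phenotype cell; ",
           "short: ", paste(names(tab)[tab < 2L], collapse = ", "))
    }
    X <- cbind(intercept = 1,
               AE_NSF = as.integer(cell == "AE_NSF"),
               AN_SF = as.integer(cell == "AN_SF"),
               AE_SF = as.integer(cell == "AE_SF"))
  } else {
    X <- cbind(intercept = 1, aerotolerant = d$aerotolerant,
               spore_forming = d$spore_forming,
               `aerotolerant:spore_forming` = d$aerotolerant * d$spore_forming)
  }
  if (is.null(C)) {
    Cm <- diag(1, n)
  } else {
    Cm <- C[d$genus, d$genus, drop = FALSE]
  }
  fit <- .fit_gls_marginal(d$scaled, X, Cm, mcmc, seed)
  fit$factorization <- factorization
  if (factorization == "four_level") {
    dr <- fit$draws
    mu <- list(AN_NSF = dr[, "b_intercept"],
               AE_NSF = dr[, "b_intercept"] + dr[, "b_AE_NSF"],
               AN_SF = dr[, "b_intercept"] + dr[, "b_AN_SF"],
               AE_SF = dr[, "b_intercept"] + dr[, "b_AE_SF"])
    fit$contrasts <- do.call(rbind, lapply(names(mu), function(k) {
      others <- Reduce(`+`, mu[setdiff(names(mu), k)]) / 3
      x <- mu[[k]] - others
      data.frame(category = k, mean = mean(x),
                 ci_low = unname(quantile(x, 0.025)),
                 ci_high = unname(quantile(x, 0.975)))
    }))
  }
  fit
}

#' Correlations among the three effects' importance scores
#'
#' Pearson correlation between per-genus importance score vectors for each
#' pair of effects, with a permutation p-value (genus labels of the second
#' vector permuted).
#'
#' @param records a [scale_importance()]d records table.
#' @param use \code{"scaled"} (default) or \code{"raw"}.
#' @param n_perm permutations for the p-value.
#' @param seed permutation seed.
#' @return data.frame \code{effect_a, effect_b, r, p}.
#' @export
importance_correlations <- function(records, use = "scaled", n_perm = 999,
                                    seed = NULL) {
  effs <- unique(records$effect)
  wide <- lapply(effs, function(e) {
    r <- records[records$effect == e, ]
    setNames(r[[use]], r$genus)
  })
  names(wide) <- effs
  genera <- Reduce(intersect, lapply(wide, names))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (i in seq_along(effs)[-length(effs)]) for (j in (i + 1):length(effs)) {
    a <- wide[[i]][genera]; b <- wide[[j]][genera]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    r <- cor(a, b)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (abs(cor(a, sample(b))) >= abs(r) - 1e-12) hits <- hits + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      effect_a = effs[i], effect_b = effs[j], r = r,
      p = (hits + 1) / (n_perm + 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# univariate slice sampler (stepping out + shrinkage)
.slice1d <- function(x0, f, w = 0.5, m = 50) {
  logy <- f(x0) + log(runif(1))
  L <- x0 - w * runif(1); R <- L + w
  j <- floor(m * runif(1)); k <- m - 1 - j
  while (j > 0 && f(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && f(R) > logy) { R <- R + w; k <- k - 1 }
  for (it in 1:100) {
    x1 <- runif(1, L, R)
    if (f(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# Gaussian regression with a correlated genus-level random effect,
# fitted on the marginal likelihood y ~ N(X beta, sb^2 C + s^2 I).
# The eigendecomposition of C diagonalizes the covariance, so each
# evaluation is O(n p); parameters are updated by componentwise slice
# sampling (robust for the weakly identified sb/s split at one
# observation per genus). Returns an mt_fit-compatible object.
.fit_gls_marginal <- function(y, X, C, mcmc = mcmc_profile("reduced"),
                              seed = 1L) {
  n <- length(y); p <- ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  lp_half_t <- function(sigma, ls) {
    -2 * log1p(sigma^2 / (3 * 2.5^2)) + ls
  }
  logpost <- function(th) {
    beta <- th[1:p]; sb <- exp(th[p + 1]); sres <- exp(th[p + 2])
    v <- sb^2 * lam + sres^2
    r <- yt - as.numeric(Xt %*% beta)
    ll <- -0.5 * sum(log(v)) - 0.5 * sum(r^2 / v)
    pr <- -2 * log1p(beta[1]^2 / (3 * 2.5^2)) - sum(beta[-1]^2) / 50 +
      lp_half_t(sb, th[p + 1]) + lp_half_t(sres, th[p + 2])
    ll + pr
  }
  set.seed(seed)
  P <- p + 2L
  total <- mcmc$iter * mcmc$chains
  draws <- matrix(NA_real_, total, P)
  chain <- integer(total)
  sdy <- max(sd(y), 1e-3)
  for (cc in seq_len(mcmc$chains)) {
    th <- c(mean(y), rep(0, p - 1L), log(sdy / 2), log(sdy / 2)) +
      rnorm(P, 0, 0.05)
    for (it in seq_len(mcmc$warmup + mcmc$iter)) {
      for (k in seq_len(P)) {
        th[k] <- .slice1d(th[k], function(v) {
          t2 <- th; t2[k] <- v; logpost(t2)
        })
      }
      if (it > mcmc$warmup) {
        row <- (cc - 1L) * mcmc$iter + it - mcmc$warmup
        draws[row, ] <- th
        chain[row] <- cc
      }
    }
  }
  colnames(draws) <- c(paste0("b_", gsub("[()]", "", colnames(X))),
                       "sd_genus", "sigma")
  draws[, p + 1L] <- exp(draws[, p + 1L])
  draws[, p + 2L] <- exp(draws[, p + 2L])
  summ <- do.call(rbind, lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    data.frame(term = nm, mean = mean(x),
               ci_low = unname(quantile(x, 0.025)),
               ci_high = unname(quantile(x, 0.975)),
               rhat = rhat(x, chain), ess_bulk = ess_bulk(x, chain),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- summ$term
  rh <- summ$rhat[is.finite(summ$rhat)]
  es <- summ$ess_bulk[is.finite(summ$ess_bulk)]
  converged <- length(rh) > 0 && all(rh < 1.05) && all(es >= 0.1 * total)
  structure(list(draws = draws, chain = chain, summary = summ,
                 likelihood = "gaussian",
                 diagnostics = list(divergences = 0L,
                                    div_nonfinite = 0L, div_energy = 0L,
                                    max_rhat = if (length(rh)) max(rh) else NA,
                                    min_ess = if (length(es)) min(es) else NA,
                                    n_draws = total),
                 converged = converged, mcmc = mcmc, seed = seed,
                 dropped_terms = character()),
            class = "mt_fit")
}
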