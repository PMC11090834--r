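#' Jaccard index between two presence sets
#'
#' \code{|intersect| / |union|}; defined as 0 when both sets are empty.
#'
#' @param a,b vectors of taxon identifiers (or logical presence vectors of
#'   equal length over a common universe).
#' @return numeric in \code{[0, 1]}.
#' @export
jaccard <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    stopifnot(length(a) == length(b))
    u <- sum(a | b)
    return(if (u == 0) 0 else sum(a & b) / u)
  }
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' @rdname bray_curtis_similarity
#' @export
bray_curtis_sim <- function(x, y) bray_curtis_similarity(x, y)

#' Shared-taxon count between two presence sets
#'
#' @inheritParams jaccard
#' @return non-negative integer.
#' @export
shared_count <- function(a, b) {
  if (is.logical(a) && is.logical(b)) return(sum(a & b))
  length(intersect(a, b))
}

#' Min-max scale a vector of counts to \code{[0, 1]}
#'
#' @param counts numeric vector (e.g. shared-taxon counts over dyads).
#' @return vector in \code{[0, 1]}; all zeros when the input is constant.
#' @export
scale_count <- function(counts) {
  rng <- range(counts)
  if (diff(rng) == 0) {
    warning("constant counts: scaled values all set to 0")
    return(rep(0, length(counts)))
  }
  (counts - rng[1L]) / diff(rng)
}

#' Normalize a count table to per-sample proportions
#'
#' @param counts samples x taxa numeric matrix (row names = sample ids).
#' @return matrix of row proportions (rows summing to 1; all-zero rows stay 0).
#' @export
normalize_proportions <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  rs[rs == 0] <- 1
  counts / rs
}

# presence/absence from counts or proportions: any positive abundance
.presence <- function(table) as.matrix(table) > 0

#' Pairwise microbiota similarity matrix
#'
#' Computes sample-by-sample similarity over an abundance table:
#' \code{jaccard} (presence/absence), \code{bray} (Bray-Curtis similarity
#' of per-sample proportions) or \code{count} (raw shared-taxon count).
#' Presence means abundance > 0 after per-sample normalization.
#'
#' @param table samples x ASV matrix of counts or proportions, with row
#'   (sample) and column (ASV) names.
#' @param metric one of \code{"jaccard"}, \code{"bray"}, \code{"count"}.
#' @return symmetric matrix; \code{[0,1]} for jaccard/bray, integer counts
#'   otherwise.
#' @export
similarity_matrix <- function(table, metric = c("jaccard", "bray", "count")) {
  metric <- match.arg(metric)
  table <- as.matrix(table)
  if (any(table < 0)) stop("abundances must be non-negative")
  n <- nrow(table)
  ids <- rownames(table)
  if (metric %in% c("jaccard", "count")) {
    p <- .presence(table) * 1
    inter <- tcrossprod(p)
    if (metric == "count") {
      m <- inter
    } else {
      sz <- rowSums(p)
      un <- outer(sz, sz, `+`) - inter
      m <- ifelse(un == 0, 0, inter / un)
    }
  } else {
    pr <- normalize_proportions(table)
    m <- diag(1, n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- bray_curtis_similarity(pr[i, ], pr[j, ])
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Phenotype-restricted Jaccard similarity
#'
#' Restricts the ASV universe to genera with known phenotype and the chosen
#' phenotypic subset, then computes the pairwise Jaccard matrix. Samples
#' with an empty restricted presence set are flagged in
#' \code{attr(, "empty_samples")}.
#'
#' @param table samples x ASV abundance matrix.
#' @param genus character vector, genus of each ASV (column order).
#' @param pheno data.frame \code{genus, aerotolerant, spore_forming} and
#'   optionally \code{known} (0/1; rows with \code{known = 0} are excluded,
#'   as are genera absent from the table's annotation).
#' @param subset one of \code{"all"}, \code{"anaerobic"},
#'   \code{"aerotolerant"}, \code{"spore"}, \code{"non_spore"}.
#' @return symmetric Jaccard matrix over samples.
#' @export
subset_jaccard <- function(table, genus, pheno,
                           subset = c("all", "anaerobic", "aerotolerant",
                                      "spore", "non_spore")) {
  subset <- match.arg(subset)
  stopifnot(length(genus) == ncol(table))
  if (!"known" %in% names(pheno)) pheno$known <- 1L
  pheno <- pheno[pheno$known == 1L, , drop = FALSE]
  keep_genus <- switch(subset,
    all = pheno$genus,
    anaerobic = pheno$genus[pheno$aerotolerant == 0L],
    aerotolerant = pheno$genus[pheno$aerotolerant == 1L],
    spore = pheno$genus[pheno$spore_forming == 1L],
    non_spore = pheno$genus[pheno$spore_forming == 0L])
  keep <- genus %in% keep_genus
  if (!any(keep)) stop(sprintf("phenotype subset '%s' contains no ASVs", subset))
  sub <- as.matrix(table)[, keep, drop = FALSE]
  m <- similarity_matrix(sub, "jaccard")
  empty <- rownames(sub)[rowSums(.presence(sub)) == 0]
  attr(m, "empty_samples") <- empty
  m
}

#' Boundary-shrinking transform for beta-regression responses
#'
#' Maps proportions in \code{[0, 1]} strictly inside \code{(0, 1)} via
#' \code{(j * (n - 1) + 0.5) / n}, where \code{n} is the number of dyadic
#' observations entering the model. Standard remedy for exact zeros/ones
#' under a beta likelihood.
#'
#' @param j proportions in \code{[0, 1]} (vectorized).
#' @param n sample size (number of dyads), \code{n >= 1}.
#' @return values in \code{(0, 1)}.
#' @export
smithson_verkuilen <- function(j, n) {
  if (any(!is.finite(j)) || any(j < 0) || any(j > 1)) {
    stop("j must lie in [0, 1]")
  }
  stopifnot(n >= 1)
  (j * (n - 1) + 0.5) / n
}

#' Mantel correlation between two dyadic matrices
#'
#' Pearson correlation over the lower off-diagonal triangle, with a
#' permutation test that jointly permutes rows and columns of the second
#' matrix. The two-sided p-value uses the add-one correction
#' \code{(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)}.
#'
#' @param m1,m2 symmetric matrices over the same individuals.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with \code{r} and \code{p}.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = NULL) {
  stopifnot(identical(dim(m1), dim(m2)))
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]; v2 <- m2[lt]
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("Mantel correlation undefined for a constant matrix")
  }
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    rp <- cor(v1, m2[pp, pp][lt])
    if (abs(rp) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1))
}
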