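test_that("raw_importance formula and the sqrt(nASV) normalizer", {
  expect_equal(raw_importance(0.10, 0.12, 4), 0.1)
  expect_equal(raw_importance(0.2, 0.2, 9), 0)
  expect_error(raw_importance(0, 0.1, 1), "> 0")
  expect_error(raw_importance(0.1, 0.1, 0), "n_asv")
  # splitting a genus into two equal pseudo-genera only changes the
  # normalizer: raw(n) = raw(n/2) * sqrt(n/2)/sqrt(n)
  r_whole <- raw_importance(0.1, 0.14, 8)
  r_half <- raw_importance(0.1, 0.14, 4)
  expect_equal(r_whole, r_half * sqrt(4) / sqrt(8))
})

test_that("scale_importance min-max per effect, rank preservation, edge cases", {
  rec <- data.frame(genus = rep(c("g1", "g2", "g3"), 2),
                    effect = rep(c("social", "spatial"), each = 3),
                    raw = c(-0.2, 0.3, 0.8, 5, 1, 3))
  out <- scale_importance(rec)
  expect_equal(out$scaled[out$effect == "social"], c(0, 0.5, 1))
  expect_equal(out$scaled[out$effect == "spatial"], c(1, 0, 0.5))
  expect_equal(cor(out$raw[1:3], out$scaled[1:3], method = "spearman"), 1)
  two <- scale_importance(data.frame(effect = "social", raw = c(1, 4),
                                     genus = c("a", "b")))
  expect_equal(two$scaled, c(0, 1))
  expect_warning(const <- scale_importance(
    data.frame(effect = "social", raw = c(2, 2), genus = c("a", "b"))),
    "constant")
  expect_equal(const$scaled, c(0, 0))
  # non-converged rows are excluded from scaling
  rec2 <- data.frame(genus = c("g1", "g2", "g3"), effect = "social",
                     raw = c(0, 1, 99), converged = c(TRUE, TRUE, FALSE))
  out2 <- scale_importance(rec2)
  expect_equal(out2$scaled, c(0, 1, NA))
})

test_that("phylo_cov: star tree, sister-tip limit, 5-tip hand computation", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(phylo_cov(star), diag(1, 4), ignore_attr = TRUE)
  sis <- ape::read.tree(text = "((a:0.001,b:0.001):0.999,c:1);")
  C <- phylo_cov(sis)
  expect_gt(C["a", "b"], 0.99)
  expect_equal(C["a", "c"], 0)
  # 5-tip tree, hand-computed shared path lengths / sqrt(depth products)
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:1.5,e:1.5):1.5);")
  C5 <- phylo_cov(tr)
  expect_equal(C5["a", "b"], 2 / 3)   # shared 2, depths 3
  expect_equal(C5["a", "c"], 1 / 3)
  expect_equal(C5["d", "e"], 1.5 / 3)
  expect_equal(C5["a", "d"], 0)
  expect_equal(diag(C5), rep(1, 5), ignore_attr = TRUE)
  ev <- eigen(C5, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_error(phylo_cov(star, genera = c("a", "zz")), "zz")
})

test_that("taxonomic fallback covariance encodes rank proximity", {
  tax <- data.frame(genus = c("g1", "g2", "g3", "g4"),
                    family = c("f1", "f1", "f2", "f3"),
                    phylum = c("p1", "p1", "p1", "p2"))
  C <- taxonomic_cov(tax)
  expect_equal(C["g1", "g2"], 0.5)
  expect_equal(C["g1", "g3"], 0.25)
  expect_equal(C["g1", "g4"], 0.05)
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
})

test_that("importance_correlations matches direct Pearson and detects identity", {
  rec <- data.frame(
    genus = rep(c("g1", "g2", "g3", "g4"), 3),
    effect = rep(c("social", "spatial", "habitat"), each = 4),
    scaled = c(0.1, 0.4, 0.6, 0.9,
               0.1, 0.4, 0.6, 0.9,
               0.8, 0.2, 0.9, 0.1))
  out <- importance_correlations(rec, n_perm = 99, seed = 1)
  soc_spa <- out[out$effect_a == "social" & out$effect_b == "spatial", ]
  expect_equal(soc_spa$r, 1)
  soc_hab <- out[out$effect_a == "social" & out$effect_b == "habitat", ]
  expect_equal(soc_hab$r,
               cor(c(0.1, 0.4, 0.6, 0.9), c(0.8, 0.2, 0.9, 0.1)))
  # independent vectors -> |r| small on average across seeds
  set.seed(2)
  rs <- replicate(20, {
    r2 <- data.frame(genus = rep(sprintf("g%02d", 1:30), 2),
                     effect = rep(c("social", "spatial"), each = 30),
                     scaled = runif(60))
    importance_correlations(r2, n_perm = 9)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("loo importance: absent genus gives exactly zero; errors are informative", {
  st <- make_stack(tiny_cfg(seed = 21))
  counts <- st$mic$counts
  genus <- st$world$asvs$genus
  spec <- dyadic_spec(covariates = c("age_similarity", "sex_similarity"),
                      mcmc = quick_mcmc(), seed = 6)
  dy <- micetrans:::.jaccard_dyads(counts, st$mic$metadata, st$sri, st$ov, st$hab)
  baseline <- suppressMessages(fit_dyadic(dy, spec))
  # a genus absent from every sample: identical data + identical seed ->
  # identical fit -> raw importance exactly 0
  counts2 <- cbind(counts, ghost1 = 0L, ghost2 = 0L)
  genus2 <- c(genus, "ghost", "ghost")
  rec <- suppressMessages(
    loo_importance(counts2, genus2, st$mic$metadata, st$sri, st$ov, st$hab,
                   baseline, "ghost", spec))
  expect_equal(rec$raw, rep(0, 3))
  expect_equal(rec$n_asv, rep(2L, 3))
  expect_setequal(rec$effect, c("social", "spatial", "habitat"))
  expect_error(suppressMessages(
    loo_importance(counts, genus, st$mic$metadata, st$sri, st$ov, st$hab,
                   baseline, "not_a_genus", spec)), "not present")
  one_genus <- counts[, genus == genus[1], drop = FALSE]
  expect_error(suppressMessages(
    loo_importance(one_genus, genus[genus == genus[1]], st$mic$metadata,
                   st$sri, st$ov, st$hab, baseline, genus[1], spec)),
    "entire community")
})

test_that("phenotype regression: null calibration and identity-C reduction", {
  set.seed(8)
  ng <- 20
  pheno <- data.frame(genus = sprintf("g%02d", 1:ng),
                      aerotolerant = rep(0:1, ng / 2),
                      spore_forming = rep(c(0, 0, 1, 1), ng / 4))
  # balanced null: scores independent of phenotype
  cover <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    scores <- data.frame(genus = pheno$genus, effect = "social",
                         scaled = runif(ng))
    f <- phenotype_regression(scores, pheno, NULL, seed = s)
    ci <- f$summary["b_aerotolerant", ]
    if (ci$ci_low <= 0 && 0 <= ci$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 9L)

  # C = identity equals the no-C fit up to MCMC error
  set.seed(5)
  scores <- data.frame(genus = pheno$genus, effect = "social",
                       scaled = runif(ng))
  f_id <- phenotype_regression(scores, pheno, diag(1, ng,
                                                   ng) |>
                                 `dimnames<-`(list(pheno$genus, pheno$genus)),
                               seed = 2)
  f_no <- phenotype_regression(scores, pheno, NULL, seed = 2)
  fe <- grep("^b_", f_no$summary$term, value = TRUE)
  expect_lt(max(abs(f_id$summary[fe, "mean"] - f_no$summary[fe, "mean"])), 0.05)

  # four-level factorization: contrasts recover an elevated cell
  scores2 <- data.frame(genus = pheno$genus, effect = "spatial",
                        scaled = ifelse(pheno$aerotolerant == 1 &
                                          pheno$spore_forming == 1,
                                        0.8, 0.2) + rnorm(ng, 0, 0.05))
  f4 <- phenotype_regression(scores2, pheno, NULL,
                             factorization = "four_level", seed = 3)
  aesf <- f4$contrasts[f4$contrasts$category == "AE_SF", ]
  expect_gt(aesf$ci_low, 0)
  # error when a cell is too sparse
  ph_bad <- pheno
  ph_bad$spore_forming[ph_bad$aerotolerant == 1] <- 1
  expect_error(phenotype_regression(scores2, ph_bad, NULL,
                                    factorization = "four_level", seed = 1),
               "per phenotype cell")
})
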