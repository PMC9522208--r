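test_that("newick reading validates tips and applies unit branch lengths", {
  t1 <- read_phylogeny(text = "(A:1,B:1);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(t1)[1:2]), c(1, 1))

  # unit lengths: tip depths equal the number of edges to the root
  t2 <- read_phylogeny(text = "((A,B),C);", unit_branch_lengths = TRUE)
  d <- ape::node.depth.edgelength(t2)[seq_along(t2$tip.label)]
  expect_equal(unname(d[match(c("A", "B", "C"), t2$tip.label)]), c(2, 2, 1))

  expect_error(read_phylogeny(text = "(A,A);"), "duplicate tip")
  expect_error(read_phylogeny(text = "((A,B);"), "malformed newick")
})

test_that("phylogenetic covariance encodes shared branch length, lambda, and replicates", {
  # star tree: no shared ancestry, identity up to jitter
  star <- read_phylogeny(text = "(A:1,B:1,C:1);")
  V <- phylo_covariance(star, c("A", "B", "C"), lambda = 0.7, jitter = 0)
  expect_equal(unclass(V), diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  # hand-computed shared branch lengths
  tr <- read_phylogeny(text = "((A:0.5,B:0.5):0.5,C:1);")
  V1 <- phylo_covariance(tr, c("A", "B", "C"), lambda = 1, jitter = 0)
  expect_equal(V1[1, 2], 0.5)
  expect_equal(V1[1, 3], 0)
  expect_equal(unname(diag(V1)), c(1, 1, 1))

  # lambda = 0 kills all off-diagonals regardless of topology
  V0 <- phylo_covariance(tr, c("A", "B", "C"), lambda = 0, jitter = 0)
  expect_equal(unclass(V0), diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  # conspecific specimens share the full (lambda-scaled) tip depth
  V2 <- phylo_covariance(tr, c("A", "A", "C"), lambda = 0.8, jitter = 1e-6)
  expect_equal(V2[1, 2], 0.8 * 1)
  expect_equal(V2[1, 1], 1 * (1 + 1e-6))

  # invariant to specimen ordering (consistent permutation)
  sp <- c("A", "B", "C", "B")
  perm <- c(3, 1, 4, 2)
  Va <- phylo_covariance(tr, sp, lambda = 0.6)
  Vb <- phylo_covariance(tr, sp[perm], lambda = 0.6)
  expect_equal(unclass(Vb), unclass(Va)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(phylo_covariance(tr, c("A", "Z")), "Z")
  expect_error(phylo_covariance(tr, "A", lambda = 1.4), "lambda")

  # positive semi-definite on generated trees
  cfg <- generator_config(seed = 9)
  tree <- generate_tree(cfg)
  tab <- generate_specimens(cfg, tree)
  sp17 <- tab$species[tab$spiracle == "S"]
  Vg <- phylo_covariance(tree, sp17, lambda = 0.9)
  ev <- eigen(unclass(Vg), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("pGLS reduces to OLS under (scaled) identity covariance", {
  set.seed(31)
  mass <- 10^runif(10, -1, 1)
  value <- 10^(0.2 + 0.6 * log10(mass) + rnorm(10, 0, 0.15))
  ols <- loglog_ols(mass, value)
  g1 <- pgls_fit(mass, value, diag(10))
  expect_equal(g1$slope, ols$slope, tolerance = 1e-10)
  expect_equal(g1$intercept, ols$intercept, tolerance = 1e-10)
  # scale invariance of the GLS point estimate
  g2 <- pgls_fit(mass, value, 2 * diag(10))
  expect_equal(g2$slope, g1$slope, tolerance = 1e-10)
  expect_equal(g2$intercept, g1$intercept, tolerance = 1e-10)
})

test_that("pGLS matches the Cholesky-whitening oracle on small fixtures", {
  tr <- read_phylogeny(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:3);")
  set.seed(32)
  for (rep in 1:5) {
    sp <- c("A", "A", "B", "C", "D", "E")
    mass <- 10^runif(6, -1, 1)
    value <- 10^(0.1 + 0.5 * log10(mass) + rnorm(6, 0, 0.2))
    V <- phylo_covariance(tr, sp, lambda = 1)
    fit <- pgls_fit(mass, value, unclass(V))
    orc <- gls_whitening_oracle(mass, value, unclass(V))
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
  }
  expect_error(pgls_fit(c(1, 2, 3), c(1, 2, 3),
                        matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3)),
               "positive definite")
})

test_that("lambda profile recovers strong signal and is flat when uninformed", {
  # constant response: perfect fit at every lambda, exactly flat by convention
  tr <- read_phylogeny(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pr <- lambda_profile(c(1, 2, 4, 8), rep(5, 4), tr, c("A", "B", "C", "D"))
  expect_true(attr(pr, "degenerate"))
  expect_equal(attr(pr, "flatness"), 0)
  expect_false(attr(pr, "identifiable"))

  # lambda = 0 truth, large n: profile maximized near zero
  cfg <- generator_config(n_species = 40, specimens_per_species = rep(2L, 40),
                          lambda_signal = 0, seed = 7)
  tree <- generate_tree(cfg)
  tab <- generate_specimens(cfg, tree)
  a1 <- spiracle_morphometrics(tab)
  a1 <- a1[a1$spiracle == "A1", ]
  pr0 <- lambda_profile(a1$mass_g, a1$area_cm2, tree, a1$species)
  expect_lte(attr(pr0, "lambda_hat"), 0.2)

  # jitter-dominated grid points (singular before jittering) are flagged
  expect_true(any(pr0$jitter_dominated))
  expect_true(pr0$jitter_dominated[pr0$lambda == 1])

  # strong signal, many species: clearly identifiable with the error-term model
  cfgs <- generator_config(n_species = 40, specimens_per_species = rep(2L, 40),
                           lambda_signal = 0.9, phylo_sd = 0.4, seed = 5)
  trs <- generate_tree(cfgs)
  tabs <- generate_specimens(cfgs, trs)
  s1 <- spiracle_morphometrics(tabs)
  s1 <- s1[s1$spiracle == "A1", ]
  prs <- lambda_profile(s1$mass_g, s1$area_cm2, trs, s1$species,
                        error_term = "profiled")
  expect_true(attr(prs, "identifiable"))
  expect_gte(attr(prs, "lambda_hat"), 0.5)

  expect_error(lambda_profile(1:3, 1:3, tr, c("A", "B", "C"), grid = c(-0.1, 1)),
               "grid")
})

test_that("lambda profiles round-trip through their CSV export", {
  tr <- read_phylogeny(text = "((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(40)
  pr <- lambda_profile(c(1, 2, 4, 8), 2^runif(4), tr, c("A", "B", "C", "D"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_lambda_profile(pr, p)
  back <- utils::read.csv(p)
  expect_equal(back$loglik, pr$loglik, tolerance = 1e-6)
})
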