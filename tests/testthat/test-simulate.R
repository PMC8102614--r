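test_that("simulated trees have the requested tips, unit height, and are reproducible", {
  tr <- simulate_tree(4, 1.0, seed = 1)
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1.0)
  expect_identical(ape::write.tree(simulate_tree(4, 1.0, seed = 1)),
                   ape::write.tree(tr))
  expect_error(simulate_tree(3, 1.0, 1), class = "phyloyawn_domain_error")
  big <- simulate_tree(50, 1.0, seed = 2)
  C <- phylo_cov(big, scale_to_unit_height = TRUE)
  off <- C[upper.tri(C)]
  expect_gt(mean(off), 0)
  expect_lt(mean(off), 1)
})

test_that("Brownian traits collapse to the root under zero evolutionary variance", {
  tr <- simulate_tree(6, 1, seed = 3)
  bm <- simulate_bm_traits(tr, c(2, 1), matrix(0, 2, 2), seed = 1)
  expect_equal(bm$log_body, rep(2, 6))
  expect_equal(bm$log_brain, rep(1, 6))
  expect_error(simulate_bm_traits(tr, c(0, 0),
                                  matrix(c(1, 2, 2, 1), 2, 2), seed = 1),
               class = "phyloyawn_domain_error")
})

test_that("Brownian trait moments match height x evo_cov on a star tree", {
  star <- ape::stree(3, "star")
  star$edge.length <- rep(1, 3)
  evo <- matrix(c(2, 0.8, 0.8, 1), 2, 2)
  reps <- 2000
  sims <- vapply(seq_len(reps), function(r) {
    bm <- simulate_bm_traits(star, c(0, 0), evo, seed = 1000 + r)
    c(bm$log_body[1], bm$log_brain[1])
  }, numeric(2))
  emp <- stats::cov(t(sims))
  expect_equal(emp[1, 1], evo[1, 1], tolerance = 0.15)
  expect_equal(emp[2, 2], evo[2, 2], tolerance = 0.15)
  expect_equal(emp[1, 2], evo[1, 2], tolerance = 0.2)
})

test_that("an evolutionary correlation of 0.95 is visible in simulated traits", {
  cfg <- sim_config("mammal", n_species = 200, seed = 21)
  tr <- simulate_tree(200, 1, seed = 4)
  bm <- simulate_bm_traits(tr, cfg$trait_root, cfg$evo_cov, seed = 5)
  r <- phylo_correlation(bm$log_body, bm$log_brain, tr)
  expect_equal(r, 0.95, tolerance = 0.05)
  expect_gt(stats::cor(bm$log_body, bm$log_brain), 0.8)
})

test_that("neuron allometry is exact without noise and recoverable with it", {
  lb <- seq(0, 5, length.out = 500)
  expect_equal(simulate_neurons(lb, 1, 0, 0, seed = 1), lb)
  expect_equal(simulate_neurons(lb, 0.7, 2, 0, seed = 1), 2 + 0.7 * lb)
  ln <- simulate_neurons(lb, 0.7, 2, 0.3, seed = 2)
  slope <- unname(coef(lm(ln ~ lb))[2])
  expect_equal(slope, 0.7, tolerance = 0.05)
  expect_error(simulate_neurons(lb, 1, 0, -1, 1),
               class = "phyloyawn_domain_error")
})

test_that("yawn simulation hits its degenerate noiseless limit", {
  tr <- simulate_tree(5, 1, seed = 6)
  z <- setNames(rep(0.7, 5), tr$tip.label)
  cfg <- sim_config("mammal", n_species = 5, sigma_phylo = 0,
                    sigma_species = 0, shape = 1e6, beta = 0, seed = 1)
  ev <- simulate_yawns(tr, z, cfg)
  expect_equal(ev$duration, rep(exp(cfg$beta0), nrow(ev)), tolerance = 0.02)
  expect_error(simulate_yawns(tr, unname(z), cfg),
               class = "phyloyawn_domain_error")
})

test_that("per-species means converge to exp(eta) by the law of large numbers", {
  tr <- simulate_tree(4, 1, seed = 7)
  z <- setNames(c(-1, 0, 0.5, 1), tr$tip.label)
  cfg <- sim_config("mammal", n_species = 4, individuals_per_species = 100,
                    yawns_per_individual = 100, seed = 8)
  ev <- simulate_yawns(tr, z, cfg)
  truth <- attr(ev, "truth")
  means <- tapply(ev$duration, ev$species, mean)[tr$tip.label]
  expect_equal(as.numeric(means), unname(exp(truth$eta)), tolerance = 0.01)
})

test_that("a positive slope induces a positive duration-predictor association", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config("mammal", n_species = 50, seed = 100 + s)
    ds <- simulate_dataset(cfg)
    means <- tapply(ds$events$duration, ds$events$species,
                    mean)[ds$tree$tip.label]
    stats::cor(means, ds$z_predictor, method = "spearman") > 0
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("simulation is bit-reproducible given (config, seed)", {
  a <- simulate_dataset(sim_config("bird", n_species = 10, seed = 33))
  b <- simulate_dataset(sim_config("bird", n_species = 10, seed = 33))
  expect_identical(a$events$duration, b$events$duration)
  expect_identical(a$traits, b$traits)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("order assignment carves the requested number of monophyletic groups", {
  tr <- simulate_tree(40, 1, seed = 9)
  ord <- phyloyawn:::assign_orders(tr, 5)
  expect_equal(nlevels(ord), 5L)
  expect_equal(length(ord), 40L)
})

test_that("config validation names offending fields", {
  expect_error(sim_config("mammal", n_species = 3),
               "n_species", class = "phyloyawn_config_error")
  expect_error(sim_config("mammal", shape = -1), "shape",
               class = "phyloyawn_config_error")
  expect_error(sim_config("mammal", lambda_sim = 1.2), "lambda",
               class = "phyloyawn_config_error")
})
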