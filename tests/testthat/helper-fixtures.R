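# Shared fixtures and short-chain fit settings for the test suite.
# Simulation suites use deliberately short chains with the convergence
# gate disabled; the gate itself is exercised in its own test.

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Simulate, aggregate and tree-match one clade; returns list(data, tree,
# truth) with a `z` column standardized on the matched sample.
quick_clade <- function(n = 30, seed = 1, clade = "mammal", ...) {
  cfg <- sim_config(clade, n_species = n, seed = seed, ...)
  ds <- simulate_dataset(cfg)
  agg <- suppressMessages(aggregate_species(ds$events, ds$traits))
  m <- match_tree(agg, ds$tree)
  m$data$z <- as.numeric(standardize(m$data$log_brain))
  list(data = m$data, tree = m$tree, truth = ds$truth, dataset = ds)
}

quick_fit <- function(data, tree, spec = yawn_model("z"), seed = 1,
                      iterations = 1200, ...) {
  fit_model(data, tree, spec, chains = 2, iterations = iterations,
            warmup = iterations %/% 2, seed = seed,
            check_convergence = "none", ...)
}

# Minimal hand-built fit object for closed-form prediction tests.
fake_fit <- function(draws, predictors = "z") {
  structure(list(draws = draws, spec = yawn_model(predictors),
                 group_levels = ""),
            class = "yawn_fit")
}

write_csv_fixture <- function(df, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
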