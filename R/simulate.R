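#' Simulation configuration
#'
#' Bundles every generative parameter of the synthetic-data generator.
#' The clade presets encode the study conditions the generator emulates:
#' sample sizes of 55 mammal / 46 bird species, expected durations of
#' 3.4 s (mammals) and 1.46 s (birds) at clade-average brain size, slopes
#' of 0.35 / 0.20 per SD of log brain mass, phylogenetic signal
#' lambda = 0.80 / 0.64, and log brain-body evolutionary correlations of
#' 0.95 / 0.87.
#'
#' @param clade `"mammal"` or `"bird"`; selects the preset defaults.
#' @param n_species Number of tips (>= 4).
#' @param birth_rate Speciation rate of the pure-birth tree.
#' @param trait_root Length-2 vector: root values of (log body g, log
#'   brain g).
#' @param evo_cov 2x2 evolutionary covariance of (log body, log brain)
#'   per unit branch length; must be symmetric PSD.
#' @param neuron_slope,neuron_intercept,neuron_noise_sd Allometric map
#'   from log brain mass to log total neuron count.
#' @param beta0 Intercept on the log-seconds scale.
#' @param beta Slope per SD of the standardized brain predictor.
#' @param sigma_phylo,sigma_species SDs of the phylogenetically
#'   correlated and i.i.d. species intercepts (link scale).
#' @param shape Gamma shape of individual yawn durations around the
#'   species mean.
#' @param lambda_sim Pagel's lambda applied to the simulated phylogenetic
#'   intercepts (in `[0, 1]`).
#' @param individuals_per_species,yawns_per_individual Sampling design.
#' @param n_orders Number of taxonomic orders carved out of the tree.
#' @param sigma_slope SD of per-order slope deviations (0 = none).
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A validated list of class `yawn_sim_config`.
#' @export
sim_config <- function(clade = c("mammal", "bird"),
                       n_species = NULL, birth_rate = 1,
                       trait_root = NULL, evo_cov = NULL,
                       neuron_slope = NULL, neuron_intercept = NULL,
                       neuron_noise_sd = 0.3,
                       beta0 = NULL, beta = NULL,
                       sigma_phylo = 0.2, sigma_species = 0.1,
                       shape = 20, lambda_sim = NULL,
                       individuals_per_species = NULL,
                       yawns_per_individual = 2L,
                       n_orders = 5L, sigma_slope = 0,
                       seed = 42L) {
  clade <- match.arg(clade)
  preset <- if (clade == "mammal") {
    list(n_species = 55L, beta0 = log(3.4), beta = 0.35, lambda_sim = 0.80,
         corr = 0.95, trait_root = c(log(10000), log(30)),
         vars = c(6, 4), neuron_slope = 0.85, neuron_intercept = 18.5,
         individuals_per_species = 8L)
  } else {
    list(n_species = 46L, beta0 = log(1.46), beta = 0.20, lambda_sim = 0.64,
         corr = 0.87, trait_root = c(log(300), log(3)),
         vars = c(4, 3), neuron_slope = 0.90, neuron_intercept = 18.8,
         individuals_per_species = 6L)
  }
  if (is.null(evo_cov)) {
    v <- preset$vars
    evo_cov <- matrix(c(v[1], preset$corr * sqrt(v[1] * v[2]),
                        preset$corr * sqrt(v[1] * v[2]), v[2]), 2, 2)
  }
  cfg <- list(
    clade = clade,
    n_species = as.integer(n_species %||% preset$n_species),
    birth_rate = birth_rate,
    trait_root = trait_root %||% preset$trait_root,
    evo_cov = evo_cov,
    neuron_slope = neuron_slope %||% preset$neuron_slope,
    neuron_intercept = neuron_intercept %||% preset$neuron_intercept,
    neuron_noise_sd = neuron_noise_sd,
    beta0 = beta0 %||% preset$beta0,
    beta = beta %||% preset$beta,
    sigma_phylo = sigma_phylo,
    sigma_species = sigma_species,
    shape = shape,
    lambda_sim = lambda_sim %||% preset$lambda_sim,
    individuals_per_species =
      as.integer(individuals_per_species %||% preset$individuals_per_species),
    yawns_per_individual = as.integer(yawns_per_individual),
    n_orders = as.integer(n_orders),
    sigma_slope = sigma_slope,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "yawn_sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character()
  if (cfg$n_species < 4L) problems <- c(problems, "n_species must be >= 4")
  if (cfg$shape <= 0) problems <- c(problems, "shape must be > 0")
  if (cfg$lambda_sim < 0 || cfg$lambda_sim > 1)
    problems <- c(problems, "lambda_sim must be in [0, 1]")
  ec <- cfg$evo_cov
  if (!isTRUE(all.equal(ec, t(ec))) ||
      min(eigen(ec, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    problems <- c(problems, "evo_cov must be symmetric positive semi-definite")
  if (cfg$sigma_phylo < 0 || cfg$sigma_species < 0 || cfg$sigma_slope < 0)
    problems <- c(problems, "random-effect SDs must be non-negative")
  if (length(problems)) {
    abort(paste0("invalid simulation config: ",
                 paste(problems, collapse = "; ")),
          class = "phyloyawn_config_error")
  }
  invisible(cfg)
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with the requested number of tips, rescaled so the
#' root-to-tip height is exactly 1 (all downstream variance parameters
#' are therefore on a common per-tree-height scale).
#'
#' @param n_species Number of tips (>= 4).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed; the tree is deterministic given it.
#' @return A rooted ultrametric `phylo` object of unit height.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (n_species < 4L) stop_domain("n_species must be >= 4")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Draws (log body, log brain) from the matrix normal implied by Brownian
#' motion: across-species covariance equal to the tree's shared-path
#' matrix, across-trait covariance `evo_cov` per unit branch length.
#'
#' @param tree A `phylo` tree with positive branch lengths.
#' @param trait_root Length-2 root state (log body, log brain).
#' @param evo_cov 2x2 symmetric PSD evolutionary covariance.
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `log_body`, `log_brain`.
#' @export
simulate_bm_traits <- function(tree, trait_root, evo_cov, seed = 1L) {
  if (any(tree$edge.length < 0)) stop_domain("tree has negative branch lengths")
  C <- phylo_cov(tree)
  Fc <- psd_factor(evo_cov)       # errors if evo_cov is not PSD
  Lc <- psd_factor(unclass(C))
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  Z <- matrix(rnorm(n * 2L), n, 2L)
  X <- matrix(trait_root, n, 2L, byrow = TRUE) + Lc %*% Z %*% t(Fc)
  tibble(species = tree$tip.label, log_body = X[, 1L], log_brain = X[, 2L])
}

#' Simulate log neuron counts from log brain mass
#'
#' Linear allometry on the log scale with i.i.d. Gaussian noise:
#' `log_neurons = intercept + slope * log_brain + N(0, noise_sd)`.
#'
#' @param log_brain Numeric vector of log brain masses.
#' @param slope,intercept Allometric coefficients.
#' @param noise_sd Residual SD (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of log neuron counts.
#' @export
simulate_neurons <- function(log_brain, slope, intercept, noise_sd, seed = 1L) {
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  intercept + slope * log_brain + rnorm(length(log_brain), 0, noise_sd)
}

#' Simulate per-individual yawn events
#'
#' Species latent means follow the model the estimator assumes:
#' `eta_i = beta0 + beta * z_i + b_i + u_i` with `b ~ MVN(0,
#' sigma_phylo^2 C_lambda)` (lambda-transformed unit-height phylogenetic
#' correlation) and `u_i ~ N(0, sigma_species^2)`. Each yawn duration is
#' Gamma with mean `exp(eta_i)` and shape `shape`. When
#' `config$sigma_slope > 0` and `orders` is supplied, per-order slope
#' deviations `g_j ~ N(0, sigma_slope^2)` enter as `(beta + g_j) * z_i`.
#'
#' @param tree A `phylo` tree; `z_predictor` must be named by its tips.
#' @param z_predictor Standardized species-level predictor, aligned to
#'   (named by) the tree tips.
#' @param config A [sim_config()].
#' @param orders Optional factor of taxonomic orders aligned to tips.
#' @param seed Seed; defaults to `config$seed`.
#' @return Tibble of yawn events (`species`, `individual`, `duration`,
#'   `source`); the latent truth (`eta`, `b`, `u`, order deviations) is
#'   attached as `attr(, "truth")`.
#' @export
simulate_yawns <- function(tree, z_predictor, config, orders = NULL,
                           seed = config$seed) {
  tips <- tree$tip.label
  if (is.null(names(z_predictor)) || !identical(names(z_predictor), tips)) {
    stop_domain("z_predictor must be named by, and ordered as, the tree tips")
  }
  n <- length(tips)
  C <- lambda_transform(unit_correlation(tree), config$lambda_sim)
  set.seed(as.integer(seed))
  b <- config$sigma_phylo * drop(psd_factor(C) %*% rnorm(n))
  u <- rnorm(n, 0, config$sigma_species)
  slope_i <- rep(config$beta, n)
  gdev <- NULL
  if (!is.null(orders) && config$sigma_slope > 0) {
    orders <- factor(orders)
    gdev <- rnorm(nlevels(orders), 0, config$sigma_slope)
    names(gdev) <- levels(orders)
    slope_i <- slope_i + gdev[as.integer(orders)]
  }
  eta <- config$beta0 + slope_i * z_predictor + b + u
  mu <- exp(eta)
  m <- config$individuals_per_species
  k <- config$yawns_per_individual
  events <- tibble(
    species = rep(tips, each = m * k),
    individual = rep(sprintf("%s_ind%02d", rep(tips, each = m),
                             rep(seq_len(m), times = n)), each = k),
    duration = NA_real_,
    source = "synthetic"
  )
  events$duration <- rgamma(nrow(events), shape = config$shape,
                            rate = config$shape / rep(mu, each = m * k))
  attr(events, "truth") <- list(eta = eta, b = b, u = u, order_dev = gdev)
  events
}

#' Simulate a complete clade dataset
#'
#' Runs the full generative process: a unit-height Yule tree, correlated
#' Brownian (log body, log brain), allometric neuron counts (total and
#' cortical/pallial), taxonomic orders carved from the tree, and
#' per-individual Gamma yawn durations driven by the within-clade
#' z-score of log brain mass.
#'
#' @param config A [sim_config()].
#' @return List with `events`, `traits` (species trait CSV shape),
#'   `tree`, `z_predictor`, and `truth` (all generative parameter
#'   values, for recovery checks).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 5L)
  tree <- simulate_tree(config$n_species, config$birth_rate, seeds[1L])
  bm <- simulate_bm_traits(tree, config$trait_root, config$evo_cov, seeds[2L])
  log_total <- simulate_neurons(bm$log_brain, config$neuron_slope,
                                config$neuron_intercept,
                                config$neuron_noise_sd, seeds[3L])
  # cortical/pallial counts: a fixed log-offset below total, own noise
  log_cortex <- simulate_neurons(bm$log_brain, config$neuron_slope,
                                 config$neuron_intercept - 0.7,
                                 config$neuron_noise_sd, seeds[4L])
  orders <- assign_orders(tree, config$n_orders)
  z <- as.numeric(scale(bm$log_brain))
  names(z) <- tree$tip.label
  events <- simulate_yawns(tree, z, config, orders = orders, seed = seeds[5L])
  traits <- tibble(
    species = tree$tip.label,
    clade = config$clade,
    order = as.character(orders),
    body_mass = exp(bm$log_body),
    brain_mass = exp(bm$log_brain),
    ecv = NA_real_,
    total_neurons = exp(log_total),
    cortex_neurons = exp(log_cortex)
  )
  truth <- c(unclass(config),
             attr(events, "truth")[c("eta", "b", "u", "order_dev")])
  list(events = events, traits = traits, tree = tree,
       z_predictor = z, truth = truth)
}

# Carve `n_orders` monophyletic groups out of an ultrametric tree by
# cutting it at the depth where the lineage count first reaches n_orders.
assign_orders <- function(tree, n_orders) {
  n <- length(tree$tip.label)
  n_orders <- min(n_orders, n)
  depths <- ape::node.depth.edgelength(tree)
  internal <- sort(depths[(n + 1L):(n + tree$Nnode)])
  # after the k-th branching event there are k+1 lineages
  cut_at <- if (n_orders <= 1L) -1 else
    mean(internal[c(n_orders - 1L, min(n_orders, length(internal)))])
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  group <- vapply(seq_len(n), function(tip) {
    node <- tip
    while (parent[node] != 0L && depths[parent[node]] > cut_at) {
      node <- parent[node]
    }
    node
  }, integer(1))
  factor(sprintf("order%02d", match(group, sort(unique(group)))))
}

#' Write a simulated dataset to disk
#'
#' Emits `events.csv`, `traits.csv`, `tree.nwk` and `truth.json` under
#' `dir`, in the same formats the readers consume (lossless round trip).
#'
#' @param dataset A list from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$events[c("species", "individual", "duration",
                                    "source")],
                   file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  truth$evo_cov <- as.vector(truth$evo_cov)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated dataset back from disk
#' @param dir Directory written by [write_dataset()].
#' @return List with `events`, `traits`, `tree`, `truth`.
#' @export
read_dataset <- function(dir) {
  list(events = read_yawn_events(file.path(dir, "events.csv")),
       traits = read_species_traits(file.path(dir, "traits.csv")),
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
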