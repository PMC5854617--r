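# Virtual fish-community generator. Sites carry latent habitat factors;
# environmental variables are noisy linear views of the latents and species
# occurrence probabilities are logistic in the latents (optionally plus a
# biotic dependence on a parent species). Because the observed environment
# sees some latents only partially, co-predictor species can carry habitat
# information beyond the measured variables -- the premise the cascade
# exploits.

#' Configuration for a virtual community survey
#'
#' @param n_sites number of survey records.
#' @param latent_dims number of latent habitat factors (standard normal).
#' @param species named list; each element a list with `loading` (length
#'   `latent_dims`), `intercept`, optional `parent` (species name) with
#'   `parent_coef`, optional `env_loading` (length = number of
#'   environmental variables, applied to z-scored environment).
#' @param env named list; each element a list with `loading` (length
#'   `latent_dims`), `noise_sd`, and `range = c(min, max)` used to rescale
#'   the raw variable to a field-plausible span.
#' @param target,copredictors species names used by reporting and by
#'   realized-correlation checks.
#' @param seed integer seed.
#' @return An object of class `community_sim_config`.
#' @export
community_sim_config <- function(n_sites, latent_dims, species, env,
                                 target = names(species)[1],
                                 copredictors = character(0),
                                 seed = 1) {
  stopifnot(n_sites >= 1, latent_dims >= 1,
            length(species) >= 1, length(env) >= 1)
  if (is.null(names(species)) || is.null(names(env))) {
    stop("species and env lists must be named", call. = FALSE)
  }
  parents <- vapply(species, function(s) s$parent %||% NA_character_,
                    character(1))
  # reject cyclic biotic dependence by attempting a topological order
  topo_order_species(names(species), parents)
  structure(list(n_sites = as.integer(n_sites),
                 latent_dims = as.integer(latent_dims),
                 species = species, env = env,
                 target = target, copredictors = copredictors,
                 seed = as.integer(seed)),
            class = "community_sim_config")
}

topo_order_species <- function(nms, parents) {
  placed <- character(0)
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(s) {
      p <- parents[[s]]
      is.na(p) || p %in% placed
    }, logical(1))]
    if (!length(ready)) {
      stop("cyclic biotic dependence among: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Simulate a virtual community survey
#'
#' Draws per-site latent factors, builds environmental variables as noisy
#' linear mixes of the latents rescaled to the configured ranges, computes
#' each species' occurrence probability as
#' `plogis(intercept + loading . latents [+ parent_coef * parent occurrence]
#' [+ env_loading . z-scored environment])`, and samples occurrences
#' independently given the probabilities. Identical seeds give identical
#' datasets.
#'
#' @param config a [community_sim_config()].
#' @param compute_truth_cor also estimate the realized tetrachoric
#'   correlation of every species with the target from a large auxiliary
#'   sample (default FALSE).
#' @param n_aux auxiliary sample size for the realized correlations.
#' @return A list with `data` (an unnormalized [survey_dataset()]) and
#'   `truth` (latents, true probabilities, and optionally `realized_r`).
#' @export
simulate_community <- function(config, compute_truth_cor = FALSE,
                               n_aux = 20000) {
  stopifnot(inherits(config, "community_sim_config"))
  draw <- function(n, seed) {
    with_seed(seed, {
      L <- matrix(stats::rnorm(n * config$latent_dims), n,
                  config$latent_dims)
      env_raw <- vapply(config$env, function(v) {
        as.numeric(L %*% v$loading) + stats::rnorm(n, 0, v$noise_sd)
      }, numeric(n))
      env_raw <- matrix(env_raw, nrow = n,
                        dimnames = list(NULL, names(config$env)))
      env_z <- scale(env_raw)
      parents <- vapply(config$species, function(s) {
        s$parent %||% NA_character_
      }, character(1))
      order_sp <- topo_order_species(names(config$species), parents)
      prob <- occ <- matrix(NA_real_, n, length(config$species),
                            dimnames = list(NULL, names(config$species)))
      for (sp in order_sp) {
        s <- config$species[[sp]]
        eta <- s$intercept + as.numeric(L %*% s$loading)
        if (!is.na(parents[[sp]])) {
          eta <- eta + (s$parent_coef %||% 0) * occ[, parents[[sp]]]
        }
        if (!is.null(s$env_loading)) {
          eta <- eta + as.numeric(env_z %*% s$env_loading)
        }
        prob[, sp] <- stats::plogis(eta)
        occ[, sp] <- stats::rbinom(n, 1, prob[, sp])
      }
      list(L = L, env_raw = env_raw, prob = prob, occ = occ)
    })
  }

  d <- draw(config$n_sites, config$seed)
  env_scaled <- vapply(seq_along(config$env), function(j) {
    rng <- config$env[[j]]$range %||% c(0, 1)
    x <- d$env_raw[, j]
    if (max(x) > min(x)) {
      rng[1] + (x - min(x)) / (max(x) - min(x)) * (rng[2] - rng[1])
    } else {
      rep(mean(rng), length(x))
    }
  }, numeric(config$n_sites))
  env_scaled <- matrix(env_scaled, nrow = config$n_sites,
                       dimnames = list(NULL, names(config$env)))

  data <- survey_dataset(
    occurrence = d$occ,
    environment = env_scaled,
    site_ids = sprintf("site%04d", seq_len(config$n_sites)))

  truth <- list(latents = d$L, probabilities = d$prob)
  if (compute_truth_cor) {
    aux <- draw(n_aux, derive_seed(config$seed, 424243))
    others <- setdiff(names(config$species), config$target)
    yt <- aux$occ[, config$target]
    truth$realized_r <- data.frame(
      species = others,
      r = vapply(others, function(sp) {
        tryCatch(
          tetrachoric_r(contingency_from_binary(yt, aux$occ[, sp]))$r,
          error = function(e) NA_real_)
      }, numeric(1)),
      row.names = NULL)
  }
  list(data = data, truth = truth)
}

#' A canned survey shaped like a regional fish-monitoring data set
#'
#' 264 sites, 20 environmental variables, 23 species, three latent habitat
#' factors. The target species and its two co-predictors load strongly on a
#' habitat factor that the measured environment observes only partially
#' (each of twelve variables sees it weakly through heavy noise), which is
#' what makes the co-predictors informative beyond the environmental inputs:
#' recovering the factor requires pooling many weak signals, a statistically
#' expensive readout that the co-predictors' near-deterministic occurrence
#' expresses directly. The
#' remaining species cover weakly correlated taxa, one strongly negatively
#' correlated taxon, and one designated independent "noise" species.
#'
#' @param seed integer seed.
#' @param compute_truth_cor estimate realized tetrachoric correlations with
#'   the target from a large auxiliary sample (default TRUE).
#' @return As [simulate_community()]; the dataset's target species is
#'   `"target"`, co-predictors `"cop1"` and `"cop2"`, the negatively
#'   correlated species `"negcor"`, the independent one `"noise"`.
#' @export
make_benchmark_scenario <- function(seed = 1, compute_truth_cor = TRUE) {
  env <- list()
  ranges <- list(c(0, 1800), c(0, 1.5), c(0, 100), c(0, 100), c(0, 100),
                 c(1, 80), c(0, 100), c(0, 100), c(0, 100), c(0, 100),
                 c(0, 100), c(0, 5), c(0, 100), c(0, 100), c(0, 4),
                 c(5.6, 9.3), c(10, 1850), c(0, 42), c(0.3, 3300),
                 c(0.3, 120))
  for (j in 1:4) {
    env[[sprintf("env%02d", j)]] <-
      list(loading = c(0, 1, 0), noise_sd = 0.5, range = ranges[[j]])
  }
  for (j in 5:8) {
    env[[sprintf("env%02d", j)]] <-
      list(loading = c(0, 0, 1), noise_sd = 0.5, range = ranges[[j]])
  }
  for (j in 9:20) {
    env[[sprintf("env%02d", j)]] <-
      list(loading = c(0.35, 0, 0), noise_sd = 1, range = ranges[[j]])
  }

  species <- list(
    target = list(loading = c(4.0, 0.5, 0), intercept = -0.6),
    cop1 = list(loading = c(9.0, 0.5, 0), intercept = 0.5),
    cop2 = list(loading = c(8.5, 0, 0.5), intercept = -0.5),
    negcor = list(loading = c(-3.5, 0.5, 0.5), intercept = 0),
    noise = list(loading = c(0, 0, 0), intercept = -0.4))
  a_cycle <- c(1.2, 0.6, -0.6, -1.2)
  b_cycle <- c(0.5, -0.5, 1.0, -1.0, 0)
  i_cycle <- c(-1, -0.3, 0.4)
  for (i in 1:18) {
    species[[sprintf("sp%02d", i + 5)]] <- list(
      loading = c(0, a_cycle[(i - 1) %% 4 + 1], b_cycle[(i - 1) %% 5 + 1]),
      intercept = i_cycle[(i - 1) %% 3 + 1])
  }

  cfg <- community_sim_config(
    n_sites = 264, latent_dims = 3, species = species, env = env,
    target = "target", copredictors = c("cop1", "cop2"), seed = seed)
  simulate_community(cfg, compute_truth_cor = compute_truth_cor)
}

#' Dichotomized bivariate-normal pair
#'
#' Draws `n` samples of a standard bivariate normal with correlation `rho`
#' and dichotomizes each margin at its threshold (`1` when the latent
#' exceeds it). Serves as the recovery oracle for the tetrachoric
#' estimator.
#'
#' @param rho latent correlation, `|rho| < 1`.
#' @param thresholds length-2 numeric thresholds (default `c(0, 0)`).
#' @param n sample size.
#' @param seed integer seed; identical seeds give identical vectors.
#' @return A list with binary vectors `x` and `y`.
#' @export
simulate_latent_binary_pair <- function(rho, thresholds = c(0, 0), n,
                                        seed = 1) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("|rho| must be < 1", call. = FALSE)
  }
  stopifnot(length(thresholds) == 2, n >= 1)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    list(x = as.integer(z1 > thresholds[1]),
         y = as.integer(z2 > thresholds[2]))
  })
}
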