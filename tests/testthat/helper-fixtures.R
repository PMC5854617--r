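# Shared fixtures and independent oracles, all built in code.

toy_survey <- function() {
  occ <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0,
                  0, 1, 0, 1, 1, 0, 1, 0,
                  1, 1, 1, 1, 0, 0, 0, 0),
                nrow = 8, ncol = 3,
                dimnames = list(paste0("s", 1:8), c("spA", "spB", "spC")))
  env <- matrix(c(2, 4, 6, 8, 10, 12, 14, 16,
                  0.5, 0.25, 0.75, 1, 0, 0.6, 0.4, 0.9),
                nrow = 8, ncol = 2,
                dimnames = list(paste0("s", 1:8), c("depth", "shade")))
  survey_dataset(occ, env)
}

# Small, fast training configuration for pipeline tests.
quick_config <- function(n_hidden = 3, ...) {
  train_config(n_hidden = n_hidden, weight_decay = 0.003, restarts = 2,
               max_iterations = 150, seed = 42, ...)
}

# A small community where one species is strongly environment-driven and
# another is pure noise; used by baseline and screening tests.
env_driven_survey <- function(n = 200, seed = 7, tgt_coef = 2.5) {
  species <- list(
    tgt = list(loading = c(tgt_coef, 0), intercept = 0),
    indep = list(loading = c(0, 0), intercept = 0))
  env <- list(
    e1 = list(loading = c(1, 0), noise_sd = 0.3, range = c(0, 10)),
    e2 = list(loading = c(0, 1), noise_sd = 0.3, range = c(0, 100)),
    e3 = list(loading = c(0.5, 0.5), noise_sd = 0.5, range = c(0, 1)))
  cfg <- community_sim_config(n_sites = n, latent_dims = 2,
                              species = species, env = env,
                              target = "tgt", seed = seed)
  simulate_community(cfg)$data
}

# A community with a habitat factor hidden from the environment: the target
# and a good candidate share it, so the candidate carries information the
# environmental inputs miss. A pure-noise candidate is included.
hidden_factor_survey <- function(n = 250, seed = 11) {
  species <- list(
    tgt = list(loading = c(3, 1), intercept = 0),
    good = list(loading = c(6, 0.5), intercept = 0),
    junk = list(loading = c(0, 0), intercept = 0))
  env <- list(
    e1 = list(loading = c(0, 1), noise_sd = 0.3, range = c(0, 10)),
    e2 = list(loading = c(0, 1), noise_sd = 0.3, range = c(0, 50)),
    e3 = list(loading = c(0.3, 0), noise_sd = 1, range = c(0, 1)),
    e4 = list(loading = c(0.3, 0), noise_sd = 1, range = c(0, 5)))
  cfg <- community_sim_config(n_sites = n, latent_dims = 2,
                              species = species, env = env,
                              target = "tgt", seed = seed)
  simulate_community(cfg)$data
}

# --- independent oracles ------------------------------------------------

# Bivariate-normal upper-right rectangle probability via an independent
# quadrature (Gauss-Kronrod from pracma) of the density-over-rho integral.
oracle_bvn_upper <- function(tx, ty, rho) {
  base <- stats::pnorm(-tx) * stats::pnorm(-ty)
  if (rho == 0) return(base)
  f <- function(r) {
    exp(-(tx^2 - 2 * r * tx * ty + ty^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  base + pracma::quadgk(f, 0, rho, tol = 1e-10)
}

oracle_tetra_loglik <- function(rho, n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  px <- (n11 + n10) / n
  py <- (n11 + n01) / n
  tx <- stats::qnorm(1 - px)
  ty <- stats::qnorm(1 - py)
  p11 <- oracle_bvn_upper(tx, ty, rho)
  p10 <- px - p11
  p01 <- py - p11
  p00 <- 1 - px - py + p11
  eps <- 1e-12
  n11 * log(max(p11, eps)) + n10 * log(max(p10, eps)) +
    n01 * log(max(p01, eps)) + n00 * log(max(p00, eps))
}

# Brute-force grid maximization of the two-step likelihood: coarse scan,
# then a fine 0.001-step scan around the coarse optimum.
oracle_tetra_grid <- function(n11, n10, n01, n00) {
  if (any(c(n11, n10, n01, n00) == 0)) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  coarse <- seq(-0.95, 0.95, by = 0.05)
  ll <- vapply(coarse, oracle_tetra_loglik, numeric(1),
               n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  centre <- coarse[which.max(ll)]
  fine <- seq(max(-0.999, centre - 0.06), min(0.999, centre + 0.06),
              by = 0.001)
  llf <- vapply(fine, oracle_tetra_loglik, numeric(1),
                n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  fine[which.max(llf)]
}

# Exhaustive best-Youden-cutoff search over midpoints between adjacent
# distinct scores, with the package's documented tie rules re-derived
# independently (loop, no vectorized reuse of package code).
oracle_best_cutoff <- function(scores, obs) {
  uq <- sort(unique(scores))
  if (length(uq) < 2) return(list(cutoff = 0.5, j = NA_real_))
  mids <- (uq[-1] + uq[-length(uq)]) / 2
  best_j <- -Inf
  best_c <- NA_real_
  for (ct in mids) {
    pred <- as.integer(scores >= ct)
    sens <- sum(pred == 1 & obs == 1) / sum(obs == 1)
    spec <- sum(pred == 0 & obs == 0) / sum(obs == 0)
    j <- sens + spec - 1
    replace <- j > best_j + 1e-12 ||
      (abs(j - best_j) <= 1e-12 &&
         (abs(ct - 0.5) < abs(best_c - 0.5) - 1e-12 ||
            (abs(abs(ct - 0.5) - abs(best_c - 0.5)) <= 1e-12 &&
               ct < best_c)))
    if (replace) {
      best_j <- j
      best_c <- ct
    }
  }
  list(cutoff = best_c, j = best_j)
}

# AUC as the Mann-Whitney U probability (ties counted half).
oracle_auc_mw <- function(scores, obs) {
  pos <- scores[obs == 1]
  neg <- scores[obs == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_confusion <- function() {
  repeat {
    v <- stats::rpois(4, lambda = 8)
    m <- structure(list(TP = v[1], FP = v[2], FN = v[3], TN = v[4],
                        n = sum(v)), class = "confusion_matrix")
    if (m$n >= 1 &&
        abs(m$n - cascadeSDM:::kappa_chance_term(m)) > 1e-9) return(m)
  }
}
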