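#' 2x2 contingency table from two binary vectors
#'
#' @param x,y binary (0/1) vectors of equal length.
#' @return An object of class `contingency_2x2` with counts `n11` (joint
#'   presence), `n10` (x only), `n01` (y only), `n00` (joint absence) and
#'   total `n`.
#' @export
contingency_from_binary <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 1) stop("vectors must be non-empty", call. = FALSE)
  if (!is_binary_vector(x) || !is_binary_vector(y)) {
    stop("inputs must contain only 0 and 1", call. = FALSE)
  }
  structure(list(n11 = sum(x == 1 & y == 1),
                 n10 = sum(x == 1 & y == 0),
                 n01 = sum(x == 0 & y == 1),
                 n00 = sum(x == 0 & y == 0),
                 n = length(x)),
            class = "contingency_2x2")
}

# Standard bivariate normal CDF P(Z1 <= h, Z2 <= k) with correlation rho,
# via the one-dimensional integral of the bivariate density over the
# correlation parameter (the classic reduction; exact at rho = 0).
bvn_lower <- function(h, k, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    if (k == Inf) return(stats::pnorm(h))
  }
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  integrand <- function(r) {
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  base + stats::integrate(integrand, lower = 0, upper = rho,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
}

tetra_loglik <- function(rho, tab, tx, ty) {
  n <- tab$n11 + tab$n10 + tab$n01 + tab$n00
  px <- (tab$n11 + tab$n10) / n  # P(x = 1)
  py <- (tab$n11 + tab$n01) / n
  # latent presence when Z > threshold; P(Z > t) = p
  p11 <- 1 - stats::pnorm(tx) - stats::pnorm(ty) + bvn_lower(tx, ty, rho)
  p10 <- px - p11
  p01 <- py - p11
  p00 <- 1 - px - py + p11
  eps <- 1e-12
  tab$n11 * log(max(p11, eps)) + tab$n10 * log(max(p10, eps)) +
    tab$n01 * log(max(p01, eps)) + tab$n00 * log(max(p00, eps))
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum-likelihood estimate of the correlation of a latent
#' bivariate normal whose dichotomization produced the table: the latent
#' thresholds are fixed from the margins by the inverse normal, then the
#' table likelihood is maximized over the correlation alone. When any cell
#' is zero, 0.5 is added to every cell (continuity correction) and the
#' `corrected` flag is set.
#'
#' @param table a `contingency_2x2` from [contingency_from_binary()], or a
#'   list/vector with components `n11`, `n10`, `n01`, `n00`.
#' @return An object of class `tetrachoric_cor`: `r`, latent `thresholds`,
#'   `corrected`, `converged`.
#' @export
tetrachoric_r <- function(table) {
  tab <- as.list(table)[c("n11", "n10", "n01", "n00")]
  if (any(vapply(tab, is.null, logical(1)))) {
    stop("table must provide n11, n10, n01, n00", call. = FALSE)
  }
  if (any(unlist(tab) < 0)) stop("negative cell count", call. = FALSE)
  if ((tab$n11 + tab$n10) == 0 || (tab$n01 + tab$n00) == 0 ||
      (tab$n11 + tab$n01) == 0 || (tab$n10 + tab$n00) == 0) {
    stop("degenerate margin: one variable is constant", call. = FALSE)
  }
  corrected <- any(unlist(tab) == 0)
  if (corrected) tab <- lapply(tab, function(v) v + 0.5)
  n <- tab$n11 + tab$n10 + tab$n01 + tab$n00
  px <- (tab$n11 + tab$n10) / n
  py <- (tab$n11 + tab$n01) / n
  tx <- stats::qnorm(1 - px)
  ty <- stats::qnorm(1 - py)
  bound <- 0.9999
  opt <- stats::optimize(tetra_loglik, interval = c(-bound, bound),
                         tab = tab, tx = tx, ty = ty,
                         maximum = TRUE, tol = 1e-6)
  r <- opt$maximum
  structure(list(r = r,
                 thresholds = c(x = tx, y = ty),
                 corrected = corrected,
                 converged = abs(r) < bound - 1e-5),
            class = "tetrachoric_cor")
}

#' @export
print.tetrachoric_cor <- function(x, ...) {
  cat(sprintf("tetrachoric r = %.4f (thresholds %.3f, %.3f)%s\n",
              x$r, x$thresholds[1], x$thresholds[2],
              if (x$corrected) " [zero-cell corrected]" else ""))
  invisible(x)
}

#' Rank species by tetrachoric correlation with a target
#'
#' Computes the tetrachoric correlation between the target species and every
#' other species in the dataset and orders candidates by decreasing absolute
#' correlation. Species whose occurrence column is constant cannot support an
#' estimate; they are retained in the output with `r = NA` rather than being
#' dropped silently.
#'
#' @param data a [survey_dataset()].
#' @param target target species name.
#' @return A data frame with columns `species`, `r`, `corrected`,
#'   `converged`, sorted by descending `|r|` (NA last).
#' @export
correlation_ranking <- function(data, target) {
  validate_survey(data)
  if (!target %in% data$species_names) {
    stop("unknown target species: ", target, call. = FALSE)
  }
  others <- setdiff(data$species_names, target)
  if (length(others) < 1) {
    stop("need at least two species to rank", call. = FALSE)
  }
  yt <- data$occurrence[, target]
  rows <- lapply(others, function(sp) {
    ys <- data$occurrence[, sp]
    res <- tryCatch(
      tetrachoric_r(contingency_from_binary(yt, ys)),
      error = function(e) NULL)
    if (is.null(res)) {
      data.frame(species = sp, r = NA_real_, corrected = NA,
                 converged = NA)
    } else {
      data.frame(species = sp, r = res$r, corrected = res$corrected,
                 converged = res$converged)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$r), -abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
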