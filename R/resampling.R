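#' Environment-mixing resampling null for a trait pair
#'
#' The masking test: can intraspecific divergence between environments
#' weaken an interspecific trait correlation when species are sampled
#' haphazardly across environments? For each of B replicate datasets every
#' species independently contributes its (x, y) trait pair from either the
#' greenhouse or the field table (one coin per species per replicate, equal
#' probability by default, so a species' phenotype always comes from a
#' single environment). The squared Pearson correlation across species is
#' recorded for each replicate and compared with the observed R^2 among
#' species in the standardized greenhouse environment: an observed R^2 at
#' or above the 95th quantile of the simulated distribution indicates that
#' mixed-environment sampling weakens the pair's correlation.
#'
#' @param greenhouse,field \code{\link{trait_table}}s sharing species and
#'   trait names; species with a complete (x, y) pair in both tables are
#'   used (the intersection is logged).
#' @param trait_pair character vector of two trait names.
#' @param B number of replicate datasets (default 10000; fewer than 100
#'   triggers a warning about unstable quantiles).
#' @param seed integer seed; fixed seed gives identical replicate vectors.
#' @param prob_field probability a species is drawn from the field table
#'   (0.5 for the canonical equal-probability null).
#' @param per_trait_independent sensitivity-analysis mode in which the two
#'   traits of a species are drawn with independent coins; not the default
#'   because a real specimen's phenotype comes from one environment.
#' @return object of class \code{resample_result}: trait_pair, observed_r2,
#'   simulated_r2 (length B), quantile_position, exceeds_95th, degenerate,
#'   n_species, B, seed.
#' @export
resample_mixed_environments <- function(greenhouse, field, trait_pair,
                                        B = 10000, seed = 1L,
                                        prob_field = 0.5,
                                        per_trait_independent = FALSE) {
  stopifnot(inherits(greenhouse, "trait_table"),
            inherits(field, "trait_table"), length(trait_pair) == 2)
  if (!all(trait_pair %in% trait_names(greenhouse)) ||
      !all(trait_pair %in% trait_names(field)))
    stop("trait pair not present in both tables")
  if (B < 100) warning("B < 100: simulated quantiles will be unstable")

  G <- greenhouse$traits[, trait_pair, drop = FALSE]
  F <- field$traits[, trait_pair, drop = FALSE]
  shared <- intersect(rownames(G)[stats::complete.cases(G)],
                      rownames(F)[stats::complete.cases(F)])
  if (length(shared) < 5)
    stop("fewer than 5 species shared between environments")
  message(length(shared), " species enter the ", trait_pair[1], "-",
          trait_pair[2], " resampling")
  G <- G[shared, , drop = FALSE]
  F <- F[shared, , drop = FALSE]
  S <- length(shared)

  # same arithmetic path as the replicates, so identical environments give
  # bitwise-identical observed and simulated values
  observed_r2 <- row_cor(matrix(G[, 1], 1), matrix(G[, 2], 1))^2

  set.seed(seed)
  gx <- matrix(G[, 1], B, S, byrow = TRUE)
  gy <- matrix(G[, 2], B, S, byrow = TRUE)
  fx <- matrix(F[, 1], B, S, byrow = TRUE)
  fy <- matrix(F[, 2], B, S, byrow = TRUE)
  coin_x <- matrix(stats::runif(B * S) < prob_field, B, S)
  coin_y <- if (per_trait_independent)
    matrix(stats::runif(B * S) < prob_field, B, S) else coin_x
  X <- ifelse(coin_x, fx, gx)
  Y <- ifelse(coin_y, fy, gy)
  simulated_r2 <- row_cor(X, Y)^2

  qp <- observed_quantile_position(observed_r2, simulated_r2)
  degenerate <- diff(range(simulated_r2)) < 1e-12
  structure(list(trait_pair = trait_pair, observed_r2 = observed_r2,
                 simulated_r2 = simulated_r2, quantile_position = qp,
                 exceeds_95th = if (degenerate) FALSE else qp >= 0.95,
                 degenerate = degenerate, n_species = S, B = B,
                 seed = seed),
            class = "resample_result")
}

# rowwise Pearson correlation of two matrices
row_cor <- function(X, Y) {
  S <- ncol(X)
  sx <- rowSums(X); sy <- rowSums(Y)
  num <- rowSums(X * Y) - sx * sy / S
  den <- sqrt((rowSums(X^2) - sx^2 / S) * (rowSums(Y^2) - sy^2 / S))
  num / den
}

#' Position of an observed value in a simulated distribution
#'
#' The empirical quantile position with a "<=" tie rule, so an observed
#' value equal to the maximum has position 1 and one equal to the minimum
#' has position 1/B.
#'
#' @param observed observed statistic.
#' @param simulated nonempty numeric vector of simulated statistics.
#' @return fraction of simulated values <= observed.
#' @export
observed_quantile_position <- function(observed, simulated) {
  if (length(simulated) == 0) stop("empty simulated vector")
  mean(simulated <= observed)
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("Environment-mixing resampling: %s vs %s (%d species, B = %d)\n",
              x$trait_pair[1], x$trait_pair[2], x$n_species, x$B))
  cat(sprintf(
    "  observed R2 (greenhouse) = %.3f; simulated mean = %.3f, 95th = %.3f\n",
    x$observed_r2, mean(x$simulated_r2),
    unname(stats::quantile(x$simulated_r2, 0.95, type = 7))))
  cat(sprintf("  quantile position = %.3f -> exceeds 95th: %s%s\n",
              x$quantile_position, x$exceeds_95th,
              if (x$degenerate) " (degenerate spread)" else ""))
  invisible(x)
}
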