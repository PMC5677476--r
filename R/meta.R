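#' Fisher z transform of a correlation
#' @param r correlation with |r| < 1.
#' @return z = atanh(r); its sampling variance is approximately 1/(n - 3).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("boundary error: |r| must be < 1")
  atanh(r)
}

#' Inverse Fisher z transform
#' @param z Fisher z value.
#' @return r = tanh(z).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Site-level trait-growth correlations
#'
#' Computes, for each site, the Pearson correlation between species trait
#' means and a species-level growth measure (RGR or RGR95), together with
#' its Fisher z transform and within-site variance 1/(n - 3). Sites with
#' fewer than four species are excluded (the z variance is undefined) and
#' logged; a site correlation numerically at |r| = 1 is nudged to 0.9999
#' with a warning rather than dropped.
#'
#' @param growth_by_site data.frame from \code{\link{species_summary}}
#'   (columns species, site, n, rgr_mean, rgr95).
#' @param traits a \code{\link{trait_table}} of species means.
#' @param trait trait name to correlate.
#' @param growth_measure \code{"RGR"} (mean) or \code{"RGR95"}.
#' @return data.frame with columns site, trait, growth_measure, r, n, z, v.
#' @export
site_correlations <- function(growth_by_site, traits, trait,
                              growth_measure = c("RGR95", "RGR")) {
  growth_measure <- match.arg(growth_measure)
  stopifnot(inherits(traits, "trait_table"),
            trait %in% trait_names(traits))
  gcol <- if (growth_measure == "RGR95") "rgr95" else "rgr_mean"
  tvals <- stats::setNames(traits$traits[, trait], traits$species)
  out <- list()
  for (site in unique(growth_by_site$site)) {
    sub <- growth_by_site[growth_by_site$site == site, , drop = FALSE]
    sub <- sub[sub$species %in% names(tvals), , drop = FALSE]
    x <- tvals[sub$species]
    y <- sub[[gcol]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) {
      message("site ", site, " excluded from meta-analysis (",
              sum(ok), " species < 4)")
      next
    }
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("site ", site, " excluded (zero variance)")
      next
    }
    r <- stats::cor(x, y)
    if (abs(r) >= 1 - 1e-12) {
      warning("site ", site, ": |r| numerically 1, nudged to 0.9999")
      r <- sign(r) * 0.9999
    }
    out[[length(out) + 1L]] <- data.frame(
      site = site, trait = trait, growth_measure = growth_measure,
      r = r, n = sum(ok), z = fisher_z(r), v = 1 / (sum(ok) - 3))
  }
  if (length(out) == 0)
    return(data.frame(site = character(), trait = character(),
                      growth_measure = character(), r = numeric(),
                      n = integer(), z = numeric(), v = numeric()))
  do.call(rbind, out)
}

#' Random-effects pooling of site-level correlations
#'
#' Pools Fisher-z transformed correlations across sites with site as a
#' random effect, the DerSimonian-Laird estimator for the between-site
#' variance tau^2 (REML available via \code{method}). The pooled z, its
#' 95\% CI and the heterogeneity Q are back-transformed to the r scale.
#'
#' @param sites data.frame as returned by \code{\link{site_correlations}}
#'   (needs columns z, v; r and n are carried along when present).
#' @param method tau^2 estimator passed to \code{metafor::rma.uni}
#'   (\code{"DL"} default, or \code{"REML"}).
#' @return object of class \code{meta_pool}: pooled_z, pooled_r, ci95 (r
#'   scale), tau_squared, Q, k, method, no_pooling flag.
#' @export
dl_random_effects_pool <- function(sites, method = "DL") {
  k <- nrow(sites)
  if (k == 0) stop("no sites to pool")
  if (k == 1) {
    z <- sites$z[1]; v <- sites$v[1]
    ci <- inv_fisher_z(z + c(-1, 1) * stats::qnorm(0.975) * sqrt(v))
    return(structure(list(pooled_z = z, pooled_r = inv_fisher_z(z),
                          ci95 = ci, tau_squared = 0, Q = 0, k = 1L,
                          method = method, no_pooling = TRUE),
                     class = "meta_pool"))
  }
  fit <- metafor::rma.uni(yi = sites$z, vi = sites$v, method = method)
  z <- as.numeric(fit$beta)
  ci <- inv_fisher_z(c(fit$ci.lb, fit$ci.ub))
  structure(list(pooled_z = z, pooled_r = inv_fisher_z(z), ci95 = ci,
                 tau_squared = fit$tau2, Q = fit$QE, k = as.integer(k),
                 method = method, no_pooling = FALSE),
            class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf(
    "Random-effects pooled correlation (%s%s): r = %.4f [%.4f, %.4f]\n",
    x$method, if (x$no_pooling) ", single site" else "",
    x$pooled_r, x$ci95[1], x$ci95[2]))
  cat(sprintf("  k = %d sites, tau^2 = %.4f, Q = %.4f\n", x$k,
              x$tau_squared, x$Q))
  invisible(x)
}
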