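#' Configuration for a synthetic whole-plant trait study
#'
#' Bundles the generative assumptions the analysis relies on: species means
#' evolve under correlated Brownian motion on a phylogeny; each species has
#' an intraspecific reaction norm (a displacement between a standardized
#' greenhouse and an unstandardized field environment); individuals add
#' multiplicative measurement noise; growth follows a composite trait score
#' in the greenhouse and is additionally one-sidedly suppressed in the
#' field.
#'
#' Defaults emulate the study structure the pipeline targets: 56 temperate
#' tree species, seven tissue traits with strong positive evolutionary
#' correlation (a single fast-slow axis), greenhouse replicate numbers of
#' about nine per species, three field sites with patchy occupancy, and
#' divergent field responses (LMA decreases in shade while WD and RTD
#' increase).
#'
#' @param n_species number of species (>= 4).
#' @param trait_names the seven trait identifiers.
#' @param evo_correlation 7x7 positive-semidefinite evolutionary correlation
#'   matrix with unit diagonal (default: equicorrelation 0.8).
#' @param evo_variances per-trait Brownian rates (trait-unit^2 per unit
#'   branch length; trees have unit depth, so these are the interspecific
#'   variances at the tips).
#' @param root_state ancestral trait values (trait units).
#' @param shift_spec a \code{\link{trait_shift_spec}}.
#' @param n_replicates_per_species individuals measured per species.
#' @param replicate_cv coefficient of variation of individual measurement
#'   noise (fraction, >= 0).
#' @param n_sites number of field sites.
#' @param site_occupancy probability a species occurs at a given field site.
#' @param rgr_baseline mean RGR (1/yr) at an average composite trait score.
#' @param rgr_trait_slope signed change in RGR per SD of composite trait
#'   score (negative: dense-tissue species grow slower).
#' @param suppression_sd SD of the half-normal growth suppression applied to
#'   field individuals (log scale, 1/yr); 0 disables suppression.
#' @param greenhouse_interval,field_interval census intervals (years).
#' @param seed integer master seed.
#'
#' @return object of class \code{synthetic_config} (a validated list).
#' @export
synthetic_config <- function(n_species = 56,
                             trait_names = TRAIT_NAMES,
                             evo_correlation = equicorrelation(0.8,
                               length(trait_names)),
                             evo_variances = c(LMA = 30^2, LTD = 0.08^2,
                               LDMC = 0.06^2, WD = 0.08^2, WDMC = 0.07^2,
                               RTD = 0.08^2, RDMC = 0.05^2),
                             root_state = c(LMA = 140, LTD = 0.35,
                               LDMC = 0.35, WD = 0.50, WDMC = 0.45,
                               RTD = 0.30, RDMC = 0.25),
                             shift_spec = trait_shift_spec(),
                             n_replicates_per_species = 9,
                             replicate_cv = 0.15,
                             n_sites = 3,
                             site_occupancy = 0.6,
                             rgr_baseline = 1.5,
                             rgr_trait_slope = -0.4,
                             suppression_sd = 1.0,
                             greenhouse_interval = 0.31,
                             field_interval = 2,
                             seed = 1L) {
  p <- length(trait_names)
  evo_correlation <- as.matrix(evo_correlation)
  if (n_species < 4) stop("invalid argument: n_species must be >= 4")
  if (!isTRUE(all.equal(evo_correlation, t(evo_correlation))) ||
      any(abs(diag(evo_correlation) - 1) > 1e-8))
    stop("invalid argument: evo_correlation must be symmetric with unit diagonal")
  if (min(eigen(evo_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("invalid argument: evo_correlation must be positive semidefinite")
  if (any(evo_variances < 0)) stop("invalid argument: negative Brownian rate")
  if (replicate_cv < 0) stop("invalid argument: replicate_cv must be >= 0")
  stopifnot(length(evo_variances) == p, length(root_state) == p,
            n_replicates_per_species >= 1, n_sites >= 1,
            site_occupancy > 0, site_occupancy <= 1)
  dimnames(evo_correlation) <- list(trait_names, trait_names)
  names(evo_variances) <- names(root_state) <- trait_names
  structure(list(n_species = as.integer(n_species),
                 trait_names = trait_names,
                 evo_correlation = evo_correlation,
                 evo_variances = evo_variances, root_state = root_state,
                 shift_spec = shift_spec,
                 n_replicates_per_species =
                   as.integer(n_replicates_per_species),
                 replicate_cv = replicate_cv, n_sites = as.integer(n_sites),
                 site_occupancy = site_occupancy,
                 rgr_baseline = rgr_baseline,
                 rgr_trait_slope = rgr_trait_slope,
                 suppression_sd = suppression_sd,
                 greenhouse_interval = greenhouse_interval,
                 field_interval = field_interval, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Equicorrelation matrix
#' @param rho common off-diagonal correlation.
#' @param p dimension.
#' @return p x p correlation matrix.
#' @export
equicorrelation <- function(rho, p = 7) {
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}

#' Intraspecific greenhouse-to-field reaction norms
#'
#' Per-trait mean displacement (trait units) and between-species SD of the
#' displacement, applied additively when moving a species from the
#' standardized greenhouse to the field. The defaults are divergent in the
#' sense of the masking hypothesis: LMA decreases under field shade while
#' wood and root tissue densities increase.
#'
#' Between-species variation in the displacement can be correlated across
#' traits via \code{shift_correlation}: a latent per-species environment
#' exposure (e.g. microsite light) moves several organ traits together,
#' with opposite signs for divergent responses. The identity default keeps
#' displacements independent across traits.
#'
#' @param mean_shift named per-trait mean displacement (field minus
#'   greenhouse, trait units).
#' @param shift_sd named per-trait between-species SD of the displacement
#'   (>= 0).
#' @param shift_correlation correlation matrix of the per-species
#'   displacements across traits (positive semidefinite, unit diagonal;
#'   default identity).
#' @return object of class \code{trait_shift_spec}.
#' @export
trait_shift_spec <- function(mean_shift = c(LMA = -30, LTD = 0, LDMC = 0,
                                            WD = 0.08, WDMC = 0,
                                            RTD = 0.08, RDMC = 0),
                             shift_sd = c(LMA = 10, LTD = 0, LDMC = 0,
                                          WD = 0.025, WDMC = 0,
                                          RTD = 0.025, RDMC = 0),
                             shift_correlation = diag(length(mean_shift))) {
  stopifnot(identical(names(mean_shift), names(shift_sd)))
  if (any(shift_sd < 0)) stop("invalid argument: shift_sd must be >= 0")
  shift_correlation <- as.matrix(shift_correlation)
  stopifnot(nrow(shift_correlation) == length(mean_shift),
            isTRUE(all.equal(shift_correlation, t(shift_correlation))),
            all(abs(diag(shift_correlation) - 1) < 1e-8))
  dimnames(shift_correlation) <- list(names(mean_shift), names(mean_shift))
  structure(list(mean_shift = mean_shift, shift_sd = shift_sd,
                 shift_correlation = shift_correlation),
            class = "trait_shift_spec")
}

#' Divergent-exposure shift specification
#'
#' A convenience constructor for the masking mechanism: a single latent
#' environment-exposure axis per species displaces LMA downward while
#' displacing wood and root tissue density upward (perfectly correlated
#' responses with opposite signs), on top of the mean displacement.
#'
#' @param response_sd named SDs of the exposure-driven displacement for the
#'   responding traits (others 0).
#' @param response_sign named signs of each responding trait's loading on
#'   the exposure axis.
#' @param mean_shift as in \code{\link{trait_shift_spec}}.
#' @return a \code{\link{trait_shift_spec}} with a rank-1 correlated
#'   displacement structure.
#' @export
exposure_shift_spec <- function(response_sd = c(LMA = 45, LTD = 0,
                                  LDMC = 0, WD = 0.12, WDMC = 0,
                                  RTD = 0.12, RDMC = 0),
                                response_sign = c(LMA = -1, LTD = 0,
                                  LDMC = 0, WD = 1, WDMC = 0, RTD = 1,
                                  RDMC = 0),
                                mean_shift = c(LMA = -30, LTD = 0,
                                  LDMC = 0, WD = 0.08, WDMC = 0,
                                  RTD = 0.08, RDMC = 0)) {
  b <- response_sign
  R <- outer(b, b)
  diag(R) <- 1
  trait_shift_spec(mean_shift = mean_shift, shift_sd = response_sd,
                   shift_correlation = R)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' A strictly bifurcating ultrametric tree rescaled to unit root-to-tip
#' depth, with tips labelled \code{sp001, sp002, ...}. Deterministic for a
#' fixed seed.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an \code{ape::phylo} tree.
#' @export
generate_yule_tree <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("invalid argument: n_species must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate correlated Brownian-motion species means on a tree
#'
#' Draws the species x trait matrix from the matrix-normal distribution
#' with row covariance C (the phylogenetic covariance of the tree) and
#' column covariance D R D, where R is the evolutionary correlation matrix
#' and D the diagonal of per-trait Brownian-rate square roots. Marginal
#' per-trait tip variance is tip depth times the rate.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed (default: the config's seed).
#' @return a \code{\link{trait_table}} of species means
#'   (environment \code{"cultivated"}).
#' @export
simulate_bm_traits <- function(tree, config, seed = config$seed) {
  C <- ape::vcv(tree)
  D <- diag(sqrt(config$evo_variances), length(config$evo_variances))
  S <- D %*% config$evo_correlation %*% D
  set.seed(seed)
  Z <- matrix(stats::rnorm(nrow(C) * ncol(S)), nrow(C), ncol(S))
  X <- matrix_sqrt(C) %*% Z %*% t(matrix_sqrt(S))
  X <- sweep(X, 2, config$root_state, `+`)
  dimnames(X) <- list(rownames(C), config$trait_names)
  trait_table(X[tree$tip.label, , drop = FALSE], environment = "cultivated")
}

# symmetric PSD square root via eigen decomposition (chol fails on PSD)
matrix_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("invalid argument: matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Apply intraspecific environment shifts to a trait table
#'
#' Field values are greenhouse values plus a per-species displacement drawn
#' Normal(mean_shift, shift_sd^2) per trait. Trait values are floored at a
#' small fraction of the greenhouse value so that additive shifts cannot
#' produce non-positive tissue traits; dry-matter fractions are capped just
#' below 1.
#'
#' @param greenhouse a \code{\link{trait_table}} of greenhouse means.
#' @param spec a \code{\link{trait_shift_spec}} naming the same traits.
#' @param seed integer seed.
#' @param floor_frac positive floor as a fraction of the greenhouse value.
#' @return a \code{\link{trait_table}} with environment
#'   \code{"wild_juvenile"}.
#' @export
apply_environment_shifts <- function(greenhouse, spec, seed = 1L,
                                     floor_frac = 0.02) {
  stopifnot(inherits(greenhouse, "trait_table"),
            inherits(spec, "trait_shift_spec"))
  if (!identical(sort(trait_names(greenhouse)), sort(names(spec$mean_shift))))
    stop("invalid argument: trait names of table and shift spec differ")
  G <- greenhouse$traits
  tn <- colnames(G)
  set.seed(seed)
  D <- diag(spec$shift_sd[tn], length(tn))
  Sig <- D %*% spec$shift_correlation[tn, tn] %*% D
  Z <- matrix(stats::rnorm(nrow(G) * length(tn)), nrow(G))
  delta <- Z %*% t(matrix_sqrt(Sig))
  delta <- sweep(delta, 2, spec$mean_shift[tn], `+`)
  F <- G + delta
  lo <- floor_frac * abs(G)
  n_floor <- sum(F < lo)
  if (n_floor > 0) {
    warning(n_floor, " shifted value(s) floored at ", floor_frac,
            " of the greenhouse value")
    F <- pmax(F, lo)
  }
  # dry-matter fractions that a shift pushed above 1 are capped; untouched
  # values pass through so a zero spec is the exact identity
  dmc <- grepl("DMC$", tn)
  cap <- sweep(F, 2, dmc, `*`) > 0.999 & G <= 0.999
  F[cap] <- 0.999
  trait_table(F, greenhouse$counts, environment = "wild_juvenile")
}

#' Generate individual replicate measurements from species means
#'
#' Adds mean-preserving multiplicative lognormal noise of the given CV to
#' each species' trait values and back-constructs raw organ measurements
#' (leaf area/thickness/masses, wood segment dimensions/masses, root
#' volume/masses) so that the \code{derive_*} operations recover the noisy
#' trait values exactly. Leaf area, wood segment dimensions and root volume
#' are held at protocol-typical constants; masses and thickness absorb the
#' trait variation.
#'
#' @param means a \code{\link{trait_table}} of species means containing the
#'   seven canonical traits.
#' @param n replicates per species (>= 1).
#' @param cv coefficient of variation of the noise (>= 0).
#' @param seed integer seed.
#' @return data.frame of raw measurements, one row per individual, with the
#'   column schema read by \code{\link{derive_individual_traits}}.
#' @export
generate_individual_replicates <- function(means, n, cv, seed = 1L) {
  stopifnot(inherits(means, "trait_table"))
  if (n < 1) stop("invalid argument: n must be >= 1")
  if (cv < 0) stop("invalid argument: cv must be >= 0")
  M <- means$traits[, TRAIT_NAMES, drop = FALSE]
  if (anyNA(M)) stop("species means must be complete for all seven traits")
  sp <- rownames(M)
  sigma <- sqrt(log(1 + cv^2))
  set.seed(seed)
  rows <- M[rep(seq_along(sp), each = n), , drop = FALSE]
  if (cv > 0) {
    noise <- exp(matrix(stats::rnorm(length(rows), 0, sigma),
                        nrow(rows), ncol(rows)) - sigma^2 / 2)
    rows <- rows * noise
  }
  dmc <- grepl("DMC$", colnames(rows))
  rows[, dmc] <- pmin(rows[, dmc, drop = FALSE], 0.999)

  leaf_area <- 25                         # cm2
  wood_len <- 20; wood_diam <- 4          # mm
  root_vol <- 100; root_len <- 500        # mm3, mm
  wood_vol <- pi * (wood_diam / 2)^2 * wood_len
  leaf_dry <- rows[, "LMA"] * leaf_area * 1e-4          # g
  data.frame(
    species = rep(sp, each = n),
    individual = paste0(rep(sp, each = n), "_i",
                        rep(seq_len(n), times = length(sp))),
    environment = means$environment,
    leaf_area_cm2 = leaf_area,
    leaf_thickness_mm = (leaf_dry * 1000) /
      (rows[, "LTD"] * leaf_area * 100),
    leaf_fresh_g = leaf_dry / rows[, "LDMC"],
    leaf_dry_g = leaf_dry,
    wood_length_mm = wood_len,
    wood_diameter_a_mm = wood_diam,
    wood_diameter_b_mm = wood_diam,
    wood_fresh_mg = rows[, "WD"] * wood_vol / rows[, "WDMC"],
    wood_dry_mg = rows[, "WD"] * wood_vol,
    root_volume_mm3 = root_vol,
    root_length_mm = root_len,
    root_fresh_mg = rows[, "RTD"] * root_vol / rows[, "RDMC"],
    root_dry_mg = rows[, "RTD"] * root_vol,
    row.names = NULL
  )
}

#' Generate repeated stem-measurement growth records
#'
#' Each species' true RGR is a linear function of its standardized composite
#' trait score (the mean z-score across the seven traits); field individuals
#' are additionally suppressed by a one-sided half-normal term (suppression
#' can only lower growth). Initial height and diameter are drawn from a
#' lognormal size distribution and final dimensions are solved so that
#' \code{\link{compute_rgr}} returns the intended RGR exactly (isometric
#' growth: d and h share the log increment RGR * dt / 3).
#'
#' @param traits a \code{\link{trait_table}} of species means (the
#'   environment whose growth is being generated).
#' @param config a \code{\link{synthetic_config}}.
#' @param environment \code{"cultivated"} (single greenhouse site, no
#'   suppression) or \code{"wild_juvenile"} (spread over
#'   \code{config$n_sites} sites with occupancy sampling and suppression).
#' @param seed integer seed.
#' @return data.frame of growth records: species, individual, site,
#'   environment, h1, d1, h2, d2, t1, t2 (heights cm, diameters mm,
#'   times years).
#' @export
generate_growth_trajectories <- function(traits, config,
                                         environment = "cultivated",
                                         seed = config$seed) {
  if (!environment %in% c("cultivated", "wild_juvenile"))
    stop("invalid argument: unknown environment label '", environment, "'")
  M <- traits$traits[, config$trait_names, drop = FALSE]
  if (anyNA(M)) stop("trait table must be complete for the composite score")
  score <- rowMeans(scale(M))
  score <- as.numeric(scale(score))
  true_rgr <- config$rgr_baseline + config$rgr_trait_slope * score
  names(true_rgr) <- rownames(M)

  set.seed(seed)
  sp <- rownames(M)
  if (environment == "cultivated") {
    site_of <- lapply(sp, function(s) "greenhouse")
    dt <- config$greenhouse_interval
  } else {
    site_names <- sprintf("site%02d", seq_len(config$n_sites))
    site_of <- lapply(sp, function(s) {
      occ <- site_names[stats::runif(config$n_sites) < config$site_occupancy]
      if (length(occ) == 0) occ <- sample(site_names, 1)
      occ
    })
    dt <- config$field_interval
  }
  recs <- list()
  for (i in seq_along(sp)) {
    for (site in site_of[[i]]) {
      n <- config$n_replicates_per_species
      r <- rep(true_rgr[i], n)
      if (environment == "wild_juvenile" && config$suppression_sd > 0)
        r <- r - abs(stats::rnorm(n, 0, config$suppression_sd))
      h1 <- stats::rlnorm(n, log(30), 0.25)   # cm
      d1 <- stats::rlnorm(n, log(4), 0.25)    # mm
      g <- r * dt / 3
      recs[[length(recs) + 1L]] <- data.frame(
        species = sp[i],
        individual = paste0(sp[i], "_", site, "_g", seq_len(n)),
        site = site, environment = environment,
        h1 = h1, d1 = d1, h2 = h1 * exp(g), d2 = d1 * exp(g),
        t1 = 0, t2 = dt)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Runs the whole generative chain: phylogeny, greenhouse species means
#' under correlated Brownian motion, field means via intraspecific reaction
#' norms, individual replicate measurements for both environments, and
#' growth records (greenhouse and multi-site field). Sub-stage seeds are
#' derived from the config seed, so the study is fully reproducible.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return object of class \code{synthetic_study}: list with
#'   \code{phylogeny}, \code{greenhouse_traits}, \code{field_traits},
#'   \code{individuals}, \code{growth_records}, \code{config}.
#' @export
generate_study <- function(config = synthetic_config()) {
  s <- config$seed
  tree <- generate_yule_tree(config$n_species, seed = s)
  gh <- simulate_bm_traits(tree, config, seed = s + 1L)
  fld <- apply_environment_shifts(gh, config$shift_spec, seed = s + 2L)
  ind <- rbind(
    generate_individual_replicates(gh, config$n_replicates_per_species,
                                   config$replicate_cv, seed = s + 3L),
    generate_individual_replicates(fld, config$n_replicates_per_species,
                                   config$replicate_cv, seed = s + 4L))
  growth <- rbind(
    generate_growth_trajectories(gh, config, "cultivated", seed = s + 5L),
    generate_growth_trajectories(fld, config, "wild_juvenile",
                                 seed = s + 6L))
  structure(list(phylogeny = tree, greenhouse_traits = gh,
                 field_traits = fld, individuals = ind,
                 growth_records = growth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic whole-plant trait study\n")
  cat(sprintf("  %d species, %d traits, seed %d\n", x$config$n_species,
              length(x$config$trait_names), x$config$seed))
  cat(sprintf("  %d individual measurements, %d growth records\n",
              nrow(x$individuals), nrow(x$growth_records)))
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Writes \code{tree.nwk} (Newick), \code{individuals.csv},
#' \code{growth.csv} and \code{config.json}; the returned manifest lists
#' each file with its row count. The bundle is a sufficient input for
#' \code{\link{run_pipeline}}.
#'
#' @param study a \code{synthetic_study}.
#' @param directory output directory (created if needed).
#' @return data.frame manifest (file, rows), invisibly written as part of
#'   the bundle too.
#' @export
write_study_bundle <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  if (length(study$phylogeny$tip.label) == 0 ||
      nrow(study$individuals) == 0)
    stop("empty species set: nothing to write")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot write to ", directory)
  ape::write.tree(study$phylogeny, file.path(directory, "tree.nwk"))
  utils::write.csv(study$individuals,
                   file.path(directory, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(study$growth_records,
                   file.path(directory, "growth.csv"), row.names = FALSE)
  cfg <- study$config
  cfg$evo_correlation <- as.data.frame(cfg$evo_correlation)
  jsonlite::write_json(cfg, file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c("tree.nwk", "individuals.csv", "growth.csv", "config.json")
  manifest <- data.frame(
    file = files,
    rows = c(length(study$phylogeny$tip.label), nrow(study$individuals),
             nrow(study$growth_records), NA),
    md5 = unname(tools::md5sum(file.path(directory, files))))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       digits = NA)
  manifest
}

#' Read a study bundle written by \code{\link{write_study_bundle}}
#' @param directory bundle directory.
#' @return list with \code{phylogeny}, \code{individuals},
#'   \code{growth_records}.
#' @export
read_study_bundle <- function(directory) {
  need <- c("tree.nwk", "individuals.csv", "growth.csv")
  miss <- need[!file.exists(file.path(directory, need))]
  if (length(miss) > 0)
    stop("bundle incomplete, missing: ", paste(miss, collapse = ", "))
  list(phylogeny = read_newick(file.path(directory, "tree.nwk")),
       individuals = utils::read.csv(file.path(directory,
                                               "individuals.csv")),
       growth_records = utils::read.csv(file.path(directory, "growth.csv")))
}
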