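#' Derive leaf economic traits from raw organ measurements
#'
#' Leaf mass per area is dry mass over fresh (one-sided) area; leaf dry
#' matter content is the dry:fresh mass ratio; leaf tissue density is dry
#' mass over fresh volume, the volume being the product of leaf area and
#' thickness.
#'
#' @param area_cm2 fresh leaf area (cm2).
#' @param thickness_mm leaf thickness (mm), measured away from the midrib.
#' @param fresh_mass_g fresh leaf mass (g).
#' @param dry_mass_g oven-dry leaf mass (g).
#'
#' @return data.frame with columns \code{LMA} (g/m2), \code{LDMC}
#'   (fraction) and \code{LTD} (mg/mm3). Vectorized over samples.
#' @examples
#' derive_leaf_traits(25, 0.2, 0.25, 0.05)  # LMA 20, LDMC 0.2, LTD 0.1
#' @export
derive_leaf_traits <- function(area_cm2, thickness_mm, fresh_mass_g,
                               dry_mass_g) {
  check_positive(area_cm2 = area_cm2, thickness_mm = thickness_mm,
                 fresh_mass_g = fresh_mass_g, dry_mass_g = dry_mass_g)
  check_dry_le_fresh(dry_mass_g, fresh_mass_g)
  data.frame(
    LMA  = dry_mass_g / (area_cm2 * 1e-4),
    LDMC = dry_mass_g / fresh_mass_g,
    # dry mass in mg over fresh volume in mm3 (area cm2 -> mm2 is x100)
    LTD  = (dry_mass_g * 1000) / (area_cm2 * 100 * thickness_mm)
  )
}

#' Derive wood economic traits from a stem segment
#'
#' Fresh volume uses the equation for a cylinder with an elliptical
#' cross-section built from the two orthogonal diameters measured with
#' calipers: V = pi * (a/2) * (b/2) * length. Wood density is dry mass over
#' that fresh volume; WDMC is the dry:fresh mass ratio.
#'
#' @param length_mm segment length (mm).
#' @param diameter_a_mm,diameter_b_mm the two orthogonal diameters (mm).
#' @param fresh_mass_mg fresh mass (mg).
#' @param dry_mass_mg oven-dry mass (mg).
#'
#' @return data.frame with columns \code{WD} (mg/mm3), \code{WDMC}
#'   (fraction) and \code{wood_volume_mm3}. Vectorized.
#' @examples
#' derive_wood_traits(20, 4, 5, 300, 150)  # volume 100*pi, WD ~0.477
#' @export
derive_wood_traits <- function(length_mm, diameter_a_mm, diameter_b_mm,
                               fresh_mass_mg, dry_mass_mg) {
  if (missing(diameter_a_mm) || missing(diameter_b_mm) ||
      anyNA(diameter_a_mm) || anyNA(diameter_b_mm))
    stop("invalid measurement: both orthogonal diameters are required")
  check_positive(length_mm = length_mm, diameter_a_mm = diameter_a_mm,
                 diameter_b_mm = diameter_b_mm,
                 fresh_mass_mg = fresh_mass_mg, dry_mass_mg = dry_mass_mg)
  check_dry_le_fresh(dry_mass_mg, fresh_mass_mg)
  volume <- pi * (diameter_a_mm / 2) * (diameter_b_mm / 2) * length_mm
  data.frame(WD = dry_mass_mg / volume, WDMC = dry_mass_mg / fresh_mass_mg,
             wood_volume_mm3 = volume)
}

#' Derive fine-root economic traits
#'
#' Root tissue density is dry mass over fresh volume (from volumetric
#' scanning); RDMC is the dry:fresh mass ratio.
#'
#' @param volume_mm3 fresh root volume (mm3).
#' @param fresh_mass_mg fresh mass after blotting (mg).
#' @param dry_mass_mg oven-dry mass (mg).
#' @param length_mm total root length (mm); carried through but not used by
#'   the density traits.
#'
#' @return data.frame with columns \code{RTD} (mg/mm3) and \code{RDMC}
#'   (fraction). A boundary value RDMC = 1 (dry equals fresh) is kept but
#'   flagged with a warning. Vectorized.
#' @export
derive_root_traits <- function(volume_mm3, fresh_mass_mg, dry_mass_mg,
                               length_mm = NULL) {
  check_positive(volume_mm3 = volume_mm3, fresh_mass_mg = fresh_mass_mg,
                 dry_mass_mg = dry_mass_mg)
  check_dry_le_fresh(dry_mass_mg, fresh_mass_mg)
  rdmc <- dry_mass_mg / fresh_mass_mg
  if (any(rdmc >= 1 - 1e-12))
    warning("RDMC at boundary 1 (dry mass equals fresh mass) for ",
            sum(rdmc >= 1 - 1e-12), " sample(s)")
  data.frame(RTD = dry_mass_mg / volume_mm3, RDMC = rdmc)
}

#' Relative growth rate from two stem measurements
#'
#' RGR is the change in ln(d^2 h) per unit time, d^2 h being a standard
#' proxy linearly related to above-ground mass:
#' (ln(d2^2 h2) - ln(d1^2 h1)) / (t2 - t1). The units of d and h cancel, so
#' only the time unit (years) matters. Negative values are allowed here and
#' filtered downstream by \code{\link{filter_growth_records}}.
#'
#' @param d1,d2 initial and final stem diameter (any consistent unit).
#' @param h1,h2 initial and final stem height (any consistent unit).
#' @param t1,t2 initial and final time (decimal years).
#'
#' @return RGR in 1/year. Vectorized.
#' @examples
#' compute_rgr(d1 = 2, h1 = 10, d2 = 3, h2 = 20, t1 = 0, t2 = 1)  # ln(4.5)
#' @export
compute_rgr <- function(d1, h1, d2, h2, t1 = 0, t2 = 1) {
  if (any(t2 <= t1)) stop("invalid interval: t2 must exceed t1")
  check_positive(d1 = d1, h1 = h1, d2 = d2, h2 = h2)
  (log(d2^2 * h2) - log(d1^2 * h1)) / (t2 - t1)
}

#' Generic diameter-height allometry
#'
#' Power-law height estimate h = a * d^b * elevation_adj, a pluggable stand-in
#' for species-specific, elevation-adjusted allometric equations used when
#' repeated surveys record diameters but not heights. Parameters must be
#' supplied explicitly per species; a missing parameter is an error, never a
#' silent default.
#'
#' @param d_cm stem diameter (cm).
#' @param a,b power-law coefficients (a in m/cm^b, a > 0).
#' @param elevation_adj multiplicative site-elevation adjustment (default 1).
#'
#' @return estimated height (m). Vectorized over \code{d_cm}.
#' @export
apply_height_allometry <- function(d_cm, a, b, elevation_adj = 1) {
  if (anyNA(c(a, b, elevation_adj)))
    stop("missing allometry: supply a, b and elevation_adj for this species")
  check_positive(d_cm = d_cm, a = a)
  if (any(b == 0))
    warning("b = 0: height is independent of diameter (degenerate allometry)")
  a * d_cm^b * elevation_adj
}

#' Filter out records with negative growth
#'
#' Two rules reflect how negative growth is screened in juvenile versus
#' mature survey data: juveniles are dropped when the computed d^2 h growth
#' is negative; mature trees are dropped when the (estimated) diameter
#' increment is negative. Zero growth is not negative and is kept under both
#' rules.
#'
#' @param records data.frame of growth records with columns \code{d1, h1,
#'   d2, h2, t1, t2} and (for \code{rule = "auto"}) \code{environment}.
#' @param rule \code{"juvenile"} (drop if d2^2 h2 < d1^2 h1),
#'   \code{"mature"} (drop if d2 < d1), or \code{"auto"} to pick per record
#'   from the environment label (labels containing \code{"mature"} use the
#'   diameter rule).
#'
#' @return list with data.frames \code{kept} and \code{dropped}; a message
#'   logs the counts.
#' @export
filter_growth_records <- function(records,
                                  rule = c("auto", "juvenile", "mature")) {
  rule <- match.arg(rule)
  if (nrow(records) == 0)
    return(list(kept = records, dropped = records))
  use_mature <- switch(rule,
    juvenile = rep(FALSE, nrow(records)),
    mature   = rep(TRUE, nrow(records)),
    auto     = grepl("mature", as.character(records$environment),
                     ignore.case = TRUE))
  neg_diam <- records$d2 < records$d1
  neg_d2h  <- records$d2^2 * records$h2 < records$d1^2 * records$h1
  drop <- ifelse(use_mature, neg_diam, neg_d2h)
  message(sprintf("growth filter: kept %d, dropped %d negative-growth records",
                  sum(!drop), sum(drop)))
  list(kept = records[!drop, , drop = FALSE],
       dropped = records[drop, , drop = FALSE])
}

#' Species-level summaries of traits and growth
#'
#' Aggregates individual-level data to the species level: unweighted trait
#' means over individuals, and per-species mean RGR together with its 95th
#' percentile (RGR95, linear interpolation between order statistics), the
#' latter acting as a maximum-realized-growth measure that screens out
#' suppressed individuals. Per-site breakdowns feed the site-level
#' meta-analysis.
#'
#' @param records data.frame of (already filtered) growth records with
#'   columns \code{species, site, d1, h1, d2, h2, t1, t2}.
#' @param individual_traits optional data.frame of per-individual trait
#'   values (a \code{species} column plus trait columns), e.g. from
#'   \code{\link{derive_individual_traits}}.
#' @param environment label attached to the returned trait table.
#'
#' @return list with \code{traits} (a \code{\link{trait_table}} or NULL),
#'   \code{growth} (species, n, rgr_mean, rgr95) and \code{growth_by_site}
#'   (species, site, n, rgr_mean, rgr95).
#' @export
species_summary <- function(records, individual_traits = NULL,
                            environment = "unspecified") {
  growth <- growth_by_site <- NULL
  if (!is.null(records) && nrow(records) > 0) {
    rgr <- compute_rgr(records$d1, records$h1, records$d2, records$h2,
                       records$t1, records$t2)
    growth <- summarize_rgr(records$species, rgr)
    growth_by_site <- summarize_rgr(records$species, rgr,
                                    site = records$site)
  }
  traits <- NULL
  if (!is.null(individual_traits)) {
    tcols <- setdiff(names(individual_traits),
                     c("species", "individual", "environment", "site"))
    sp <- sort(unique(individual_traits$species))
    m <- matrix(NA_real_, length(sp), length(tcols),
                dimnames = list(sp, tcols))
    cnt <- matrix(0L, length(sp), length(tcols), dimnames = list(sp, tcols))
    for (tc in tcols) {
      v <- tapply(individual_traits[[tc]], individual_traits$species,
                  mean, na.rm = TRUE)
      k <- tapply(!is.na(individual_traits[[tc]]),
                  individual_traits$species, sum)
      m[names(v), tc] <- v
      cnt[names(k), tc] <- as.integer(k)
    }
    m[cnt == 0L] <- NA_real_
    traits <- trait_table(m, cnt, environment)
  }
  list(traits = traits, growth = growth, growth_by_site = growth_by_site)
}

summarize_rgr <- function(species, rgr, site = NULL) {
  key <- if (is.null(site)) list(species = species)
         else list(species = species, site = site)
  agg <- aggregate(rgr, by = key, FUN = function(v)
    c(n = length(v), rgr_mean = mean(v),
      rgr95 = unname(stats::quantile(v, 0.95, type = 7))))
  out <- cbind(agg[names(key)], as.data.frame(agg$x))
  out$n <- as.integer(out$n)
  rownames(out) <- NULL
  out
}

#' Inter- vs intraspecific variance partition for one trait
#'
#' One-way random-effects decomposition from the ANOVA mean squares:
#' sigma2_b = (MSB - MSW) / n0 with n0 the effective per-species replicate
#' number for unbalanced designs; returns the interspecific fraction
#' sigma2_b / (sigma2_b + sigma2_w), truncated to [0, 1].
#'
#' @param individuals data.frame with a \code{species} column and the trait
#'   column.
#' @param trait name of the trait column.
#' @return list with \code{interspecific}, \code{intraspecific},
#'   \code{sigma2_between}, \code{sigma2_within}.
#' @export
variance_components <- function(individuals, trait) {
  stopifnot(trait %in% names(individuals))
  df <- data.frame(value = individuals[[trait]],
                   species = factor(individuals$species))
  df <- df[!is.na(df$value), , drop = FALSE]
  ni <- table(df$species)
  ni <- ni[ni > 0]
  k <- length(ni)
  if (k < 2 || max(ni) < 2)
    stop("need at least two species and replicated measurements")
  fit <- stats::aov(value ~ species, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]
  msw <- if (length(ms) > 1) ms[2] else 0
  n_tot <- sum(ni)
  n0 <- (n_tot - sum(ni^2) / n_tot) / (k - 1)
  sigma_b <- max(0, (msb - msw) / n0)
  frac <- if (sigma_b + msw == 0) 1 else sigma_b / (sigma_b + msw)
  frac <- min(1, max(0, frac))
  list(interspecific = frac, intraspecific = 1 - frac,
       sigma2_between = sigma_b, sigma2_within = msw)
}

#' Per-individual trait derivation
#'
#' Applies the three organ-level derivations to a raw measurement table
#' (the column schema written by \code{\link{write_study_bundle}}).
#'
#' @param individuals data.frame with columns \code{species},
#'   \code{individual}, \code{environment}, \code{leaf_area_cm2},
#'   \code{leaf_thickness_mm}, \code{leaf_fresh_g}, \code{leaf_dry_g},
#'   \code{wood_length_mm}, \code{wood_diameter_a_mm},
#'   \code{wood_diameter_b_mm}, \code{wood_fresh_mg}, \code{wood_dry_mg},
#'   \code{root_volume_mm3}, \code{root_fresh_mg}, \code{root_dry_mg}.
#' @return data.frame with species, individual, environment and the seven
#'   derived traits.
#' @export
derive_individual_traits <- function(individuals) {
  leaf <- derive_leaf_traits(individuals$leaf_area_cm2,
                             individuals$leaf_thickness_mm,
                             individuals$leaf_fresh_g,
                             individuals$leaf_dry_g)
  wood <- derive_wood_traits(individuals$wood_length_mm,
                             individuals$wood_diameter_a_mm,
                             individuals$wood_diameter_b_mm,
                             individuals$wood_fresh_mg,
                             individuals$wood_dry_mg)
  root <- derive_root_traits(individuals$root_volume_mm3,
                             individuals$root_fresh_mg,
                             individuals$root_dry_mg)
  data.frame(species = individuals$species,
             individual = individuals$individual,
             environment = individuals$environment,
             LMA = leaf$LMA, LTD = leaf$LTD, LDMC = leaf$LDMC,
             WD = wood$WD, WDMC = wood$WDMC,
             RTD = root$RTD, RDMC = root$RDMC)
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (anyNA(v) || any(v <= 0))
      stop("invalid measurement: ", nm, " must be positive and non-missing")
  }
  invisible(TRUE)
}

check_dry_le_fresh <- function(dry, fresh) {
  if (any(dry > fresh + 1e-12))
    stop("invalid measurement: dry mass exceeds fresh mass")
  invisible(TRUE)
}
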