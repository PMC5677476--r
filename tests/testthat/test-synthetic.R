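test_that("Yule trees are bifurcating, ultrametric, unit depth and reproducible", {
  tr2 <- generate_yule_tree(2, seed = 3)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)
  expect_equal(tr2$edge.length[1], tr2$edge.length[2])
  tr <- generate_yule_tree(56, seed = 1)
  expect_equal(length(tr$tip.label), 56)
  expect_equal(tr$Nnode, 55)
  depths <- ape::node.depth.edgelength(tr)[seq_len(56)]
  expect_true(all(abs(depths - 1) < 1e-9))     # ultrametric, unit depth
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_yule_tree(30, seed = 7)),
                   ape::write.tree(generate_yule_tree(30, seed = 7)))
  expect_error(generate_yule_tree(1), "invalid argument")
})

test_that("Brownian trait simulation has the configured correlation structure", {
  # star tree + identity correlation: cross-trait correlations near zero
  star <- star_tree(40)
  cfg0 <- synthetic_config(n_species = 40,
                           evo_correlation = diag(7),
                           shift_spec = zero_shift_spec())
  z <- replicate(60, {
    tt <- simulate_bm_traits(star, cfg0, seed = sample.int(1e6, 1))
    cor(tt$traits[, "LMA"], tt$traits[, "WD"])
  })
  expect_lt(abs(mean(z)), 0.1)
  # near-perfect equicorrelation concentrates variance on one axis
  tr <- generate_yule_tree(56, seed = 2)
  cfg1 <- synthetic_config(evo_correlation = equicorrelation(0.95, 7))
  lead <- replicate(20, {
    tt <- simulate_bm_traits(tr, cfg1, seed = sample.int(1e6, 1))
    eigen(cor(tt$traits))$values[1]
  })
  expect_true(all(lead > 5))
  # zero Brownian rates collapse every species onto the root state
  cfg2 <- synthetic_config(evo_variances = named7(0) + 0)
  tt0 <- simulate_bm_traits(tr, cfg2, seed = 9)
  expect_equal(unname(tt0$traits[3, ]), unname(cfg2$root_state),
               tolerance = 1e-12)
  expect_error(synthetic_config(evo_correlation = equicorrelation(-0.5, 7)),
               "positive semidefinite")
})

test_that("environment shifts displace species additively and preserve identity at zero", {
  tt <- toy_trait_table(10)
  same <- apply_environment_shifts(tt, zero_shift_spec(), seed = 1)
  expect_equal(same$traits, tt$traits)
  expect_equal(same$environment, "wild_juvenile")
  # deterministic offset
  spec <- trait_shift_spec(mean_shift = named7(c(-3, 0, 0, 0, 0, 0, 0)),
                           shift_sd = named7(0))
  fld <- apply_environment_shifts(tt, spec, seed = 1)
  expect_equal(fld$traits[, "LMA"], tt$traits[, "LMA"] - 3)
  expect_equal(fld$traits[, "WD"], tt$traits[, "WD"])
  # divergent defaults: LMA drops, WD rises, in every seeded run
  tr <- generate_yule_tree(56, seed = 5)
  cfg <- synthetic_config()
  gh <- simulate_bm_traits(tr, cfg, seed = 6)
  signs <- sapply(1:20, function(i) {
    f <- suppressWarnings(
      apply_environment_shifts(gh, trait_shift_spec(), seed = 100 + i))
    c(mean(f$traits[, "LMA"] - gh$traits[, "LMA"]),
      mean(f$traits[, "WD"] - gh$traits[, "WD"]))
  })
  expect_true(all(signs[1, ] < 0))
  expect_true(all(signs[2, ] > 0))
  expect_error(apply_environment_shifts(
    tt, trait_shift_spec(mean_shift = c(A = 1), shift_sd = c(A = 0))),
    "trait names")
})

test_that("correlated shift noise follows the exposure axis", {
  tr <- generate_yule_tree(56, seed = 8)
  gh <- simulate_bm_traits(tr, synthetic_config(), seed = 9)
  fld <- suppressWarnings(
    apply_environment_shifts(gh, exposure_shift_spec(), seed = 10))
  d <- fld$traits - gh$traits
  # rank-1 divergent exposure: LMA displacement anti-correlated with WD's
  expect_lt(cor(d[, "LMA"], d[, "WD"]), -0.9)
  expect_gt(cor(d[, "WD"], d[, "RTD"]), 0.9)
})

test_that("individual replicates round-trip through the trait derivations", {
  tt <- toy_trait_table(6)
  # make the DMC columns valid fractions
  tt$traits[, c("LDMC", "WDMC", "RDMC")] <-
    tt$traits[, c("LDMC", "WDMC", "RDMC")] / 20
  ind <- generate_individual_replicates(tt, n = 3, cv = 0, seed = 1)
  expect_equal(nrow(ind), 18)
  back <- derive_individual_traits(ind)
  for (trn in TRAIT_NAMES) {
    means <- tapply(back[[trn]], back$species, mean)
    expect_equal(as.numeric(means[rownames(tt$traits)]),
                 unname(tt$traits[, trn]), tolerance = 1e-9)
  }
  expect_error(generate_individual_replicates(tt, n = 0, cv = 0.1),
               "invalid argument")
  expect_error(generate_individual_replicates(tt, n = 3, cv = -0.1),
               "invalid argument")
})

test_that("replicate noise has approximately the requested coefficient of variation", {
  tr <- generate_yule_tree(56, seed = 3)
  gh <- simulate_bm_traits(tr, synthetic_config(), seed = 4)
  ind <- generate_individual_replicates(gh, n = 10, cv = 0.2, seed = 5)
  it <- derive_individual_traits(ind)
  cvs <- tapply(it$LMA, it$species, function(v) sd(v) / mean(v))
  expect_gte(mean(cvs >= 0.05 & cvs <= 0.4), 0.9)
})

test_that("growth trajectories invert the RGR formula exactly", {
  tt <- toy_trait_table(6)
  cfg <- synthetic_config(n_species = 6, n_replicates_per_species = 4,
                          suppression_sd = 0)
  g <- generate_growth_trajectories(tt, cfg, "cultivated", seed = 2)
  rgr <- compute_rgr(g$d1, g$h1, g$d2, g$h2, g$t1, g$t2)
  # the composite-score link is deterministic without suppression:
  # all individuals of a species share the injected true RGR
  per_sp <- tapply(rgr, g$species, function(v) diff(range(v)))
  expect_true(all(per_sp < 1e-12))
  # negative slope makes low-score (dense-tissue) species grow faster
  s <- species_summary(g)
  score <- rowMeans(scale(tt$traits))
  expect_lt(cor(score[s$growth$species], s$growth$rgr_mean), 0)
  expect_error(generate_growth_trajectories(tt, cfg, "orchard"),
               "unknown environment")
})

test_that("field suppression makes RGR95 exceed mean RGR substantially", {
  tr <- generate_yule_tree(56, seed = 3)
  cfg <- synthetic_config()
  gh <- simulate_bm_traits(tr, cfg, seed = 4)
  g <- generate_growth_trajectories(gh, cfg, "wild_juvenile", seed = 7)
  flt <- suppressMessages(filter_growth_records(g, "juvenile"))
  s <- species_summary(flt$kept)
  expect_gt(mean(s$growth$rgr95 / s$growth$rgr_mean), 1.5)
  expect_gt(length(unique(g$site)), 1)
})

test_that("study bundles round-trip through disk", {
  cfg <- synthetic_config(n_species = 10, n_replicates_per_species = 3,
                          n_sites = 2, seed = 11)
  study <- suppressWarnings(generate_study(cfg))
  dir <- withr::local_tempdir()
  man <- write_study_bundle(study, dir)
  expect_setequal(man$file,
                  c("tree.nwk", "individuals.csv", "growth.csv",
                    "config.json"))
  bundle <- read_study_bundle(dir)
  expect_identical(ape::write.tree(bundle$phylogeny),
                   ape::write.tree(study$phylogeny))
  expect_equal(bundle$individuals$leaf_dry_g, study$individuals$leaf_dry_g,
               tolerance = 1e-12)
  expect_equal(nrow(bundle$growth_records), nrow(study$growth_records))
  # determinism: rewriting the same study gives identical checksums
  dir2 <- withr::local_tempdir()
  man2 <- write_study_bundle(study, dir2)
  expect_identical(man$md5, man2$md5)
  # empty species set refuses to write
  empty <- study
  empty$individuals <- study$individuals[0, ]
  expect_error(write_study_bundle(empty, withr::local_tempdir()), "empty")
})
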