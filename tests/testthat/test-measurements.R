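test_that("leaf trait derivations follow the dry-mass ratios with unit conversion", {
  out <- derive_leaf_traits(area_cm2 = 25, thickness_mm = 0.2,
                            fresh_mass_g = 0.25, dry_mass_g = 0.05)
  expect_equal(out$LMA, 20)            # 0.05 g / 25 cm2 x 1e4
  expect_equal(out$LDMC, 0.20)
  expect_equal(out$LTD, 0.10)          # 50 mg / (2500 mm2 x 0.2 mm)
  expect_error(derive_leaf_traits(0, 0.2, 0.25, 0.05), "invalid measurement")
  expect_error(derive_leaf_traits(25, -1, 0.25, 0.05), "invalid measurement")
  expect_error(derive_leaf_traits(25, 0.2, 0.04, 0.05), "dry mass exceeds")
})

test_that("wood volume is an elliptical cylinder from the two orthogonal diameters", {
  out <- derive_wood_traits(length_mm = 20, diameter_a_mm = 4,
                            diameter_b_mm = 5, fresh_mass_mg = 300,
                            dry_mass_mg = 150)
  expect_equal(out$wood_volume_mm3, 100 * pi)
  expect_equal(out$WD, 150 / (100 * pi), tolerance = 1e-12)
  expect_equal(out$WDMC, 0.50)
  # circular special case
  circ <- derive_wood_traits(10, 4, 4, 200, 100)
  expect_equal(circ$wood_volume_mm3, 40 * pi)
  expect_error(derive_wood_traits(20, 4, NA, 300, 150),
               "both orthogonal diameters")
})

test_that("root traits are direct dry-mass ratios, with a boundary flag at RDMC = 1", {
  out <- derive_root_traits(volume_mm3 = 100, fresh_mass_mg = 80,
                            dry_mass_mg = 20)
  expect_equal(out$RTD, 0.20)
  expect_equal(out$RDMC, 0.25)
  expect_warning(b <- derive_root_traits(100, 20, 20), "boundary")
  expect_equal(b$RDMC, 1.0)
  expect_error(derive_root_traits(0, 80, 20), "invalid measurement")
})

test_that("RGR is the change in ln(d^2 h) per year", {
  expect_equal(compute_rgr(d1 = 2, h1 = 10, d2 = 3, h2 = 20, t1 = 0, t2 = 1),
               log(4.5), tolerance = 1e-12)
  expect_equal(compute_rgr(2, 10, 2, 10), 0)
  # d^2 h doubling over two years
  expect_equal(compute_rgr(2, 10, 2, 20, 0, 2), log(2) / 2)
  expect_error(compute_rgr(2, 10, 3, 20, t1 = 1, t2 = 1), "invalid interval")
  expect_error(compute_rgr(-2, 10, 3, 20), "invalid measurement")
})

test_that("RGR is antisymmetric in time and invariant to diameter units", {
  set.seed(42)
  for (i in 1:20) {
    d1 <- runif(1, 1, 10); h1 <- runif(1, 5, 100)
    d2 <- runif(1, 1, 10); h2 <- runif(1, 5, 100)
    t2 <- runif(1, 0.5, 3)
    fwd <- compute_rgr(d1, h1, d2, h2, 0, t2)
    # swapping the two censuses flips the sign
    expect_equal(compute_rgr(d2, h2, d1, h1, 0, t2), -fwd, tolerance = 1e-12)
    # mm vs cm diameters (and cm vs m heights) cancel in the log-difference
    expect_equal(compute_rgr(d1 / 10, h1 / 100, d2 / 10, h2 / 100, 0, t2),
                 fwd, tolerance = 1e-9)
  }
})

test_that("the generic power-law allometry behaves and fails loudly", {
  expect_equal(apply_height_allometry(25, a = 2, b = 0.5), 10)
  expect_equal(apply_height_allometry(25, 2, 0.5, elevation_adj = 0.9),
               9)
  expect_warning(h <- apply_height_allometry(25, 2, 0), "degenerate")
  expect_equal(h, 2)
  expect_error(apply_height_allometry(25, NA, 0.5), "missing allometry")
})

test_that("negative-growth filtering drops by diameter for mature and by d2h for juveniles", {
  rec <- data.frame(
    species = "sp001", individual = letters[1:10], site = "s",
    environment = "wild_mature",
    d1 = rep(5, 10), h1 = rep(50, 10),
    d2 = c(6, 6, 6, 4, 4, 4, 5, 6, 6, 6),       # 3 shrinking diameters
    h2 = c(rep(60, 9), 20), t1 = 0, t2 = 1)
  out <- suppressMessages(filter_growth_records(rec, rule = "mature"))
  expect_equal(nrow(out$kept), 7)
  expect_equal(nrow(out$dropped), 3)
  # juvenile rule: record 10 has growing d but shrinking d^2 h
  outj <- suppressMessages(filter_growth_records(rec, rule = "juvenile"))
  expect_equal(nrow(outj$dropped), 4)
  # exact zero growth is kept under both rules
  zero <- data.frame(species = "sp001", individual = "z", site = "s",
                     environment = "wild_juvenile", d1 = 5, h1 = 50,
                     d2 = 5, h2 = 50, t1 = 0, t2 = 1)
  expect_equal(nrow(suppressMessages(
    filter_growth_records(zero, "juvenile"))$kept), 1)
  expect_equal(nrow(suppressMessages(
    filter_growth_records(zero, "mature"))$kept), 1)
  # auto rule dispatches on the environment label
  auto <- suppressMessages(filter_growth_records(rec, "auto"))
  expect_equal(nrow(auto$kept), 7)
  # empty input passes through
  empty <- filter_growth_records(rec[0, ])
  expect_equal(nrow(empty$kept), 0)
})

test_that("species growth summaries use linear-interpolation percentiles", {
  rec <- data.frame(species = "sp001",
                    individual = paste0("i", 1:100), site = "s1",
                    environment = "cultivated",
                    d1 = 1, h1 = 1, d2 = exp(1:100 / 3), h2 = 1,
                    t1 = 0, t2 = 1)
  # RGR values are exactly 1..100 (2 * log d2 / 3 per year x 3/2...)
  rgr <- compute_rgr(rec$d1, rec$h1, rec$d2, rec$h2, rec$t1, rec$t2)
  expect_equal(rgr, 2 * (1:100) / 3)
  s <- species_summary(rec)
  expect_equal(s$growth$rgr95, 2 * 95.05 / 3, tolerance = 1e-9)
  # single individual: RGR95 equals the value itself
  one <- species_summary(rec[1, ])
  expect_equal(one$growth$rgr95, one$growth$rgr_mean)
  # all identical: mean equals the 95th percentile
  same <- rec; same$d2 <- exp(1)
  ss <- species_summary(same)
  expect_equal(ss$growth$rgr_mean, ss$growth$rgr95)
  # RGR95 is never below the median for replicated species
  expect_true(s$growth$rgr95 >= median(rgr))
})

test_that("species trait means aggregate individuals with replicate counts", {
  it <- data.frame(species = rep(c("a", "b"), each = 3),
                   individual = 1:6, environment = "cultivated",
                   LMA = c(10, 20, 30, 40, 50, NA))
  s <- species_summary(NULL, it, environment = "cultivated")
  expect_equal(unname(s$traits$traits[, "LMA"]), c(20, 45))
  expect_equal(unname(s$traits$counts[, "LMA"]), c(3L, 2L))
  expect_equal(s$traits$environment, "cultivated")
})

test_that("variance partitioning recovers the intraclass correlation", {
  # identical replicates within species, different means: all interspecific
  ind <- data.frame(species = rep(c("a", "b", "c"), each = 4),
                    LMA = rep(c(10, 20, 30), each = 4))
  expect_equal(variance_components(ind, "LMA")$interspecific, 1)
  # identical species means, noisy replicates: fraction near zero
  set.seed(1)
  ind2 <- data.frame(species = rep(sprintf("s%02d", 1:10), each = 50),
                     LMA = rnorm(500, mean = 10))
  expect_lte(variance_components(ind2, "LMA")$interspecific, 0.1)
  # known ICC: sigma2_b / sigma2_w = 3 -> fraction 0.75
  set.seed(2)
  k <- 40; n <- 50
  mu <- rnorm(k, 0, sqrt(3))
  ind3 <- data.frame(species = rep(sprintf("s%02d", 1:k), each = n),
                     LMA = rep(mu, each = n) + rnorm(k * n))
  expect_equal(variance_components(ind3, "LMA")$interspecific, 0.75,
               tolerance = 0.05)
  expect_error(variance_components(ind[1:4, ], "LMA"), "two species")
})
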