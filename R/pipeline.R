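#' Run the full whole-plant economic spectrum analysis
#'
#' Orchestrates the complete pipeline on either a synthetic study
#' (generated from \code{config}) or a study bundle on disk: trait
#' derivation and species-level aggregation, growth filtering and RGR /
#' RGR95 summaries, variance partitioning, phylogenetic PCA with the
#' integration index and Kaiser dimensionality per environment, SMA
#' regressions on raw species means and on independent contrasts (trait
#' pairs and trait-growth), random-effects meta-analysis of site-level
#' trait-growth correlations, Wilcoxon signed-rank paired environment
#' comparisons, and the environment-mixing resampling null for the
#' configured trait pairs.
#'
#' @param config a \code{\link{synthetic_config}} used when
#'   \code{input_dir} is NULL; its seed drives every stochastic stage.
#' @param input_dir optional study-bundle directory (see
#'   \code{\link{write_study_bundle}}); exactly one of the synthetic config
#'   or the bundle is the data source.
#' @param output_dir optional directory for CSV/JSON reports (see
#'   \code{\link{write_reports}}).
#' @param key_traits one representative trait per organ for the univariate
#'   analyses (default LMA, WD, RTD).
#' @param resample_pairs list of trait pairs for the resampling null.
#' @param b_reps replicate datasets per resampling run.
#' @param alpha significance level for the \code{both_significant} flag
#'   (a relationship is reported only when raw and PIC analyses are both
#'   significant).
#' @param skip_growth skip growth-dependent stages (useful when a bundle
#'   has no growth records).
#' @return object of class \code{trait_pipeline}: a list with elements
#'   \code{trait_tables}, \code{growth}, \code{growth_by_site},
#'   \code{variance_partition}, \code{pca}, \code{sma}, \code{meta},
#'   \code{paired_tests}, \code{resampling}, \code{log}, \code{seed},
#'   \code{species_counts}.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         input_dir = NULL, output_dir = NULL,
                         key_traits = c("LMA", "WD", "RTD"),
                         resample_pairs = list(c("LMA", "WD"),
                                               c("LMA", "RTD"),
                                               c("WD", "RTD")),
                         b_reps = 1000, alpha = 0.05,
                         skip_growth = FALSE) {
  log <- character()
  note <- function(...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(...))
    log <<- c(log, line)
    message(line)
  }
  seed <- config$seed
  note("pipeline start (traitaxes %s, seed %d)",
       as.character(utils::packageVersion("traitaxes")), seed)

  if (!is.null(input_dir)) {
    bundle <- tryCatch(read_study_bundle(input_dir), error = function(e) {
      if (skip_growth && grepl("growth.csv", conditionMessage(e))) {
        list(phylogeny = read_newick(file.path(input_dir, "tree.nwk")),
             individuals = utils::read.csv(file.path(input_dir,
                                                     "individuals.csv")),
             growth_records = NULL)
      } else stop("stage input: ", conditionMessage(e))
    })
    tree <- bundle$phylogeny
    individuals <- bundle$individuals
    growth <- bundle$growth_records
    note("loaded bundle from %s", input_dir)
  } else {
    study <- generate_study(config)
    tree <- study$phylogeny
    individuals <- study$individuals
    growth <- study$growth_records
    note("generated synthetic study: %d species", config$n_species)
  }
  if (skip_growth) growth <- NULL

  # --- measurements -------------------------------------------------------
  ind_traits <- derive_individual_traits(individuals)
  envs <- unique(ind_traits$environment)
  trait_tables <- list()
  growth_sum <- growth_site <- list()
  for (env in envs) {
    env_growth <- NULL
    if (!is.null(growth)) {
      g <- growth[growth$environment == env, , drop = FALSE]
      if (nrow(g) > 0) {
        flt <- filter_growth_records(g, rule = "auto")
        note("%s: %d growth records kept, %d dropped (negative growth)",
             env, nrow(flt$kept), nrow(flt$dropped))
        env_growth <- flt$kept
      }
    }
    s <- species_summary(env_growth,
                         ind_traits[ind_traits$environment == env, ],
                         environment = env)
    trait_tables[[env]] <- s$traits
    growth_sum[[env]] <- s$growth
    growth_site[[env]] <- s$growth_by_site
    note("%s: %d species in trait table", env, length(s$traits$species))
  }

  # --- variance partitioning ---------------------------------------------
  variance_partition <- NULL
  if (max(table(ind_traits$species, ind_traits$environment)) >= 2) {
    variance_partition <- do.call(rbind, lapply(envs, function(env) {
      sub <- ind_traits[ind_traits$environment == env, ]
      do.call(rbind, lapply(TRAIT_NAMES, function(tr) {
        vc <- variance_components(sub, tr)
        data.frame(environment = env, trait = tr,
                   interspecific = vc$interspecific)
      }))
    }))
  }

  # --- phylogenetic PCA per environment ----------------------------------
  pca <- lapply(trait_tables, function(tt) phylo_pca(tree, tt))
  for (env in names(pca))
    note("%s: integration index %.3f, dimensionality %d (n = %d)",
         env, pca[[env]]$integration_index, pca[[env]]$dimensionality,
         pca[[env]]$n)

  # --- SMA: trait pairs and trait-growth, raw + PIC ----------------------
  sma_rows <- list()
  pairs <- utils::combn(key_traits, 2, simplify = FALSE)
  for (env in envs) {
    tt <- trait_tables[[env]]
    for (pr in pairs)
      sma_rows[[length(sma_rows) + 1L]] <-
        sma_pair_row(tree, tt, pr[1], pr[2], env, alpha)
    if (!is.null(growth_sum[[env]])) {
      for (gm in c("rgr_mean", "rgr95")) {
        gname <- if (gm == "rgr95") "RGR95" else "RGR"
        gvec <- stats::setNames(growth_sum[[env]][[gm]],
                                growth_sum[[env]]$species)
        for (tr in key_traits)
          sma_rows[[length(sma_rows) + 1L]] <-
            sma_growth_row(tree, tt, tr, gvec, gname, env, alpha)
      }
    }
  }
  sma <- do.call(rbind, sma_rows)

  # --- meta-analysis of site-level correlations --------------------------
  meta <- NULL
  meta_rows <- list()
  for (env in envs) {
    gs <- growth_site[[env]]
    if (is.null(gs) || length(unique(gs$site)) < 2) next
    for (gm in c("RGR", "RGR95")) for (tr in key_traits) {
      sites <- site_correlations(gs, trait_tables[[env]], tr, gm)
      if (nrow(sites) == 0) next
      pool <- dl_random_effects_pool(sites)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        environment = env, trait = tr, growth_measure = gm,
        k = pool$k, pooled_r = pool$pooled_r, ci_lo = pool$ci95[1],
        ci_hi = pool$ci95[2], tau_squared = pool$tau_squared, Q = pool$Q)
    }
  }
  if (length(meta_rows) > 0) meta <- do.call(rbind, meta_rows)

  # --- paired environment comparison + resampling null -------------------
  paired_tests <- NULL
  resampling <- list()
  if (all(c("cultivated", "wild_juvenile") %in% names(trait_tables))) {
    gh <- trait_tables[["cultivated"]]
    fld <- trait_tables[["wild_juvenile"]]
    shared <- intersect(gh$species, fld$species)
    paired_tests <- do.call(rbind, lapply(key_traits, function(tr) {
      w <- wilcoxon_signed_rank(gh$traits[shared, tr],
                                fld$traits[shared, tr])
      data.frame(trait = tr, W = w$W, p_value = w$p_value, n = w$n_used,
                 median_difference = w$median_difference)
    }))
    for (pr in resample_pairs) {
      rs <- resample_mixed_environments(gh, fld, pr, B = b_reps,
                                        seed = seed)
      resampling[[paste(pr, collapse = "_")]] <- rs
      note("resampling %s-%s: observed R2 %.3f at quantile %.3f (exceeds: %s)",
           pr[1], pr[2], rs$observed_r2, rs$quantile_position,
           rs$exceeds_95th)
    }
  }

  result <- structure(list(
    trait_tables = trait_tables, growth = growth_sum,
    growth_by_site = growth_site, variance_partition = variance_partition,
    pca = pca, sma = sma, meta = meta, paired_tests = paired_tests,
    resampling = resampling, log = log, seed = seed,
    species_counts = vapply(trait_tables,
                            function(tt) length(tt$species), 1L)),
    class = "trait_pipeline")
  if (!is.null(output_dir)) write_reports(result, output_dir)
  result
}

sma_pair_row <- function(tree, tt, tx, ty, env, alpha) {
  M <- tt$traits[, c(tx, ty), drop = FALSE]
  M <- M[stats::complete.cases(M), , drop = FALSE]
  raw <- sma_fit(M[, 1], M[, 2])
  pic <- pic_sma(tree, M)
  data.frame(environment = env, trait_x = tx, trait_y = ty,
             n = raw$n, slope = raw$slope, intercept = raw$intercept,
             r = raw$r, r_squared = raw$r_squared, p_raw = raw$p_value,
             r_pic = pic$r, p_pic = pic$p_value,
             both_significant = raw$p_value < alpha & pic$p_value < alpha)
}

sma_growth_row <- function(tree, tt, tr, gvec, gname, env, alpha) {
  sp <- intersect(tt$species, names(gvec))
  M <- cbind(tt$traits[sp, tr], gvec[sp])
  rownames(M) <- sp
  colnames(M) <- c(tr, gname)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  raw <- sma_fit(M[, 1], M[, 2])
  pic <- pic_sma(tree, M)
  data.frame(environment = env, trait_x = tr, trait_y = gname,
             n = raw$n, slope = raw$slope, intercept = raw$intercept,
             r = raw$r, r_squared = raw$r_squared, p_raw = raw$p_value,
             r_pic = pic$r, p_pic = pic$p_value,
             both_significant = raw$p_value < alpha & pic$p_value < alpha)
}

# through-origin SMA on the contrasts of a two-column species matrix
pic_sma <- function(tree, M) {
  drop <- setdiff(tree$tip.label, rownames(M))
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  cx <- compute_pics(tree, M[, 1][rownames(M)])
  cy <- compute_pics(tree, M[, 2][rownames(M)])
  sma_fit_origin(cx, cy)
}

#' @export
print.trait_pipeline <- function(x, ...) {
  cat("Whole-plant economic spectrum pipeline (seed", x$seed, ")\n")
  for (env in names(x$pca))
    cat(sprintf(
      "  %s: n = %d, integration index %.3f, dimensionality %d\n", env,
      x$pca[[env]]$n, x$pca[[env]]$integration_index,
      x$pca[[env]]$dimensionality))
  if (!is.null(x$sma))
    cat("  SMA fits:", nrow(x$sma), "  meta-analyses:",
        if (is.null(x$meta)) 0 else nrow(x$meta),
        "  resampling pairs:", length(x$resampling), "\n")
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Writes stable-named CSV tables (species trait tables, growth summaries,
#' SMA fits, meta-analysis pools, PCA eigenvalues, resampling summaries), a
#' JSON summary with every headline statistic, and a plain-text run log.
#' The returned manifest lists every file with its row count.
#'
#' @param results a \code{trait_pipeline} object (or an empty list, which
#'   yields an empty manifest with a warning).
#' @param directory output directory (created if needed).
#' @return data.frame manifest (file, rows).
#' @export
write_reports <- function(results, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot write reports to ", directory)
  if (length(results) == 0) {
    warning("empty results: writing empty manifest")
    manifest <- data.frame(file = character(), rows = integer())
    jsonlite::write_json(manifest, file.path(directory, "manifest.json"))
    return(manifest)
  }
  files <- list()
  put_csv <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return()
    utils::write.csv(df, file.path(directory, name), row.names = FALSE)
    files[[name]] <<- nrow(df)
  }
  for (env in names(results$trait_tables)) {
    tt <- results$trait_tables[[env]]
    put_csv(data.frame(species = tt$species, tt$traits,
                       check.names = FALSE),
            paste0("species_traits_", env, ".csv"))
    put_csv(results$growth[[env]], paste0("species_growth_", env, ".csv"))
    put_csv(results$growth_by_site[[env]],
            paste0("species_growth_by_site_", env, ".csv"))
  }
  put_csv(results$variance_partition, "variance_partition.csv")
  put_csv(results$sma, "sma_fits.csv")
  put_csv(results$meta, "meta_results.csv")
  put_csv(results$paired_tests, "paired_tests.csv")
  eig <- do.call(rbind, lapply(names(results$pca), function(env)
    data.frame(environment = env, axis = seq_len(results$pca[[env]]$N),
               eigenvalue = results$pca[[env]]$eigenvalues)))
  put_csv(eig, "pca_eigenvalues.csv")
  rs <- do.call(rbind, lapply(results$resampling, function(r)
    data.frame(trait_x = r$trait_pair[1], trait_y = r$trait_pair[2],
               n_species = r$n_species, B = r$B,
               observed_r2 = r$observed_r2,
               simulated_mean_r2 = mean(r$simulated_r2),
               simulated_q95 = unname(stats::quantile(r$simulated_r2,
                                                      0.95, type = 7)),
               quantile_position = r$quantile_position,
               exceeds_95th = r$exceeds_95th)))
  put_csv(rs, "resampling.csv")

  summary <- list(
    seed = results$seed,
    species_counts = as.list(results$species_counts),
    integration_index = lapply(results$pca, `[[`, "integration_index"),
    dimensionality = lapply(results$pca, `[[`, "dimensionality"),
    eigenvalues = lapply(results$pca, `[[`, "eigenvalues"),
    resampling = if (is.null(rs)) NULL else rs,
    meta = results$meta)
  jsonlite::write_json(summary, file.path(directory, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  files[["summary.json"]] <- NA_integer_
  writeLines(results$log, file.path(directory, "run_log.txt"))
  files[["run_log.txt"]] <- length(results$log)
  manifest <- data.frame(file = names(files),
                         rows = unlist(files, use.names = FALSE))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       digits = NA)
  manifest
}
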