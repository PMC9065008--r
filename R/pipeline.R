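# End-to-end orchestration: filtering -> age replicates -> subsets ->
# lifespan posteriors -> merged fixed-times rates -> trajectories ->
# MBD (combined + pairwise + sensitivity) -> effect network. Every stage
# writes plain-text artifacts and a manifest entry with its seed and a
# config hash; identical configs reproduce identical artifacts.

#' Pipeline configuration
#'
#' Defaults follow the documented production workflow (fifty age
#' replicates, eleven species subsets, 20\% burn-in, shrinkage-weight
#' significance at `w > 0.7`); every stage is overridable, and
#' desk-scale analyses shrink the chain lengths and replicate counts.
#'
#' @param table an `occurrence_table` (alternatively give `input_path`).
#' @param input_path,dialect input file read via [read_occurrences()].
#' @param filter_rules rules for [filter_occurrences()].
#' @param extant_names optional extant-species name list for
#'   [mark_extant()].
#' @param n_replicates age replicates (default 50).
#' @param n_subsets species subsets for lifespan estimation (default 11).
#' @param lifespan_replicates replicates actually run through the
#'   lifespan sampler (default all).
#' @param preservation preservation model kind for lifespan sampling.
#' @param epochs TPP epoch boundaries (default from the data span).
#' @param lifespan_cfg,rates_cfg,mbd_cfg per-stage [mcmc_config()]s
#'   (seeds are re-derived from `seed` and the stage name).
#' @param env_covariates named list of environmental `covariate_series`.
#' @param families families for per-family trajectories and MBD runs
#'   (default: all families with at least `min_family_species` species).
#' @param min_family_species smallest family analysed separately.
#' @param w_threshold effect-network significance threshold.
#' @param ltt_step trajectory grid step (Myr).
#' @param bin_width discrete bin width (Myr) for per-capita rates.
#' @param slope_window window (Ma) for the mean diversity slope.
#' @param sensitivity named list of extra filter-rule sets re-running the
#'   MBD on filtered data (e.g. an Indo-Pacific longitude window, or an
#'   Acroporidae co-occurrence restriction).
#' @param seed master seed; stage seeds derive from it by stable hashing
#'   of stage names.
#' @param out_dir artifact directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(table = NULL, input_path = NULL,
                            dialect = "pbdb_csv", filter_rules = list(),
                            extant_names = NULL,
                            n_replicates = 50L, n_subsets = 11L,
                            lifespan_replicates = n_replicates,
                            preservation = "TPP", epochs = NULL,
                            lifespan_cfg = mcmc_config(50e6, 40e3),
                            rates_cfg = mcmc_config(100e6, 40e3),
                            mbd_cfg = mcmc_config(25e6, 25e3),
                            env_covariates = list(),
                            families = NULL, min_family_species = 3L,
                            w_threshold = 0.7, ltt_step = 0.1,
                            bin_width = 1, slope_window = c(12, 0),
                            sensitivity = list(),
                            seed = 1L, out_dir = tempfile("fossilbd_run")) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(entries, path) {
  df <- do.call(rbind, lapply(entries, as.data.frame))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read/filter, age replication, species subsetting,
#' per-subset lifespan posteriors (medians merged across subsets),
#' fixed-times rate estimation, diversity trajectories/slopes and
#' discrete-bin per-capita rates, MBD runs (combined, per-family
#' pairwise, sensitivity variants) and the effect network. Each stage
#' writes its outputs under `config$out_dir` plus a manifest with seeds
#' and a config hash. A completed stage (matching hash) is skipped on
#' re-run; re-running with an identical config reproduces the artifacts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory stage results, including the
#'   artifact directory.
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest <- list()
  res <- list(out_dir = config$out_dir)

  stage_dir <- function(name) {
    d <- file.path(config$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  stage_done <- function(name) {
    f <- file.path(config$out_dir, name, ".done")
    file.exists(f) && identical(readLines(f, n = 1L), hash)
  }
  mark_done <- function(name) {
    writeLines(hash, file.path(config$out_dir, name, ".done"))
  }
  note <- function(name, seed) {
    manifest[[name]] <<- list(stage = name, config_hash = hash,
                              seed = seed %||% NA_integer_)
  }

  # -- stage 1: input ---------------------------------------------------
  d <- stage_dir("01_input")
  tab <- if (!is.null(config$table)) config$table
         else read_occurrences(config$input_path, config$dialect)
  if (!is.null(config$extant_names))
    tab <- mark_extant(tab, config$extant_names)
  tab <- filter_occurrences(tab, config$filter_rules)
  if (nrow(tab) == 0L) stop("stage 01_input: no occurrences after filtering")
  write_occurrences(tab, file.path(d, "filtered.csv"), "pbdb_csv")
  mark_done("01_input"); note("01_input", NULL)
  res$table <- tab

  fams <- config$families
  if (is.null(fams)) {
    cnt <- tapply(tab$species_name, tab$family,
                  function(x) length(unique(x)))
    fams <- names(cnt)[!is.na(names(cnt)) &
                         cnt >= config$min_family_species]
  }
  res$families <- fams

  # -- stage 2: age replicates ------------------------------------------
  d <- stage_dir("02_replicates")
  s2 <- derive_seed(config$seed, "replicates")
  reps <- resample_ages(tab, config$n_replicates, seed = s2)
  ages_mat <- vapply(reps, `[[`, numeric(nrow(tab)), "ages")
  utils::write.csv(
    data.frame(occurrence_id = tab$occurrence_id, ages_mat),
    file.path(d, "replicate_ages.csv"), row.names = FALSE)
  mark_done("02_replicates"); note("02_replicates", s2)
  res$replicates <- reps

  # -- stage 3: subsets --------------------------------------------------
  d <- stage_dir("03_subsets")
  s3 <- derive_seed(config$seed, "subsets")
  part <- split_subsets(tab, config$n_subsets, seed = s3)
  utils::write.csv(
    data.frame(species_name = names(part$assignment),
               subset = part$assignment),
    file.path(d, "subsets.csv"), row.names = FALSE)
  mark_done("03_subsets"); note("03_subsets", s3)
  res$partition <- part

  # -- stage 4: lifespans ------------------------------------------------
  d <- stage_dir("04_lifespans")
  ls_file <- file.path(d, "lifespans_merged.tsv")
  s4 <- derive_seed(config$seed, "lifespans")
  if (stage_done("04_lifespans") && file.exists(ls_file)) {
    lf <- utils::read.delim(ls_file)
    merged <- lifespan_table(lf$species_name, lf$ts, lf$te, lf$extant)
  } else {
    nrep <- min(config$lifespan_replicates, config$n_replicates)
    per_subset <- vector("list", config$n_subsets)
    mt_rows <- list()
    for (ss in seq_len(config$n_subsets)) {
      sub <- subset_occurrences(tab, part, ss)
      mt <- model_test(sub, replicate = reps[[1L]],
                       epochs = config$epochs)
      mt_rows[[ss]] <- data.frame(subset = ss, selected = mt$selected)
      med_list <- vector("list", nrep)
      for (r in seq_len(nrep)) {
        cfg_r <- config$lifespan_cfg
        cfg_r$seed <- derive_seed(s4, sprintf("s%d_r%d", ss, r))
        post <- sample_lifespans(sub, replicate = reps[[r]],
                                 model = config$preservation,
                                 epochs = config$epochs, cfg = cfg_r)
        med_list[[r]] <- median_lifespans(post)
      }
      # median of per-replicate medians, per species
      all_med <- do.call(rbind, med_list)
      agg_ts <- tapply(all_med$ts, all_med$species_name, stats::median)
      agg_te <- tapply(all_med$te, all_med$species_name, stats::median)
      agg_ex <- tapply(all_med$extant, all_med$species_name, any)
      sp <- names(agg_ts)
      per_subset[[ss]] <- lifespan_table(
        sp, as.numeric(agg_ts),
        ifelse(as.logical(agg_ex), 0, as.numeric(agg_te)),
        as.logical(agg_ex))
    }
    merged <- merge_lifespans(per_subset)
    utils::write.table(as.data.frame(merged), ls_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(do.call(rbind, mt_rows),
                       file.path(d, "model_selection.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    mark_done("04_lifespans")
  }
  note("04_lifespans", s4)
  res$lifespans <- merged

  # -- stage 5: fixed-times rates ---------------------------------------
  d <- stage_dir("05_rates")
  s5 <- derive_seed(config$seed, "rates")
  cfg5 <- config$rates_cfg; cfg5$seed <- s5
  rates_post <- rj_mcmc_rates(merged, cfg5)
  rs <- summarize_rates(rates_post, step = config$ltt_step)
  utils::write.csv(rs, file.path(d, "rate_summary.csv"), row.names = FALSE)
  write_rate_trace(rates_post, file.path(d, "rate_trace.tsv"))
  mark_done("05_rates"); note("05_rates", s5)
  res$rates <- rates_post

  # -- stage 6: trajectories / slopes / per-capita rates -----------------
  d <- stage_dir("06_trajectories")
  span <- ceiling(max(merged$ts))
  fam_of <- tapply(tab$family, tab$species_name, function(x) x[1L])
  traj_rows <- list(); slope_rows <- list()
  fam_traj <- list()
  for (fm in fams) {
    sp <- names(fam_of)[fam_of == fm]
    lf <- merged[merged$species_name %in% sp, , drop = FALSE]
    if (nrow(lf) == 0L) next
    tr <- range_through(lf, step = config$ltt_step, max_age = span)
    fam_traj[[fm]] <- tr
    traj_rows[[fm]] <- data.frame(family = fm, age = tr$age,
                                  count = tr$count)
    sl <- diversity_slope(tr, window = config$slope_window)
    slope_rows[[fm]] <- data.frame(family = fm, sl$series,
                                   mean_slope = sl$mean_slope)
  }
  utils::write.csv(do.call(rbind, traj_rows),
                   file.path(d, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, slope_rows),
                   file.path(d, "slopes.csv"), row.names = FALSE)
  bins <- myr_bins(span, config$bin_width)
  pc_rows <- lapply(seq_len(min(length(res$replicates), 10L)), function(r) {
    fr <- foote_rates(bin_occurrence_ranges(tab, res$replicates[[r]], bins))
    cbind(replicate = r, fr)
  })
  utils::write.csv(do.call(rbind, pc_rows),
                   file.path(d, "per_capita_rates.csv"), row.names = FALSE)
  mark_done("06_trajectories"); note("06_trajectories", NULL)
  res$trajectories <- fam_traj

  # -- stage 7: MBD ------------------------------------------------------
  d <- stage_dir("07_mbd")
  s7 <- derive_seed(config$seed, "mbd")
  grid <- fam_traj[[1L]]$age
  env <- lapply(config$env_covariates, function(cv)
    covariate_series(grid, stats::approx(cv$age, cv$value, xout = grid,
                                         rule = 2)$y,
                     label = attr(cv, "label")))
  names(env) <- names(config$env_covariates)
  fam_cov <- lapply(fam_traj, function(tr)
    covariate_series(tr$age, tr$count))
  run_mbd <- function(lf, covs, tag) {
    cfg7 <- config$mbd_cfg
    cfg7$seed <- derive_seed(s7, tag)
    fit <- mbd_mcmc(lf, covariate_set(covs), link = "exponential",
                    cfg = cfg7)
    sm <- mbd_summary(fit, w_threshold = config$w_threshold)
    utils::write.csv(sm, file.path(d, paste0("mbd_", tag, ".csv")),
                     row.names = FALSE)
    list(fit = fit, summary = sm)
  }
  combined <- run_mbd(merged, c(fam_cov, env), "combined")
  pairwise <- list()
  for (fm in names(fam_traj)) {
    sp <- names(fam_of)[fam_of == fm]
    lf <- merged[merged$species_name %in% sp, , drop = FALSE]
    class(lf) <- c("lifespan_table", "data.frame")
    if (nrow(lf) < 2L) next
    pairwise[[fm]] <- run_mbd(lf, c(fam_cov, env),
                              paste0("pairwise_", fm))
  }
  sens <- list()
  for (sn in names(config$sensitivity)) {
    stab <- filter_occurrences(tab, config$sensitivity[[sn]])
    keep <- merged$species_name %in% unique(stab$species_name)
    lf <- merged[keep, , drop = FALSE]
    class(lf) <- c("lifespan_table", "data.frame")
    if (nrow(lf) < 2L) next
    sens[[sn]] <- run_mbd(lf, c(fam_cov, env), paste0("sens_", sn))
  }
  mark_done("07_mbd"); note("07_mbd", s7)
  res$mbd <- list(combined = combined, pairwise = pairwise,
                  sensitivity = sens)

  # -- stage 8: effect network ------------------------------------------
  d <- stage_dir("08_network")
  edges <- list()
  add_edges <- function(sm, target) {
    for (i in seq_len(nrow(sm))) {
      edges[[length(edges) + 1L]] <<- data.frame(
        source = sm$covariate[i], target = target,
        channel = c("speciation", "extinction"),
        gamma_med = c(sm$gamma_lambda_med[i], sm$gamma_mu_med[i]),
        w_med = c(sm$w_lambda_med[i], sm$w_mu_med[i]),
        stringsAsFactors = FALSE)
    }
  }
  add_edges(combined$summary, "combined")
  for (fm in names(pairwise)) add_edges(pairwise[[fm]]$summary, fm)
  all_effects <- do.call(rbind, edges)
  net <- build_effect_network(all_effects, config$w_threshold)
  utils::write.csv(net$edges, file.path(d, "network_edges.csv"),
                   row.names = FALSE)
  mark_done("08_network"); note("08_network", NULL)
  res$network <- net

  write_manifest(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(res)
}

#' Build a cross-clade effect network
#'
#' Keeps, from a table of per-(source, target, channel) MBD effect
#' summaries, the directed edges whose median shrinkage weight exceeds
#' the threshold; edge sign is the sign of the median correlation
#' parameter (positive = promoting, negative = suppressing). Self-edges
#' (loops) express self-diversity dependence.
#'
#' @param effects data frame with columns `source`, `target`, `channel`,
#'   `gamma_med`, `w_med`.
#' @param threshold shrinkage-weight threshold (default 0.7).
#' @return object of class `effect_network` with `nodes` and the kept
#'   `edges` (plus `sign` and `promoting` columns).
#' @export
build_effect_network <- function(effects, threshold = 0.7) {
  need <- c("source", "target", "channel", "gamma_med", "w_med")
  if (!all(need %in% names(effects)))
    stop("effects table must have columns: ",
         paste(need, collapse = ", "))
  keep <- effects$w_med > threshold
  edges <- effects[keep, , drop = FALSE]
  edges$sign <- sign(edges$gamma_med)
  edges$promoting <- edges$gamma_med > 0
  rownames(edges) <- NULL
  structure(list(nodes = unique(c(effects$source, effects$target)),
                 edges = edges, threshold = threshold),
            class = "effect_network")
}

#' @export
print.effect_network <- function(x, ...) {
  cat(sprintf("Effect network: %d nodes, %d edges (w > %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  if (nrow(x$edges))
    print(x$edges[, c("source", "target", "channel", "gamma_med",
                      "w_med")], row.names = FALSE, digits = 3)
  invisible(x)
}
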