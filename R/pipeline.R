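# End-to-end pipeline on a synthetic landscape: composites ->
# classification -> refinement -> active-fire fusion -> relocation ->
# dating -> patches -> overwintering -> peat attribution -> combustion
# models -> uncertainty.

#' Run the full burned-area / peat-fire / emissions pipeline
#'
#' Trains the burn classifier on the first analysis year (reference-year
#' training, reused across years), classifies and refines every year,
#' fuses active fires (appending, Voronoi dating, previous-year
#' relocation), clusters fire patches, flags overwintering fires,
#' attributes peat fires through area-conserving downscaling, and -- when
#' `do_emissions` -- fits the chained combustion models on the simulated
#' field plots and predicts per-pixel emissions with Gaussian-process
#' uncertainty on the annual totals.
#'
#' @param sim a [simulate_scenes()] result (or a [sim_config()], which is
#'   simulated first).
#' @param do_emissions fit and apply the combustion models.
#' @param emissions_budget hyperparameter draws for [tune_and_select()]
#'   (desk scale; 200 at full scale).
#' @param emissions_repeats evaluation repeats for [fit_evaluate()] (desk
#'   scale; 100 at full scale).
#' @param p_threshold classification threshold on the burn probability.
#' @return list with per-year burned masks (`burned`), day rasters,
#'   `patches`, `overwintering` tables, `peat` attribution, `accuracy`
#'   against ground truth, `relocation` diagnostics, and (optionally)
#'   `models`, `emissions`, `uncertainty`.
#' @export
run_fire_pipeline <- function(sim, do_emissions = FALSE,
                              emissions_budget = 8L, emissions_repeats = 5L,
                              p_threshold = 0.5) {
  if (inherits(sim, "peat_sim_config")) sim <- simulate_scenes(sim)
  truth <- sim$truth
  cfg <- truth$cfg
  Y <- cfg$years
  px <- cfg$pixel_size
  last_obs <- truth$last_obs_day

  comps <- lapply(0:Y, function(y) min_nbr_composite(sim$scenes[[y + 1L]]))
  stacks <- lapply(seq_len(Y), function(y)
    build_feature_stack(comps[[y]], comps[[y + 1L]]))

  # Truth visible to the sensor in year y: same-year scars burned before
  # the last observation, plus the previous year's post-season scars.
  visible <- lapply(seq_len(Y), function(y) {
    v <- truth$scar_mask[[y]] & !is.na(truth$burn_day[[y]]) &
      truth$burn_day[[y]] <= last_obs
    if (y >= 2L)
      v <- v | (truth$scar_mask[[y - 1L]] &
                  !is.na(truth$burn_day[[y - 1L]]) &
                  truth$burn_day[[y - 1L]] > last_obs)
    v
  })

  set.seed(cfg$rng_seed + 3000L)
  samples <- extract_training_samples(stacks[[1L]], visible[[1L]])
  model <- train_burn_rf(samples)

  af_by_year <- split(truth$active_fires, truth$active_fires$year)
  af <- function(y) af_by_year[[as.character(y)]]

  detected <- vector("list", Y)
  for (y in seq_len(Y)) {
    pb <- predict_burn_probability(model, stacks[[y]])
    classified <- !is.na(pb$p_b) & pb$p_b >= p_threshold
    seeds <- confirm_seeds(pb$p_b, classified, model$seed_threshold)
    grown <- grow_region(seeds, stacks[[y]], pb$p_b, pixel_size = px)
    filtered <- filter_patches_by_seeds(grown, seeds)
    cleaned <- morphological_cleanup(filtered)
    af_day <- rasterize_active_fires(af(y), truth$dim, px)
    detected[[y]] <- append_af_pixels(cleaned, af_day, truth$water_cover)
  }

  # Previous-year relocation (late fires surfacing in the next year).
  burned <- detected
  relocated <- vector("list", Y)
  for (y in seq_len(Y)[-1L]) {
    rel <- relocate_year(burned[[y]], af(y - 1L), af(y), pixel_size = px)
    relocated[[y]] <- rel
    burned[[y - 1L]] <- burned[[y - 1L]] | rel
    burned[[y]] <- burned[[y]] & !rel
  }

  days <- vector("list", Y)
  patches <- vector("list", Y)
  for (y in seq_len(Y)) {
    vd <- assign_dates_voronoi(burned[[y]], af(y), comps[[y + 1L]]$day, px)
    days[[y]] <- vd$day
    patches[[y]] <- cluster_patches(vd$day, burned = burned[[y]],
                                    pixel_size = px, year = y)
  }

  peat_est <- downscale_peat(truth$peat_index, truth$coarse_area,
                             cell_px = cfg$coarse_cell_px, pixel_size = px)
  overwinter <- vector("list", Y)
  for (y in seq_len(Y)[-1L])
    overwinter[[y]] <- flag_overwintering(patches[[y]], patches[[y - 1L]],
                                          peat_mask = peat_est)
  peat <- classify_peat_fires(burned, peat_est, pixel_size = px)

  accuracy <- lapply(seq_len(Y), function(y)
    evaluate_burn_map(burned[[y]], truth$scar_mask[[y]],
                      valid = stacks[[y]]$valid | truth$scar_mask[[y]]))

  # Planted relocation diagnostics: late scars must end up in their true
  # year after relocation.
  # Planted relocation diagnostics: of the late-scar pixels *detected* in
  # the following year, the fraction actually moved back to the true year.
  late <- truth$scars[truth$scars$kind == "late", , drop = FALSE]
  reloc_rate <- NA_real_
  if (nrow(late) > 0L) {
    moved <- 0L; det <- 0L
    for (i in seq_len(nrow(late))) {
      yy <- late$year[i]
      if (yy + 1L > Y) next
      sel <- truth$scar_mask[[yy]] & !is.na(truth$burn_day[[yy]]) &
        truth$burn_day[[yy]] > last_obs
      cases <- detected[[yy + 1L]] & sel
      det <- det + sum(cases)
      moved <- moved + sum(relocated[[yy + 1L]] & cases)
    }
    reloc_rate <- if (det > 0L) moved / det else NA_real_
  }

  out <- list(config = cfg, truth = truth, model = model, stacks = stacks,
              burned = burned, days = days, patches = patches,
              overwintering = overwinter, peat_mask = peat_est, peat = peat,
              accuracy = accuracy, relocated = relocated,
              relocation_recovery = reloc_rate)

  if (do_emissions) {
    plots <- simulate_field_plots(cfg)
    set.seed(cfg$rng_seed + 4000L)
    dict <- predictor_dictionary("depth")
    sel_d <- tune_and_select(plots, "burn_depth", dict,
                             budget = emissions_budget, folds = 5L,
                             subset_sizes = c(3, 5, 10, 20, length(dict)),
                             nrounds = 80L)
    sel_b <- list(features = c(sel_d$features, "depth_pred"),
                  params = sel_d$params, nrounds = sel_d$nrounds)
    sel_a <- tune_and_select(plots, "aboveground_cc",
                             predictor_dictionary("aboveground"),
                             budget = emissions_budget, folds = 5L,
                             subset_sizes = c(3, 5, 10, 20),
                             nrounds = 80L)
    models <- fit_evaluate(plots, list(depth = sel_d, below = sel_b,
                                       above = sel_a),
                           folds = 5L, repeats = emissions_repeats)
    any_burned <- Reduce(`|`, burned)
    pred <- predict_pixels(models, truth$predictors, any_burned)
    emis <- aggregate_emissions(pred, any_burned, Reduce(`|`, peat$peat_fire),
                                pixel_area = px^2)
    idx <- which(any_burned)
    unc <- annual_uncertainty(
      cc = pred$belowground_cc[idx] + pred$aboveground_cc[idx],
      coords = pixel_xy(idx, truth$dim, px),
      sigma_cc = models$residual_stats$below$sigma_cc_res,
      mu_res = models$residual_stats$below$mu_res,
      pixel_area = px^2, method = "nystrom", m = 500L)
    out$models <- models
    out$emissions <- emis
    out$uncertainty <- unc
    out$combustion <- pred
  }
  out
}
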