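.config_keys <- c("acquisition", "scene", "simulate", "quantify", "stats",
                  "lrscore", "seed", "verbose")

#' Default run configuration
#'
#' A complete, structured configuration for [run_pipeline()]: acquisition and
#' scene blocks, per-stage parameter blocks and the master seed. Every
#' parameter here is echoed into the parameter log of each run.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    acquisition = list(shape_zyx = c(5L, 160L, 160L), voxel_size_yx = 0.62,
                       z_step = 8, psf_sigma_xy = 0.6, psf_sigma_z = 2,
                       photon_gain = 100, read_noise_sd = 0.01,
                       background = 0.02),
    scene = list(vessel_radius_um = 24, mural_density = 20,
                 fibroblast_density = 8, exclusion_margin_um = 10,
                 effect_multipliers = NULL),
    simulate = list(design = list(list(condition = "psnl-contra",
                                       region = "distal", n = 5L),
                                  list(condition = "psnl-ipsi",
                                       region = "distal", n = 5L)),
                    blur = TRUE, noise = TRUE, layout = "per_channel"),
    quantify = list(fitc_method = "auto", tdtomato_method = "cross",
                    broaden_radius_um = 5, min_area_um2 = 10,
                    n_planes = 5L, spacing_um = 8, overlap_frac = 0),
    stats = list(value = "n_mural", alpha = 0.05, mode = "auto"),
    lrscore = list(alpha = 0.05, min_abs_log2fc = 0, expr_threshold = 0,
                   sender_expr_threshold = 0, scaling = "minmax_0_10"),
    seed = 1L,
    verbose = FALSE
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Values in the file override the defaults; unknown top-level keys are
#' rejected so typos never pass silently.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), .config_keys)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- default_run_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]) &&
        !k %in% c("simulate", "scene")) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else if (k %in% c("simulate", "scene")) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

config_to_acq <- function(cfg) {
  a <- cfg$acquisition
  acquisition_spec(shape_zyx = unlist(a$shape_zyx),
                   voxel_size_yx = a$voxel_size_yx, z_step = a$z_step,
                   psf_sigma_xy = a$psf_sigma_xy, psf_sigma_z = a$psf_sigma_z,
                   photon_gain = a$photon_gain,
                   read_noise_sd = a$read_noise_sd,
                   background = unlist(a$background))
}

config_to_scene <- function(cfg, acq) {
  s <- cfg$scene
  em <- s$effect_multipliers
  if (!is.null(em) && !is.data.frame(em))
    em <- do.call(rbind, lapply(em, as.data.frame))
  default_scene_spec(acq, radius_um = s$vessel_radius_um,
                     mural_density = s$mural_density,
                     fibroblast_density = s$fibroblast_density,
                     exclusion_margin_um = s$exclusion_margin_um,
                     effect_multipliers = em)
}

config_design <- function(cfg) {
  do.call(rbind, lapply(cfg$simulate$design, function(d)
    data.frame(condition = d$condition, region = d$region, n = as.integer(d$n))))
}

# thresholds for one loaded volume, per the quantify config block
config_thresholds <- function(volume, qc) {
  fitc <- if (identical(qc$fitc_method, "manual"))
    compute_threshold(volume, "FITC", "manual", manual_value = qc$fitc_value)
  else compute_threshold(volume, "FITC", "auto")
  td <- switch(qc$tdtomato_method,
    cross = compute_threshold(volume, "tdTomato", "cross",
                              source_threshold = fitc),
    manual = compute_threshold(volume, "tdTomato", "manual",
                               manual_value = qc$tdtomato_value),
    compute_threshold(volume, "tdTomato", "auto"))
  list(fitc = fitc, tdtomato = td)
}

quantify_one <- function(volume, cfg, region_id, condition) {
  qc <- cfg$quantify
  quantify_region(volume, config_thresholds(volume, qc),
                  broaden_radius_um = qc$broaden_radius_um,
                  min_area_um2 = qc$min_area_um2,
                  planes_spec = list(n_planes = qc$n_planes,
                                     spacing_um = qc$spacing_um),
                  overlap_frac = qc$overlap_frac,
                  region_id = region_id, condition = condition)
}

#' Simulate and quantify a two-group injury experiment in memory
#'
#' The end-to-end chain at its default settings: simulates `n_per_group`
#' contralateral and `n_per_group` ipsilateral (injured) nerves with the
#' mural density scaled by `mural_effect` in the injured distal region,
#' quantifies every volume (auto FITC threshold, cross-channel tdTomato
#' threshold, default broadening and area filter), and compares the
#' per-animal region-averaged counts between groups with a two-sided
#' Mann-Whitney test.
#'
#' @param n_per_group animals per group.
#' @param mural_effect mural-density multiplier for the injured group.
#' @param seed master seed.
#' @param acq an [acquisition_spec()].
#' @param value which per-animal measure to test (`"n_mural"`,
#'   `"n_tdtomato"` or `"n_nuclei"`).
#' @param cfg optional `run_config` overriding quantification parameters.
#' @return list with `per_animal` (one row per animal: condition, sample and
#'   the three mean counts) and `mwu`, the `test_result`.
#' @export
injury_effect_experiment <- function(n_per_group = 6L, mural_effect = 2,
                                     seed = 1L, acq = acquisition_spec(),
                                     value = "n_mural",
                                     cfg = default_run_config()) {
  cfg$scene$effect_multipliers <- data.frame(
    condition = "psnl-ipsi", region = "distal",
    mural = mural_effect, fibroblast = 1)
  base <- config_to_scene(cfg, acq)
  design <- data.frame(condition = c("psnl-contra", "psnl-ipsi"),
                       region = "distal", n = n_per_group)
  samples <- simulate_group(design, base, acq, seed = seed,
                            blur = cfg$simulate$blur, noise = cfg$simulate$noise)
  rows <- lapply(samples, function(s) {
    rq <- quantify_one(s$volume, cfg, region_id = paste0(s$condition, "_", s$sample),
                       condition = s$condition)
    data.frame(condition = s$condition, sample = s$sample,
               n_nuclei = rq$means[["n_nuclei"]],
               n_mural = rq$means[["n_mural"]],
               n_tdtomato = rq$means[["n_tdtomato"]])
  })
  per_animal <- do.call(rbind, rows)
  g <- split(per_animal[[value]], per_animal$condition)
  mwu <- mann_whitney(g[["psnl-contra"]], g[["psnl-ipsi"]],
                      mode = cfg$stats$mode)
  list(per_animal = per_animal, mwu = mwu)
}

log_params <- function(cfg, seed, out_dir, stage) {
  yaml::write_yaml(list(stage = stage, seed = seed,
                        package_version = as.character(utils::packageVersion("perivquant")),
                        config = unclass(cfg)),
                   file.path(out_dir, paste0(stage, "_params.yml")))
}

#' Run a pipeline stage
#'
#' File-based entry point behind the command-line interface. Stages:
#' \describe{
#'   \item{simulate}{writes one TIFF volume (+ YAML sidecar) and one
#'     ground-truth CSV per simulated sample.}
#'   \item{quantify}{loads every volume under `input_dir`, quantifies it and
#'     writes `region_counts.csv` + `quantify_params.csv`.}
#'   \item{quantify-eval}{quantify, plus precision/recall/F1 against the
#'     ground-truth CSVs, written to `evaluation.csv`.}
#'   \item{stats}{reads `region_counts.csv`, averages planes per sample and
#'     compares conditions (Mann-Whitney for two, Kruskal-Wallis + Dunn for
#'     more), writing `stats_results.csv`.}
#'   \item{lrscore}{reads DE/ligand-receptor/receiver CSVs (or generates the
#'     built-in synthetic tables), writes communication scores, per-pair
#'     contributions and the pre/post enabled-interaction comparison.}
#' }
#' Every stage writes a YAML parameter log sufficient to re-execute it;
#' identical config and seed give byte-identical CSV outputs.
#'
#' @param stage one of `"simulate"`, `"quantify"`, `"quantify-eval"`,
#'   `"stats"`, `"lrscore"`.
#' @param cfg a `run_config` (see [default_run_config()], [load_run_config()]).
#' @param out_dir output directory (created if missing).
#' @param input_dir input directory for quantify/stats stages; defaults to
#'   `out_dir`.
#' @param seed master seed override (defaults to `cfg$seed`).
#' @param de,lr_db,receivers optional inputs for `lrscore`: a DE table
#'   data.frame or CSV path, an [lr_database()] or CSV path (columns ligand,
#'   receptors semicolon-joined, family, source), and a gene x population
#'   matrix or CSV path. Defaults are the package's synthetic tables.
#' @return invisibly, a list of the artifacts written.
#' @export
run_pipeline <- function(stage = c("simulate", "quantify", "quantify-eval",
                                   "stats", "lrscore"),
                         cfg = default_run_config(), out_dir = ".",
                         input_dir = NULL, seed = NULL,
                         de = NULL, lr_db = NULL, receivers = NULL) {
  stage <- match.arg(stage)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  input_dir <- input_dir %||% out_dir
  seed <- as.integer(seed %||% cfg$seed)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  if (stage == "simulate") {
    acq <- config_to_acq(cfg)
    base <- config_to_scene(cfg, acq)
    design <- config_design(cfg)
    samples <- simulate_group(design, base, acq, seed = seed,
                              blur = cfg$simulate$blur,
                              noise = cfg$simulate$noise)
    files <- character()
    for (s in samples) {
      label <- sprintf("%s_%s_%02d", s$condition, s$region, s$sample)
      prefix <- file.path(out_dir, label)
      write_volume(s$volume, prefix, layout = cfg$simulate$layout)
      write_ground_truth(s$truth, paste0(prefix, "_truth.csv"))
      files <- c(files, prefix)
      say("simulate: wrote %s", label)
    }
    log_params(cfg, seed, out_dir, "simulate")
    return(invisible(list(prefixes = files)))
  }

  if (stage %in% c("quantify", "quantify-eval")) {
    sidecars <- sort(list.files(input_dir, pattern = "\\.yml$", full.names = TRUE))
    sidecars <- sidecars[!grepl("_params\\.yml$", sidecars)]
    if (!length(sidecars)) stop("no volume sidecars found in ", input_dir,
                                call. = FALSE)
    quants <- list()
    evals <- list()
    for (sc in sidecars) {
      prefix <- sub("\\.yml$", "", sc)
      vol <- load_stack(prefix)
      label <- basename(prefix)
      rq <- quantify_one(vol, cfg, region_id = label,
                         condition = vol$condition %||% "unknown")
      quants[[label]] <- rq
      say("quantify: %s mural %.2f", label, rq$means[["n_mural"]])
      if (stage == "quantify-eval") {
        tp <- paste0(prefix, "_truth.csv")
        if (file.exists(tp)) {
          cells <- read_ground_truth(tp)
          truth <- structure(list(cells = cells,
                                  condition = vol$condition, region = vol$region),
                             class = "ground_truth")
          ev <- evaluate_against_truth(rq, truth, vol$acquisition)
          ev$region <- label
          evals[[label]] <- ev
        }
      }
    }
    write_region_quant(quants, file.path(out_dir, "region_counts.csv"))
    write_quant_params(quants, file.path(out_dir, "quantify_params.csv"))
    if (stage == "quantify-eval" && length(evals))
      utils::write.csv(do.call(rbind, evals),
                       file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    log_params(cfg, seed, out_dir, "quantify")
    return(invisible(list(quants = quants, evals = evals)))
  }

  if (stage == "stats") {
    counts <- utils::read.csv(file.path(input_dir, "region_counts.csv"))
    value <- cfg$stats$value
    per_sample <- stats::aggregate(counts[[value]],
                                   by = list(region = counts$region,
                                             condition = counts$condition),
                                   FUN = mean)
    groups <- split(per_sample$x, per_sample$condition)
    if (length(groups) < 2L) stop("stats stage needs >= 2 conditions", call. = FALSE)
    if (length(groups) == 2L) {
      tr <- mann_whitney(groups[[1]], groups[[2]], mode = cfg$stats$mode)
      res <- data.frame(comparison = paste(names(groups), collapse = " vs "),
                        method = paste0("mann_whitney_", tr$mode),
                        statistic = tr$statistic[["U"]],
                        p = tr$p_value, p_adj = tr$p_value)
    } else {
      kw <- kruskal_wallis(groups)
      dn <- dunn_posthoc(groups)
      res <- rbind(
        data.frame(comparison = "omnibus", method = "kruskal_wallis",
                   statistic = kw$statistic[["H"]], p = kw$p_value,
                   p_adj = NA_real_),
        data.frame(comparison = paste(dn$comparisons$group1, "vs",
                                      dn$comparisons$group2),
                   method = "dunn", statistic = dn$comparisons$z,
                   p = dn$comparisons$p, p_adj = dn$comparisons$p_adj))
    }
    res$value <- value
    res$alpha <- cfg$stats$alpha
    utils::write.csv(res, file.path(out_dir, "stats_results.csv"),
                     row.names = FALSE)
    log_params(cfg, seed, out_dir, "stats")
    return(invisible(list(results = res)))
  }

  # lrscore
  lc <- cfg$lrscore
  if (is.character(de)) de <- utils::read.csv(de)
  if (is.null(de)) de <- simulate_de_table(seed = seed)
  if (is.character(lr_db)) {
    tab <- utils::read.csv(lr_db)
    lr_db <- lr_database(tab$ligand, tab$receptors, tab$family, tab$source)
  }
  if (is.null(lr_db)) lr_db <- default_lr_database()
  if (is.character(receivers)) {
    tab <- utils::read.csv(receivers, row.names = 1L)
    receivers <- as.matrix(tab)
  }
  if (is.null(receivers)) receivers <- simulate_receiver_profiles(seed = seed)
  up <- select_regulated_genes(de, alpha = lc$alpha, direction = "up",
                               min_abs_log2fc = lc$min_abs_log2fc)
  sender_post <- stats::setNames(de$mean_injured, de$gene)
  sender_pre <- stats::setNames(de$mean_control, de$gene)
  panel <- expression_panel(receivers, sender = sender_post)
  scores <- list(); contribs <- list(); compare <- list()
  for (rc in colnames(receivers)) {
    prof <- receivers[, rc]
    matched <- match_ligand_receptor(up, lr_db, prof,
                                     expr_threshold = lc$expr_threshold)
    sc <- communication_scores(sender_post, prof, matched,
                               scaling = lc$scaling, panel = panel,
                               sender_label = "injured", receiver_label = rc)
    scores[[rc]] <- sc
    contribs[[rc]] <- attr(sc, "contributions")
    enabled <- function(sender) {
      lig <- names(sender)[sender > lc$sender_expr_threshold]
      nrow(match_ligand_receptor(lig, lr_db, prof,
                                 expr_threshold = lc$expr_threshold))
    }
    ct <- compare_interaction_counts(enabled(sender_pre), enabled(sender_post),
                                     nrow(lr_db))
    compare[[rc]] <- data.frame(receiver = rc,
                                pre = ct$table["matched", "pre"],
                                post = ct$table["matched", "post"],
                                universe = nrow(lr_db),
                                p = ct$p_value, direction = ct$direction)
  }
  scores_df <- do.call(rbind, scores)
  utils::write.csv(scores_df, file.path(out_dir, "communication_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, contribs),
                   file.path(out_dir, "pair_contributions.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, compare),
                   file.path(out_dir, "interaction_counts.csv"),
                   row.names = FALSE)
  log_params(cfg, seed, out_dir, "lrscore")
  invisible(list(scores = scores_df, compare = do.call(rbind, compare)))
}
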