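default_config <- function() {
  list(
    seed = 1L,
    condition = "control",
    mode = "simulate",
    camera = unclass(camera_model()),
    truth = unclass(ground_truth()),
    simulate = list(n_cells = 5L, frames_per_cell = 4L,
                    shape_px = c(128L, 128L), spot_density = 0.05),
    monomer_calibration = list(simulate_n = 2000L, imaged = TRUE),
    detection = list(psf_sigma_px = 1.2, k_sigma = 5, window_px = 9L),
    mixture = list(n_max = 3L, bootstrap_reps = 100L, bootstrap_frac = 0.5),
    pooling = "experiment",
    min_spots_per_cell = 100L,
    out_dir = "toccsl-results"
  )
}

# recursively overlay user config onto defaults
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Configurations are JSON (nested key/value); any key omitted falls back
#' to the package default. File paths referenced by the config must exist
#' at load time.
#'
#' @param config path to a JSON file, or a named list.
#' @return validated config list with attributes `hash` (md5 of the
#'   canonical JSON) and `path`.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    assert(file.exists(config), sprintf("config file not found: %s", config),
           "toccsl_config_error")
    user <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  } else {
    assert(is.list(config), "`config` must be a path or a list",
           "toccsl_config_error")
    user <- config
  }
  cfg <- merge_config(default_config(), user)
  assert(cfg$mode %in% c("simulate", "images"),
         "mode must be 'simulate' or 'images'", "toccsl_config_error")
  assert(cfg$pooling %in% c("experiment", "cell"),
         "pooling must be 'experiment' or 'cell'", "toccsl_config_error")
  if (cfg$mode == "images") {
    cells <- cfg$images$cells
    assert(!is.null(cells) && length(cells) > 0,
           "images mode requires images$cells", "toccsl_config_error")
    paths <- unlist(lapply(cells, function(cl) c(cl$prebleach, cl$toccsl)))
    missing <- paths[!file.exists(paths)]
    assert(length(missing) == 0,
           sprintf("missing image file(s): %s",
                   paste(missing, collapse = ", ")), "toccsl_config_error")
  }
  if (!is.null(cfg$monomer_calibration$csv))
    assert(file.exists(cfg$monomer_calibration$csv),
           sprintf("monomer calibration CSV not found: %s",
                   cfg$monomer_calibration$csv), "toccsl_config_error")
  # out_dir is provenance-neutral: the same analysis into two different
  # directories must produce byte-identical files
  canon_cfg <- cfg
  canon_cfg$out_dir <- NULL
  canon <- jsonlite::toJSON(canon_cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(canon, tf)
  attr(cfg, "hash") <- unname(tools::md5sum(tf))
  unlink(tf)
  cfg
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, as.integer(seed)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skipping the provenance header)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

cell_list <- function(cfg) {
  if (cfg$mode == "images") return(cfg$images$cells)
  lapply(seq_len(cfg$simulate$n_cells), function(i)
    list(cell_id = sprintf("sim%02d", i)))
}

camera_from_config <- function(cfg) {
  do.call(camera_model, cfg$camera)
}

truth_from_config <- function(cfg) {
  do.call(ground_truth, cfg$truth)
}

# emulate the monomer-calibration protocol (repeated partial bleaching
# leaves at most one active fluorophore per oligomer): render sparse
# pure-monomer frames and measure their brightness through the standard
# detect/fit path, until `simulate_n` spots are collected
simulate_imaged_monomers <- function(cfg, camera, seed) {
  truth <- truth_from_config(cfg)
  mono_truth <- ground_truth(1, truth$monomer_median, truth$monomer_gsd,
                             active_prob = 1,
                             density = cfg$simulate$spot_density)
  det <- cfg$detection
  shp <- as.integer(cfg$simulate$shape_px)
  target <- as.integer(cfg$monomer_calibration$simulate_n)
  out <- numeric(0)
  f <- 0L
  while (length(out) < target && f < 10000L) {
    f <- f + 1L
    tab <- sim_spot_field(mono_truth, camera, shp, seed = seed + f)
    raw <- render_frame(tab, det$psf_sigma_px, camera, shp,
                        seed = seed + f + 500000L)
    bt <- extract_brightness_table(list(raw), camera,
                                   psf_sigma_hint = det$psf_sigma_px,
                                   k_sigma = det$k_sigma,
                                   window = as.integer(det$window_px))
    out <- c(out, bt$B_photons)
  }
  assert(length(out) >= 50L,
         "monomer calibration produced too few spots", "toccsl_data_error")
  out[seq_len(min(length(out), target))]
}

#' Run the full TOCCSL analysis pipeline
#'
#' For each cell: photon conversion, spot detection, Gaussian fitting,
#' surface-density estimation from the prebleach frame, then (pooled per
#' experiment or per cell, per config) monomer-PDF estimation,
#' autoconvolution mixture fit, and bootstrap. Writes `brightness.csv`
#' (all accepted spots), `cells.csv` (per-cell density, spot counts and
#' per-cell fits where sample size allows), `aggregate.csv` (the pooled
#' fit), and `report.md` to `out_dir`. Every output carries the config
#' hash and seed in a header line, and reruns with an identical config are
#' byte-identical.
#'
#' @param config path to a JSON config, or a named list (see
#'   [load_config()]).
#' @return invisible list with `cells`, `brightness`, `aggregate`
#'   data.frames and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  camera <- camera_from_config(cfg)
  det <- cfg$detection
  seed <- as.integer(cfg$seed)

  # monomer calibration sample -> rho_1. In simulate mode the calibration
  # is imaged through the same render/detect/fit path by default, as in
  # the experiment: rho_1 must carry the same measurement noise as the
  # spot brightness values it will be compared with.
  mono <- if (!is.null(cfg$monomer_calibration$csv)) {
    tab <- read.csv(cfg$monomer_calibration$csv, comment.char = "#")
    assert("brightness" %in% names(tab) || "B_photons" %in% names(tab),
           "monomer CSV needs a 'brightness' or 'B_photons' column",
           "toccsl_data_error")
    if ("brightness" %in% names(tab)) tab$brightness else tab$B_photons
  } else if (isTRUE(cfg$monomer_calibration$imaged) &&
             cfg$mode == "simulate") {
    simulate_imaged_monomers(cfg, camera, seed + 1000L)
  } else {
    sim_monomer_brightness(truth_from_config(cfg),
                           cfg$monomer_calibration$simulate_n,
                           seed = seed + 1000L)
  }
  single_brightness <- mean(mono)
  n_max <- as.integer(cfg$mixture$n_max)
  rho1 <- estimate_monomer_pdf(mono, n_max = n_max)

  cells <- cell_list(cfg)
  cell_rows <- list(); bright_rows <- list()
  n_rejected <- 0L
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    res <- tryCatch({
      if (cfg$mode == "simulate") {
        truth <- truth_from_config(cfg)
        shp <- as.integer(cfg$simulate$shape_px)
        pre_tab <- sim_spot_field(truth, camera, shp, seed = seed + 10L * i)
        pre_raw <- render_frame(pre_tab, det$psf_sigma_px, camera, shp,
                                seed = seed + 10L * i + 1L)
        # sparse postbleach-like frames at the configured visible density
        sparse <- ground_truth(truth$fractions, truth$monomer_median,
                               truth$monomer_gsd, truth$active_prob,
                               density = cfg$simulate$spot_density)
        frames <- lapply(seq_len(cfg$simulate$frames_per_cell), function(f) {
          tab <- sim_spot_field(sparse, camera, shp,
                                seed = seed + 10L * i + 100L * f)
          tab <- tab[tab$visible, , drop = FALSE]
          render_frame(tab, det$psf_sigma_px, camera, shp,
                       seed = seed + 10L * i + 100L * f + 1L)
        })
      } else {
        pre_raw <- read_tiff16(cl$prebleach)[[1]]
        frames <- unlist(lapply(cl$toccsl, read_tiff16), recursive = FALSE)
      }
      pre <- counts_to_photons(pre_raw, camera)
      dens <- estimate_surface_density(pre, single_brightness)
      tab <- extract_brightness_table(frames, camera,
                                      psf_sigma_hint = det$psf_sigma_px,
                                      k_sigma = det$k_sigma,
                                      window = as.integer(det$window_px),
                                      keep_rejected = TRUE)
      n_rej <- sum(!tab$accepted)
      tab <- tab[tab$accepted, , drop = FALSE]
      list(density = dens, tab = tab, n_rej = n_rej)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[toccsl] cell %s failed: %s", cl$cell_id,
                      conditionMessage(res)))
      cell_rows[[i]] <- data.frame(cell_id = cl$cell_id,
                                   condition = cfg$condition,
                                   density = NA_real_, n_spots = 0L,
                                   avg_state = NA_real_, status = "failed")
      next
    }
    n_rejected <- n_rejected + res$n_rej
    tab <- res$tab
    if (nrow(tab) == 0) {
      warning(sprintf("cell %s: empty brightness table, skipped", cl$cell_id))
      cell_rows[[i]] <- data.frame(cell_id = cl$cell_id,
                                   condition = cfg$condition,
                                   density = res$density, n_spots = 0L,
                                   avg_state = NA_real_, status = "empty")
      next
    }
    avg_state <- NA_real_
    if (nrow(tab) >= cfg$min_spots_per_cell) {
      fit <- fit_mixture(tab$B_photons, rho1, n_max)
      avg_state <- fit$avg_state
    }
    cell_rows[[i]] <- data.frame(cell_id = cl$cell_id,
                                 condition = cfg$condition,
                                 density = res$density,
                                 n_spots = nrow(tab),
                                 avg_state = avg_state, status = "ok")
    bright_rows[[i]] <- cbind(cell_id = cl$cell_id, tab)
  }
  cells_df <- do.call(rbind, cell_rows)
  bright_df <- if (length(bright_rows)) do.call(rbind, bright_rows) else
    data.frame()
  assert(nrow(bright_df) > 0, "no spots detected in any cell",
         "toccsl_data_error")

  pooled <- bright_df$B_photons
  agg <- bootstrap_fractions(pooled, rho1, n_max,
                             subsample_frac = cfg$mixture$bootstrap_frac,
                             reps = cfg$mixture$bootstrap_reps,
                             seed = seed + 7L)
  agg_df <- data.frame(condition = cfg$condition,
                       n_samples = agg$n_samples,
                       n_clipped = agg$n_clipped,
                       t(setNames(agg$alphas,
                                  paste0("alpha_", seq_len(n_max)))),
                       t(setNames(agg$alpha_sds,
                                  paste0("sd_", seq_len(n_max)))),
                       avg_state = agg$avg_state,
                       single_brightness = single_brightness)

  hash <- attr(cfg, "hash")
  write_stamped_csv(cells_df, file.path(cfg$out_dir, "cells.csv"), hash, seed)
  write_stamped_csv(bright_df, file.path(cfg$out_dir, "brightness.csv"),
                    hash, seed)
  write_stamped_csv(agg_df, file.path(cfg$out_dir, "aggregate.csv"),
                    hash, seed)
  rep_lines <- c(
    "# TOCCSL pipeline report", "",
    sprintf("- config hash: %s, seed: %d", hash, seed),
    sprintf("- condition: %s", cfg$condition),
    sprintf("- cells analyzed: %d (ok: %d)", nrow(cells_df),
            sum(cells_df$status == "ok")),
    sprintf("- accepted spots: %d, rejected fits: %d", nrow(bright_df),
            n_rejected),
    sprintf("- single-molecule brightness: %.2f photons", single_brightness),
    "",
    "## Oligomer distribution (pooled)", "",
    sprintf("- alpha_%d = %.4f (sd %.4f)", seq_len(n_max), agg$alphas,
            agg$alpha_sds),
    sprintf("- average oligomeric state <n> = %.4f", agg$avg_state))
  writeLines(rep_lines, file.path(cfg$out_dir, "report.md"))
  invisible(list(cells = cells_df, brightness = bright_df,
                 aggregate = agg_df, distribution = agg,
                 out_dir = cfg$out_dir))
}

#' Spearman correlation of surface density and average oligomeric state
#'
#' @param cells data.frame with columns `density` and `avg_state`
#'   (>= 10 complete rows).
#' @return list with `r` (Spearman rho) and `p` (two-tailed).
#' @export
density_oligomer_correlation <- function(cells) {
  assert(is.data.frame(cells) &&
         all(c("density", "avg_state") %in% names(cells)),
         "`cells` needs columns density and avg_state")
  ok <- complete.cases(cells[, c("density", "avg_state")])
  x <- cells$density[ok]; y <- cells$avg_state[ok]
  assert(length(x) >= 10L, "at least 10 cells are required")
  assert(sd(x) > 0 && sd(y) > 0,
         "correlation undefined for constant input",
         "toccsl_undefined_result")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compare two conditions with a two-tailed Mann-Whitney test
#'
#' @param group1,group2 numeric vectors of per-experiment statistics
#'   (average oligomeric state or a fraction), each of length >= 3.
#' @return list with `U` (Mann-Whitney statistic) and `p` (two-tailed).
#' @export
compare_conditions <- function(group1, group2) {
  assert(is.numeric(group1) && length(group1) >= 3L &&
         is.numeric(group2) && length(group2) >= 3L,
         "both groups need at least 3 values")
  wt <- suppressWarnings(wilcox.test(group1, group2,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}
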