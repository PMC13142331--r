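# Analysis configuration and the staged pipeline runner.

#' Analysis configuration
#'
#' Bundles the pipeline constants. The defaults are the working values of
#' the protein-PAINT analysis: 80 nm linking radius with a 5-frame gap
#' joining length, 5 nm site-map pixels, 45 nm event-assignment radius,
#' 10 nm condensate-map pixels with sigma = 1 px smoothing and a 0.01 um^2
#' minimum region area, DBSCAN at eps = 200 nm / 3 points, and 50 ms
#' exposure.
#'
#' @param render_px_site_nm Site density-map pixel (nm).
#' @param render_px_condensate_nm Condensate map pixel (nm).
#' @param assign_radius_nm Event-to-site assignment radius (nm).
#' @param link_radius_nm,link_max_gap_frames Linking parameters.
#' @param smooth_sigma_px Condensate-map smoothing SD (pixels).
#' @param min_condensate_area_um2 Minimum retained condensate area.
#' @param dbscan_eps_nm,dbscan_min_pts DBSCAN parameters.
#' @param exposure_s Frame exposure (s).
#' @param probe_concentration_uM Probe concentration (uM).
#' @param precision_nm Localisation precision SD (nm).
#' @param min_site_events Minimum events for an accepted site.
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(render_px_site_nm = 5,
                            render_px_condensate_nm = 10,
                            assign_radius_nm = 45,
                            link_radius_nm = 80, link_max_gap_frames = 5,
                            smooth_sigma_px = 1,
                            min_condensate_area_um2 = 0.01,
                            dbscan_eps_nm = 200, dbscan_min_pts = 3,
                            exposure_s = 0.05, probe_concentration_uM = 0.01,
                            precision_nm = 10, min_site_events = 5,
                            seed = 1L) {
  vals <- list(render_px_site_nm = render_px_site_nm,
               render_px_condensate_nm = render_px_condensate_nm,
               assign_radius_nm = assign_radius_nm,
               link_radius_nm = link_radius_nm,
               link_max_gap_frames = link_max_gap_frames,
               smooth_sigma_px = smooth_sigma_px,
               min_condensate_area_um2 = min_condensate_area_um2,
               dbscan_eps_nm = dbscan_eps_nm,
               dbscan_min_pts = dbscan_min_pts,
               exposure_s = exposure_s,
               probe_concentration_uM = probe_concentration_uM,
               precision_nm = precision_nm,
               min_site_events = min_site_events,
               seed = as.integer(seed))
  pos <- setdiff(names(vals), c("link_max_gap_frames", "seed",
                                "dbscan_min_pts", "min_site_events"))
  for (nm in pos) {
    if (!is.numeric(vals[[nm]]) || vals[[nm]] <= 0) {
      abort(sprintf("`%s` must be positive", nm))
    }
  }
  structure(vals, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param config An `analysis_config`.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

stage_log <- function(stage, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — `simulate`, `link`, `sites`,
#' `kinetics`, `condensates`, `spatial` — writing every intermediate table
#' under `out_dir` together with a manifest (configuration snapshot, seed,
#' package version, per-file MD5 checksums). Re-running with the same
#' configuration and seed reproduces the outputs bit-identically. A stage
#' whose prerequisite has not run (in this call or a previous one writing to
#' the same directory) fails naming the missing input.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Ordered subset of the stage names above.
#' @param sim A [sim_config()], required by the `simulate` stage.
#' @param locs Localisation tibble (nm) for `link` when not simulating; a
#'   `species` column splits channels.
#' @param diffuse Diffuse-event tibble for `condensates` when not simulating.
#' @param window Field of view when not simulating.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "link", "sites", "kinetics",
                                    "condensates", "spatial"),
                         sim = NULL, locs = NULL, diffuse = NULL,
                         window = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  all_stages <- c("simulate", "link", "sites", "kinetics", "condensates",
                  "spatial")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s",
                                 paste(bad, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- list(locs = locs, diffuse = diffuse, window = window)
  files <- character(0)
  put <- function(obj, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(obj, p)
    files <<- c(files, p)
    p
  }
  need <- function(what, field, file) {
    if (!is.null(st[[field]])) return(st[[field]])
    p <- file.path(out_dir, file)
    if (file.exists(p)) return(readr::read_csv(p, show_col_types = FALSE))
    abort(sprintf("stage prerequisite missing: %s (no in-memory `%s` and no %s)",
                  what, field, file))
  }

  movie <- NULL
  if ("simulate" %in% stages) {
    if (is.null(sim)) abort("stage `simulate` needs a sim_config")
    res <- simulate_paint(sim)
    st$locs <- res$locs
    st$diffuse <- res$diffuse
    st$window <- sim$window
    st$truth <- res
    movie <- sim$movie
    put(res$points, "truth_sites.csv")
    put(res$locs, "localisations.csv")
    if (!is.null(res$diffuse)) put(res$diffuse, "diffuse_events.csv")
    if (!is.null(res$mask)) {
      write_mask_tiff(res$mask, file.path(out_dir, "truth_mask.tif"))
      files <- c(files, file.path(out_dir, "truth_mask.tif"))
    }
    stage_log("simulate", "%d sites, %d localisations, %d diffuse events",
              nrow(res$points), nrow(res$locs),
              if (is.null(res$diffuse)) 0L else nrow(res$diffuse))
  }
  if (is.null(movie)) {
    nf <- if (!is.null(st$locs)) max(st$locs$frame) + 1L else 1000L
    movie <- movie_params(config$exposure_s, nf, config$probe_concentration_uM)
  }

  if ("link" %in% stages) {
    lc <- need("localisations", "locs", "localisations.csv")
    sp <- lc[["species"]] %||% rep("A", nrow(lc))
    ev <- purrr::map_dfr(unique(sp), function(s) {
      e <- link_events(lc[sp == s, ], config$link_radius_nm,
                       config$link_max_gap_frames, config$exposure_s,
                       n_frames = movie$n_frames)
      e$species <- s
      e
    })
    st$events <- ev
    put(ev, "events.csv")
    stage_log("link", "%d localisations -> %d events", nrow(lc), nrow(ev))
  }

  if ("sites" %in% stages) {
    ev <- need("events", "events", "events.csv")
    if (is.null(st$window)) abort("stage prerequisite missing: window extent")
    sp <- ev[["species"]] %||% rep("A", nrow(ev))
    res <- purrr::map(unique(sp), function(s) {
      img <- render_density(ev[sp == s, ], config$render_px_site_nm,
                            st$window, quiet = TRUE)
      sites <- detect_sites(img, config$precision_nm, config$min_site_events)
      asg <- assign_events(sites, ev[sp == s, ], config$assign_radius_nm)
      asg$sites$species <- s
      asg$events$species <- s
      asg
    })
    st$sites <- dplyr::bind_rows(purrr::map(res, "sites"))
    st$assigned_events <- dplyr::bind_rows(purrr::map(res, "events"))
    put(st$sites, "sites.csv")
    put(st$assigned_events, "events_assigned.csv")
    stage_log("sites", "%d sites accepted (%d overlapping)",
              nrow(st$sites), sum(st$sites$overlapping))
  }

  if ("kinetics" %in% stages) {
    sites <- need("sites", "sites", "sites.csv")
    ev <- need("assigned events", "assigned_events", "events_assigned.csv")
    sp <- sites[["species"]] %||% rep("A", nrow(sites))
    kin <- purrr::map_dfr(unique(sp), function(s) {
      k <- kinetics_table(list(events = ev[(ev[["species"]] %||% "A") == s, ],
                               sites = sites[sp == s, ]),
                          movie, config$link_max_gap_frames)
      if (nrow(k)) k$species <- s
      k
    })
    st$kinetics <- kin
    put(kin, "kinetics.csv")
    stage_log("kinetics", "%d site fits", nrow(kin))
  }

  if ("condensates" %in% stages) {
    df <- need("diffuse events", "diffuse", "diffuse_events.csv")
    if (is.null(st$window)) abort("stage prerequisite missing: window extent")
    mask <- segment_condensates(df, st$window,
                                config$render_px_condensate_nm,
                                config$smooth_sigma_px,
                                config$min_condensate_area_um2)
    st$mask <- mask
    sites <- need("sites", "sites", "sites.csv")
    cls <- classify_sites(sites, mask)
    st$sites <- cls
    stats <- condensate_stats(mask, cls, df,
                              movie$n_frames * movie$exposure_s)
    st$condensates <- stats
    write_mask_tiff(mask, file.path(out_dir, "condensate_mask.tif"))
    files <- c(files, file.path(out_dir, "condensate_mask.tif"))
    put(cls, "sites_classified.csv")
    put(stats, "condensates.csv")
    stage_log("condensates", "%d regions retained", nrow(stats))
  }

  if ("spatial" %in% stages) {
    sites <- need("sites", "sites", "sites_classified.csv")
    if (is.null(st$mask)) abort("stage prerequisite missing: condensate mask (run `condensates`)")
    sp <- unique(sites[["species"]] %||% "A")
    for (s in sp) {
      pts <- sites[(sites[["species"]] %||% "A") == s, ]
      ac <- pair_correlation(pts, NULL, st$window,
                             config$render_px_condensate_nm)
      write_profile(ac, file.path(out_dir, paste0("autocorr_", s, ".csv")))
      files <- c(files, file.path(out_dir, paste0("autocorr_", s, ".csv")))
      lp <- tryCatch(ripley_l_masked(pts, st$mask), error = function(e) NULL)
      if (!is.null(lp)) {
        write_profile(lp, file.path(out_dir, paste0("ripley_masked_", s, ".csv")))
        files <- c(files, file.path(out_dir, paste0("ripley_masked_", s, ".csv")))
      }
    }
    if (length(sp) >= 2) {
      cl <- tryCatch(
        cross_ripley_masked(sites[(sites[["species"]] %||% "A") == sp[1], ],
                            sites[(sites[["species"]] %||% "A") == sp[2], ],
                            st$mask),
        error = function(e) NULL)
      if (!is.null(cl)) {
        write_profile(cl, file.path(out_dir, "cross_ripley.csv"))
        files <- c(files, file.path(out_dir, "cross_ripley.csv"))
      }
    }
    stage_log("spatial", "profiles written for %d species", length(sp))
  }

  manifest <- list(
    package = "nanopaint",
    version = as.character(utils::packageVersion("nanopaint")),
    config = unclass(config),
    stages = stages,
    checksums = as.list(tools::md5sum(sort(unique(files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(st, list(manifest = manifest)))
}
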