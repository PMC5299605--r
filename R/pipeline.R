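#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by
#' [run_segmentation()], with one section per pipeline stage mirroring
#' [rpe_bm_params()], [smoothing_params()], [csi_params()] and the map /
#' descriptor settings. Every key is documented in those constructors.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    rpe_bm = unclass(rpe_bm_params()),
    smoothing = unclass(smoothing_params()),
    csi = unclass(csi_params()),
    maps = list(grid_um = 50, retina_stride = 4L),
    descriptors = list(),
    seed = 1L
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with the sections of [default_config()]; missing keys take
#' their defaults, unknown sections or keys are rejected.
#'
#' @param path Path to a YAML config file, or `NULL` for the defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) abort(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  for (sec in names(user)) {
    if (sec == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badk)) {
      abort(sprintf("unknown key(s) in [%s]: %s", sec, paste(badk, collapse = ", ")))
    }
    cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
  }
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x),
                   path)
  invisible(path)
}

config_params <- function(cfg) {
  list(
    rpe_bm = do.call(rpe_bm_params, cfg$rpe_bm),
    smoothing = do.call(smoothing_params, cfg$smoothing),
    csi = do.call(csi_params, cfg$csi)
  )
}

#' Run the full choroid segmentation pipeline on a volume
#'
#' Stages: (1) RVI/RPE/BM segmentation per B-scan; (2) flattening and
#' transverse Gaussian smoothing; (3) CSI graph search per smoothed B-scan
#' with overlap resolution; (4) scattered thickness points, retinal and
#' choroidal thickness maps; (5) macula-centered 3-D descriptors. All
#' stages are deterministic, so a rerun with the same inputs and
#' configuration is bit-identical. When `out_dir` is given, traces (raw
#' frame), maps, descriptors, the success fraction, a parameter log and a
#' MANIFEST of completed stages are written there; on a stage failure the
#' partial artifacts are kept and `status` is non-zero.
#'
#' @param volume An [oct_volume()] or a volume directory for
#'   [read_oct_volume()].
#' @param config A `pipeline_config`, a YAML path, or `NULL` for defaults.
#' @param out_dir Optional artifact directory.
#' @return A list of class `choroid_segmentation` with `status` (0 = all
#'   stages completed), `manifest`, `traces` (tidy table, raw frame),
#'   `csi_segments`, `segmented` (per-B-scan logical),
#'   `success_fraction`, `points`, `choroid_map`, `retina_map`,
#'   `descriptors`, `config`.
#' @export
run_segmentation <- function(volume, config = NULL, out_dir = NULL) {
  if (is.character(config) || is.null(config)) config <- read_config(config)
  pars <- config_params(config)
  if (is.character(volume)) volume <- read_oct_volume(volume)
  res <- structure(list(status = 1L, manifest = character(0), config = config),
                   class = "choroid_segmentation")
  n <- n_bscans(volume)
  n_z <- nrow(volume$bscans[[1]])
  n_x <- ncol(volume$bscans[[1]])
  done <- function(stage) res$manifest <<- c(res$manifest, stage)
  fail <- function(stage, err) {
    res$manifest <- c(res$manifest, paste0(stage, ": FAILED (", conditionMessage(err), ")"))
    res$status <- 1L
    res
  }
  emit <- function(res) {
    if (!is.null(out_dir)) write_artifacts(res, out_dir)
    res
  }

  # -- stage 1: anterior boundaries -----------------------------------------
  ant <- tryCatch({
    lapply(volume$bscans, function(b) {
      tryCatch(segment_rpe_bm(b, pars$rpe_bm), error = function(e) NULL)
    })
  }, error = function(e) e)
  if (inherits(ant, "error") || all(vapply(ant, is.null, logical(1)))) {
    err <- if (inherits(ant, "error")) ant else
      simpleError("RVI/RPE segmentation failed on every B-scan")
    return(emit(fail("rpe_bm", err)))
  }
  res$anterior <- ant
  done("rpe_bm")

  # -- stage 2: flatten + transverse smooth ---------------------------------
  sm <- tryCatch({
    bms <- lapply(ant, function(a) if (is.null(a)) NULL else a$bm)
    transverse_smooth(volume, bms, pars$smoothing)
  }, error = function(e) e)
  if (inherits(sm, "error")) return(emit(fail("smoothing", sm)))
  res$smoothing <- sm
  done("smoothing")

  # -- stage 3: CSI ----------------------------------------------------------
  csi <- tryCatch({
    lapply(seq_len(n), function(i) {
      if (is.null(ant[[i]])) {
        return(list(segments = list(), kept = list(),
                    trace = layer_trace(rep(NA_real_, n_x), layer = "CSI"),
                    nodes = tibble(x_px = integer(0), z_px = numeric(0), p = numeric(0))))
      }
      bm_flat <- layer_trace(ant[[i]]$bm$z_px + sm$shifts[[i]], layer = "BM")
      segs <- trace_csi(sm$volume$bscans[[i]], bm_flat, pars$csi,
                        volume$dx_um, volume$dz_um)
      ro <- resolve_overlaps(segs, n_x)
      c(list(segments = segs, bm_flat = bm_flat), ro)
    })
  }, error = function(e) e)
  if (inherits(csi, "error")) return(emit(fail("csi", csi)))
  res$csi_segments <- csi
  res$segmented <- vapply(csi, function(cc) bscan_segmented(cc$kept), logical(1))
  res$success_fraction <- success_fraction(res$segmented)
  done("csi")

  # traces in the raw frame (CSI mapped back through the flattening shifts)
  res$traces <- purrr::map_dfr(seq_len(n), function(i) {
    if (is.null(ant[[i]])) return(NULL)
    shifts <- sm$shifts[[i]]
    csi_raw <- csi[[i]]$trace
    csi_raw$z_px <- csi_raw$z_px - shifts
    csi_raw$z_px[!csi_raw$valid] <- NA_real_
    trace_table(list(list(RVI = ant[[i]]$rvi, RPE_POST = ant[[i]]$rpe_post,
                          BM = ant[[i]]$bm, CSI = csi_raw)))[
      , c("layer", "x_px", "z_px", "valid")] |>
      dplyr::mutate(bscan_index = i - 1L, .before = 1)
  })

  # -- stage 4: maps ---------------------------------------------------------
  maps <- tryCatch({
    pts <- purrr::map_dfr(seq_len(n), function(i) {
      if (is.null(ant[[i]]) || nrow(csi[[i]]$nodes) == 0) return(NULL)
      node_thickness(csi[[i]]$nodes, csi[[i]]$bm_flat, volume, i - 1L)
    })
    if (nrow(pts) < 3) abort("too few CSI nodes to build a thickness map")
    bounds <- c(min(volume$positions$x0_um),
                min(volume$positions$x0_um) + (n_x - 1) * volume$dx_um,
                min(volume$positions$y0_um), max(volume$positions$y0_um))
    cmap <- interpolate_map(pts, grid_um = config$maps$grid_um, bounds = bounds)
    rmap <- retinal_thickness_map(
      lapply(ant, function(a) if (is.null(a)) NULL else a$rvi),
      lapply(ant, function(a) if (is.null(a)) NULL else a$bm),
      volume, grid_um = config$maps$grid_um, stride = config$maps$retina_stride)
    list(points = pts, choroid_map = cmap, retina_map = rmap, bounds = bounds)
  }, error = function(e) e)
  if (inherits(maps, "error")) return(emit(fail("maps", maps)))
  res$points <- maps$points
  res$choroid_map <- maps$choroid_map
  res$retina_map <- maps$retina_map
  res$bounds <- maps$bounds
  done("maps")

  # -- stage 5: descriptors --------------------------------------------------
  desc <- tryCatch(
    describe_choroid(maps$points, maps$retina_map, maps$bounds,
                     volume$laterality),
    error = function(e) e)
  if (inherits(desc, "error")) return(emit(fail("descriptors", desc)))
  res$descriptors <- desc
  done("descriptors")

  res$status <- 0L
  emit(res)
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(res$manifest, file.path(out_dir, "MANIFEST"))
  write_config(res$config, file.path(out_dir, "config_used.yaml"))
  log <- c(sprintf("choroidseg %s", as.character(utils::packageVersion("choroidseg"))),
           yaml::as.yaml(lapply(unclass(res$config),
                                function(x) if (is.list(x)) unclass(x) else x)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  if (!is.null(res$traces) && nrow(res$traces) > 0) {
    export_traces(res$traces, file.path(out_dir, "traces"))
  }
  if (!is.null(res$segmented)) {
    jsonlite::write_json(
      list(success_fraction = res$success_fraction,
           segmented = as.integer(res$segmented)),
      file.path(out_dir, "success.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$choroid_map)) {
    export_map(res$choroid_map, file.path(out_dir, "choroid_thickness"))
    export_map(res$retina_map, file.path(out_dir, "retina_thickness"))
  }
  if (!is.null(res$descriptors)) {
    jsonlite::write_json(as.list(res$descriptors),
                         file.path(out_dir, "descriptors.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.choroid_segmentation <- function(x, ...) {
  cat(sprintf("<choroid_segmentation> status %d | stages: %s\n", x$status,
              paste(x$manifest, collapse = ", ")))
  if (!is.null(x$success_fraction)) {
    cat(sprintf("  B-scans segmented: %.1f%% | points: %d\n",
                100 * x$success_fraction,
                if (is.null(x$points)) 0L else nrow(x$points)))
  }
  if (!is.null(x$descriptors)) {
    cat(sprintf("  mean thickness %.1f um | theta %.2f deg, phi %.1f deg\n",
                x$descriptors$mean_thickness_um, x$descriptors$theta_deg,
                x$descriptors$phi_deg))
  }
  invisible(x)
}

#' @export
#' @method glance choroid_segmentation
glance.choroid_segmentation <- function(x, ...) {
  dplyr::bind_cols(
    tibble(status = x$status, success_fraction = x$success_fraction %||% NA_real_),
    if (!is.null(x$descriptors)) x$descriptors else NULL
  )
}
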