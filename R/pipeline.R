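# Orchestration glue: one flat JSON run configuration, stage execution with
# dependency checks, CSV interchange, and a reproducibility manifest.

#' Default run configuration
#'
#' All tunable defaults of the pipeline in one auditable document. The demo
#' scale (400 x 400 x 300 um phantom) keeps a full run to minutes on one
#' CPU; depth bins for the demo quantification cover the demo depth.
#'
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    rng_seed = 1L,
    phantom = list(volume_size_um = c(400, 400, 300),
                   voxel_pitch_um = c(2, 2, 3),
                   culture_day = 8L, condition = "control",
                   n_sprouts = 6L, vessel_radius_um = c(5, 15)),
    optics = list(wavelength_nm = 532, numerical_aperture = 0.12,
                  k_pam_um = 2 / 431, k_lscm_um = 2 / 262),
    transducer = list(center_frequency_mhz = 19, bandwidth_frac = 0.69,
                      focal_length_mm = 11.6),
    acquisition = list(sampling_rate_msps = 500, sound_speed_mps = 1540,
                       lateral_step_um = 2, noise_sigma = 0.02),
    recon = list(z_pitch_um = 3, median_window = 3L),
    quantify = list(min_component_voxels = 100L,
                    bin_edges_um = c(0, 100, 200, 300),
                    prune_spurs_um = 15),
    characterize = list(edge_psf_fwhm_um = 2.42, edge_step_um = 0.2)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the document against [default_config()]'s schema: unknown keys are
#' rejected, missing ones filled with defaults.
#'
#' @param config Named list (possibly partial).
#' @return Completed `run_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check <- function(cfg, ref, path = "") {
    extra <- setdiff(names(cfg), names(ref))
    stop_if(length(extra) > 0, "unknown config key(s): ",
            paste0(path, extra, collapse = ", "))
    for (nm in names(cfg)) {
      if (is.list(ref[[nm]])) {
        stop_if(!is.list(cfg[[nm]]), "config key ", path, nm,
                " must be a section")
        ref[[nm]] <- check(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
      } else {
        ref[[nm]] <- cfg[[nm]]
      }
    }
    ref
  }
  out <- check(unclass(config), unclass(ref))
  class(out) <- "run_config"
  out
}

#' Read / write a run configuration
#'
#' JSON on disk; unknown keys are rejected on read.
#'
#' @param path File path.
#' @return [read_config()]: a validated `run_config`.
#' @export
read_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(validate_config(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a vessel graph as a CSV segment table
#'
#' Columns: segment id, endpoint coordinates (um), length (um), voxel
#' count, terminal flag.
#'
#' @param graph A `vessel_graph`.
#' @param path CSV path.
#' @export
write_vessel_graph_csv <- function(graph, path) {
  segs <- graph$segments
  segs <- cbind(segment_id = seq_len(nrow(segs)), segs)
  write.csv(segs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vessel_graph_csv
#' @export
read_vessel_graph_csv <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  segs <- read.csv(path)
  structure(list(segments = segs[, setdiff(names(segs), "segment_id")],
                 voxel_pitch_um = c(2, 2, 3)),
            class = "vessel_graph")
}

pipeline_stages <- c("simulate", "recon", "quantify", "stats", "characterize")

artifact_path <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, stage, producer) {
  p <- artifact_path(out_dir, name)
  stop_if(!file.exists(p), "stage '", stage, "' needs missing artifact '",
          name, "' (run stage '", producer, "' first): ", p)
  p
}

#' Run the pipeline
#'
#' Executes the requested stages against one output directory:
#' \describe{
#'   \item{simulate}{grow the configured phantom, write its absorber volume
#'     (TIFF), ground-truth graph (CSV) and the resolved config; simulate
#'     the raster-scanned RF acquisition (raw binary + JSON sidecar).}
#'   \item{recon}{envelope volume + 3D median filter (TIFF), MAP,
#'     depth-encoded and B-scan images (TIFF).}
#'   \item{quantify}{segment, depth-binned density CSV, fractal dimension
#'     per bin CSV, traced segment lengths CSV.}
#'   \item{stats}{Kruskal-Wallis + Dunn report over traced segment lengths
#'     grouped by depth bin (CSV).}
#'   \item{characterize}{resolution report CSV and bandwidth estimate.}
#' }
#' Every run writes `run_manifest.json` with the resolved config, seed and
#' per-artifact MD5 checksums; identical configs give identical checksums.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param stages Subset of
#'   `c("simulate", "recon", "quantify", "stats", "characterize")`.
#' @param out_dir Output directory (created if needed).
#' @param log Logical: print stage boundaries.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = pipeline_stages,
                         out_dir = "pamvasc_run", log = TRUE) {
  config <- validate_config(config)
  stop_if(!all(stages %in% pipeline_stages), "unknown stage name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (log) message("[pamvasc] ", ...)
  outputs <- character()
  add_out <- function(p) outputs[[length(outputs) + 1L]] <<- p

  optics <- do.call(optical_spec, config$optics)
  transducer <- do.call(transducer_spec, config$transducer)
  acquisition <- do.call(acquisition_spec,
                         c(config$acquisition, list(rng_seed = config$rng_seed)))

  if ("simulate" %in% stages) {
    note("simulate: phantom + RF acquisition")
    spec <- do.call(phantom_spec,
                    c(config$phantom, list(rng_seed = config$rng_seed)))
    ph <- grow_vascular_phantom(spec)
    write_config(config, add_out2(artifact_path(out_dir, "config.json"), add_out))
    write_volume(new_recon_volume(ph$absorber, ph$voxel_pitch_um),
                 add_out2(artifact_path(out_dir, "phantom_absorber.tif"), add_out))
    gt <- cbind(segment_id = seq_len(nrow(ph$edges)), ph$edges)
    write.csv(gt, add_out2(artifact_path(out_dir, "phantom_graph.csv"), add_out),
              row.names = FALSE)
    frames <- simulate_pam_stack(ph, optics, transducer, acquisition)
    write_rf_frames(frames, artifact_path(out_dir, "rf_frames"))
    add_out(artifact_path(out_dir, "rf_frames.bin"))
    add_out(artifact_path(out_dir, "rf_frames.json"))
  }
  if ("recon" %in% stages) {
    note("recon: envelope volume + projections")
    require_artifact(out_dir, "rf_frames.bin", "recon", "simulate")
    frames <- read_rf_frames(artifact_path(out_dir, "rf_frames"))
    vol <- assemble_volume(frames, z_pitch_um = config$recon$z_pitch_um)
    vol <- median_filter_3d(vol, config$recon$median_window)
    write_volume(vol, add_out2(artifact_path(out_dir, "volume.tif"), add_out))
    m <- map_projection(vol)
    write_volume(new_recon_volume(array(m, c(dim(m), 1L)), vol$voxel_pitch_um),
                 add_out2(artifact_path(out_dir, "map.tif"), add_out))
    dm <- depth_encoded_projection(vol)
    dm[is.na(dm)] <- -1
    write_volume(new_recon_volume(array(dm, c(dim(dm), 1L)), vol$voxel_pitch_um),
                 add_out2(artifact_path(out_dir, "depth_encoded.tif"), add_out))
    b <- extract_bscan(vol, max(1L, dim(vol$amplitude)[2] %/% 2L))
    write_volume(new_recon_volume(array(b, c(dim(b), 1L)), vol$voxel_pitch_um),
                 add_out2(artifact_path(out_dir, "bscan.tif"), add_out))
  }
  if ("quantify" %in% stages) {
    note("quantify: segmentation + morphometry")
    vp <- require_artifact(out_dir, "volume.tif", "quantify", "recon")
    vol <- read_volume(vp)
    mask <- segment_vessels(vol, config$quantify$min_component_voxels)
    dens <- depth_binned_density(mask, config$quantify$bin_edges_um)
    fd <- vapply(seq_len(nrow(dens)), function(i) {
      z <- (seq_len(dim(mask$mask)[3]) - 1) * mask$voxel_pitch_um[3]
      sel <- z >= dens$bin_lo_um[i] & z < dens$bin_hi_um[i]
      slab <- mask$mask[, , sel, drop = FALSE]
      if (any(slab)) fractal_dimension(slab) else NA_real_
    }, numeric(1))
    dens$fractal_dimension <- fd
    write.csv(dens, add_out2(artifact_path(out_dir, "density.csv"), add_out),
              row.names = FALSE)
    graph <- skeletonize_and_trace(mask,
                                   prune_spurs_um = config$quantify$prune_spurs_um)
    write_vessel_graph_csv(graph,
                           add_out2(artifact_path(out_dir, "lengths.csv"), add_out))
  }
  if ("stats" %in% stages) {
    note("stats: group comparison over depth bins")
    lp <- require_artifact(out_dir, "lengths.csv", "stats", "quantify")
    graph <- read_vessel_graph_csv(lp)
    segs <- graph$segments
    stop_if(!nrow(segs), "no traced segments to compare")
    zmid <- (segs$z0_um + segs$z1_um) / 2
    edges <- config$quantify$bin_edges_um
    bin <- cut(zmid, edges, right = FALSE,
               labels = paste0(edges[-length(edges)], "-", edges[-1], "um"))
    keep <- !is.na(bin) & !is.na(segs$length_um)
    groups <- split(segs$length_um[keep], droplevels(bin[keep]))
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) {
      rep_ <- dunn_posthoc(groups)
      tab <- rep_$pairwise
      tab$H <- rep_$kruskal$H
      tab$omnibus_p <- rep_$kruskal$p_value
      write.csv(tab, add_out2(artifact_path(out_dir, "stats_report.csv"),
                              add_out), row.names = FALSE)
    } else {
      note("stats: fewer than 2 populated depth bins, skipping report")
    }
  }
  if ("characterize" %in% stages) {
    note("characterize: resolution + bandwidth")
    rr <- resolution_report(optics, transducer, acquisition,
                            psf_fwhm_um = config$characterize$edge_psf_fwhm_um)
    pe <- simulate_pulse_echo(transducer, acquisition)
    bw <- estimate_bandwidth(transducer_impulse_response(transducer,
                                                         acquisition)$waveform,
                             acquisition)
    rr$bandwidth_est_frac <- bw$bandwidth_frac
    rr$center_frequency_est_mhz <- bw$center_frequency_mhz
    rr$pulse_echo_peak_us <- pe$t_us[which.max(abs(pe$waveform))]
    write.csv(rr, add_out2(artifact_path(out_dir, "resolution_report.csv"),
                           add_out), row.names = FALSE)
  }
  manifest <- list(package = "pamvasc",
                   version = as.character(utils::packageVersion("pamvasc")),
                   stages = stages,
                   rng_seed = config$rng_seed,
                   config = unclass(config),
                   artifacts = lapply(setNames(nm = basename(outputs)),
                                      function(nm) {
                                        p <- artifact_path(out_dir, nm)
                                        list(md5 = unname(tools::md5sum(p)),
                                             bytes = unname(file.info(p)$size))
                                      }))
  jsonlite::write_json(manifest, artifact_path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

add_out2 <- function(path, add) { add(path); path }

# RF frame container: raw little-endian float64 samples plus a JSON sidecar
# with shape and acquisition parameters.
write_rf_frames <- function(frames, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.numeric(frames$samples), con, size = 8, endian = "little")
  close(con)
  hdr <- list(shape = dim(frames$samples),
              dtype = "float64le",
              acquisition = frames$acquisition[c("sampling_rate_msps",
                                                 "sound_speed_mps",
                                                 "lateral_step_um",
                                                 "noise_sigma", "rng_seed")],
              transducer = unclass(frames$transducer),
              optics = unclass(frames$optics[c("wavelength_nm",
                                               "numerical_aperture",
                                               "k_pam_um", "k_lscm_um")]),
              scan_pitch_um = frames$scan_pitch_um,
              depth_extent_um = frames$depth_extent_um)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

read_rf_frames <- function(stem) {
  bin <- paste0(stem, ".bin")
  js <- paste0(stem, ".json")
  stop_if(!file.exists(bin) || !file.exists(js),
          "RF frame container incomplete: ", stem, ".{bin,json}")
  hdr <- jsonlite::fromJSON(js)
  n <- prod(hdr$shape)
  x <- readBin(bin, "double", n = n, size = 8, endian = "little")
  stop_if(length(x) != n, "truncated RF container: ", bin)
  acq <- do.call(acquisition_spec, as.list(hdr$acquisition))
  tra <- do.call(transducer_spec, as.list(hdr$transducer))
  opt <- do.call(optical_spec, as.list(hdr$optics))
  structure(list(samples = array(x, hdr$shape),
                 acquisition = acq, transducer = tra, optics = opt,
                 scan_pitch_um = hdr$scan_pitch_um,
                 depth_extent_um = hdr$depth_extent_um),
            class = "rf_frameset")
}
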