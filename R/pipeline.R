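#' Pipeline run configuration
#'
#' Collects every knob of the full analysis with the conventional
#' defaults: discard the first 2 us of the trajectory, dual contact
#' cutoffs of 5 and 7 Angstrom, Louvain resolution 1. The configuration
#' is serialized into the output directory for provenance.
#'
#' @param topology,trajectory input file paths (GRO + DCD).
#' @param out_dir output directory.
#' @param frame_dt trajectory stride (ns per frame).
#' @param lipid_species lipid species of interest (e.g. `"CDL"`).
#' @param trim_ns equilibration time to discard (ns).
#' @param cutoff_lower,cutoff_upper dual contact cutoffs (Angstrom).
#' @param resolution,louvain_seed,min_site_size Louvain parameters.
#' @param min_events minimum pooled events for a per-residue fit.
#' @param t_max_frames fitting lag range; `NULL` for the default rule.
#' @param head_bead head bead name for membrane descriptors.
#' @param membrane_stride analyze every k-th frame for APL (Voronoi cost).
#' @param block_frames block size for block-averaged SDs.
#' @return list of class `run_config`.
#' @export
run_config <- function(topology, trajectory, out_dir = "results",
                       frame_dt = 10, lipid_species = "CDL",
                       trim_ns = 2000, cutoff_lower = 5, cutoff_upper = 7,
                       resolution = 1.0, louvain_seed = 1,
                       min_site_size = 3, min_events = 3,
                       t_max_frames = NULL, head_bead = "HD",
                       membrane_stride = 10, block_frames = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`); numeric values are
#' converted. Keys must match [run_config()] arguments.
#'
#' @param path file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  ok <- names(formals(run_config))
  bad <- setdiff(keys, ok)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Orchestrates load -> trim -> dual-cutoff contacts -> per-residue
#' residence times -> binding sites (Louvain + kinetics + area) ->
#' membrane descriptors, writing CSV/JSON outputs plus a manifest (config
#' and package version) under `config$out_dir`. Identical config and
#' seeds give identical outputs.
#'
#' @param config a [run_config()].
#' @param system optionally, an already-loaded `cg_system` (skips file
#'   reading; files in `config` are then ignored).
#' @return list: `residence` (per-residue table), `sites` (site table),
#'   `membrane` (list: thickness, apl, order), `paths` of written files,
#'   invisibly also written to disk.
#' @export
run_pipeline <- function(config, system = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(system)) {
    if (!file.exists(config$topology %||% ""))
      stop("config error: topology file not found", call. = FALSE)
    if (!file.exists(config$trajectory %||% ""))
      stop("config error: trajectory file not found", call. = FALSE)
    system <- load_system(config$topology, config$trajectory,
                          frame_dt = config$frame_dt)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  system <- stage("trim", trim_trajectory(system, config$trim_ns))
  sel <- cg_selection(lipid_species = config$lipid_species)
  series <- stage("contacts", detect_contacts(
    system, sel, cutoff_lower = config$cutoff_lower,
    cutoff_upper = config$cutoff_upper))
  events <- events_from_series(series)
  residence <- stage("kinetics", per_residue_residence_times(
    series, min_events = config$min_events,
    t_max_frames = config$t_max_frames, seed = config$louvain_seed))
  sites <- if (nrow(events) == 0) NULL else
    stage("sites", binding_site_table(
      series, system, resolution = config$resolution,
      seed = config$louvain_seed, min_size = config$min_site_size))
  membrane <- stage("membrane", {
    leaf <- assign_leaflets(system, head_bead = config$head_bead)
    thick <- membrane_thickness(system, leaf, head_bead = config$head_bead)
    mem_frames <- seq(1, n_frames(system), by = config$membrane_stride)
    apl <- area_per_lipid(system, leaf, head_bead = config$head_bead,
                          frames = mem_frames)
    lipid_sp <- setdiff(unique(system$molecule_species), "protein")
    order <- do.call(rbind, lapply(lipid_sp, function(sp)
      cbind(species = sp,
            order_parameters(system, sp, frames = mem_frames))))
    list(thickness = thick, apl = apl, order = order,
         thickness_mean = mean(thick),
         thickness_sd = block_sd(thick, config$block_frames),
         apl_mean = mean(apl$apl),
         apl_sd = block_sd(apl$apl, max(1, config$block_frames %/%
                                          config$membrane_stride)))
  })
  paths <- c(
    events = file.path(config$out_dir, "contact_events.csv"),
    residence = file.path(config$out_dir, "residence_times.csv"),
    sites = file.path(config$out_dir, "binding_sites.json"),
    membrane = file.path(config$out_dir, "membrane.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_events_csv(events, series$frame_dt, paths[["events"]])
  utils::write.csv(residence, paths[["residence"]], row.names = FALSE)
  if (!is.null(sites))
    jsonlite::write_json(sites, paths[["sites"]], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(frame = seq_along(membrane$thickness),
               thickness_A = membrane$thickness),
    paths[["membrane"]], row.names = FALSE)
  manifest <- list(
    package = "lipidsites",
    version = as.character(utils::packageVersion("lipidsites")),
    config = config[setdiff(names(config), c())],
    n_frames_analyzed = n_frames(system))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(residence = residence, sites = sites, membrane = membrane,
                 events = events, series = series, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
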