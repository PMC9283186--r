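## Configuration and workspace plumbing. A run configuration is a JSON
## file; every command materializes its artifacts under the workspace
## directory (meshes/, flow/, snapshots/, bases/, solutions/, reports/)
## keyed by the configuration hash, so re-running with the same
## configuration and seed reuses cached artifacts unless forced.

#' Default run configuration
#'
#' Mirrors the modelled defaults: Table-style parameter ranges, POD
#' truncation `eps = 1e-2`, Picard tolerance `1e-8`, QoI threshold 0.9,
#' `r_scale = 10`.
#'
#' @param workspace workspace directory.
#' @return nested named list (class `run_config`).
#' @export
default_config <- function(workspace = tempfile("scaffoldrom-ws-")) {
  structure(list(
    geometry = list(kind = "structured",
                    box = list(Lx = 600, Ly = 600, Lz = 600, h = 50),
                    spec = list()),
    ranges = default_ranges(),
    physics = list(r_scale = 10, supg = FALSE, tol = 1e-8, max_iter = 50,
                   T_celsius = 37, k_B = 1.38e-23, rho = 114e-12),
    rom = list(sampling = "corner", levels = 3, eps = 1e-2,
               variant = "global", n = 10),
    qoi = list(threshold = 0.9),
    io = list(workspace = workspace),
    seed = 1
  ), class = "run_config")
}

#' Load and validate a JSON run configuration
#'
#' Unknown top-level keys are rejected; missing blocks fall back to
#' [default_config()] values.
#'
#' @param path JSON file.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- unclass(default_config())
  bad <- setdiff(names(raw), names(base))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(raw)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(raw[[k]]))
      utils::modifyList(base[[k]], raw[[k]]) else raw[[k]]
  }
  validate_config(structure(base, class = "run_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$geometry$kind %in% c("structured", "foamed", "file"))
  rg <- cfg$ranges
  for (nm in names(default_ranges())) {
    if (is.null(rg[[nm]]) || length(rg[[nm]]) != 2 || diff(rg[[nm]]) < 0)
      stop("config ranges$", nm, " must be a non-decreasing length-2 interval",
           " (zero-length pins the parameter)")
  }
  if (cfg$rom$eps < 0 || cfg$rom$eps >= 1) stop("rom$eps must be in [0, 1)")
  if (cfg$qoi$threshold <= 0 || cfg$qoi$threshold >= 1)
    stop("qoi$threshold must be in (0, 1)")
  cfg
}

#' Write the effective configuration as JSON
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  substr(digest_string(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                        digits = NA)), 1, 12)
}

ws_paths <- function(cfg) {
  root <- cfg$io$workspace
  dirs <- file.path(root, c("meshes", "flow", "snapshots", "bases",
                            "solutions", "reports"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  names(dirs) <- basename(dirs)
  c(as.list(dirs), root = root)
}

settings_from_config <- function(cfg) {
  ph <- cfg$physics
  solver_settings(tol = ph$tol, max_iter = ph$max_iter,
                  r_scale = ph$r_scale, supg = isTRUE(ph$supg),
                  constants = physical_constants(k_B = ph$k_B,
                                                 T_celsius = ph$T_celsius,
                                                 rho = ph$rho))
}

geometry_from_config <- function(cfg) {
  g <- cfg$geometry
  if (g$kind == "file") {
    if (is.null(g$path)) stop("geometry kind 'file' needs geometry$path")
    return(read_mesh(g$path))
  }
  box <- do.call(box_spec, g$box)
  if (g$kind == "structured") {
    generate_structured(box, do.call(structured_spec, g$spec))
  } else {
    spec_args <- g$spec
    if (is.null(spec_args$seed)) spec_args$seed <- cfg$seed
    generate_foamed(box, do.call(foamed_spec, spec_args))
  }
}

#' Build (or reuse) the mesh artifact
#'
#' @param cfg a `run_config`.
#' @param force rebuild even if the cached artifact exists.
#' @return the `tet_mesh`; side effects: RDS cache and a VTU export under
#'   `meshes/`, metadata echoed to the log.
#' @export
cmd_gen_mesh <- function(cfg, force = FALSE) {
  p <- ws_paths(cfg)
  key <- config_hash(cfg[c("geometry", "seed")])
  rds <- file.path(p$meshes, paste0("mesh-", key, ".rds"))
  if (file.exists(rds) && !force) return(readRDS(rds))
  mesh <- geometry_from_config(cfg)
  saveRDS(mesh, rds)
  write_mesh(mesh, file.path(p$meshes, paste0("mesh-", key, ".vtu")))
  message(sprintf("mesh %s: %d nodes, %d tets, porosity %.3f", key,
                  nrow(mesh$nodes), nrow(mesh$tets),
                  mesh$metadata$porosity %||% NA))
  mesh
}

#' Build (or reuse) the potential-flow velocity basis artifact
#' @inheritParams cmd_gen_mesh
#' @return a [velocity_basis()].
#' @export
cmd_flow_basis <- function(cfg, force = FALSE) {
  p <- ws_paths(cfg)
  mesh <- cmd_gen_mesh(cfg, force = force)
  rds <- file.path(p$flow, paste0("basis-", mesh_fingerprint(mesh), ".rds"))
  if (file.exists(rds) && !force) return(readRDS(rds))
  vb <- velocity_basis(mesh)
  saveRDS(vb, rds)
  vb
}

#' Full-order solve at one parameter point
#'
#' @param cfg a `run_config`.
#' @param mu a [parameter_point()] or named vector.
#' @return list with the `concentration_field`, its `qoi_result`, and the
#'   mesh; solution exported as VTU point data under `solutions/`.
#' @export
cmd_solve <- function(cfg, mu) {
  p <- ws_paths(cfg)
  mesh <- cmd_gen_mesh(cfg)
  vb <- cmd_flow_basis(cfg)
  mu <- do.call(parameter_point, as.list(mu))
  sol <- picard_solve(mesh, mu, vb, settings_from_config(cfg))
  q <- qoi_volume_ratio(mesh, sol, cfg$qoi$threshold)
  out <- file.path(p$solutions,
                   paste0("sol-", substr(digest_string(
                     paste(format(mu, digits = 15), collapse = "_")), 1, 12)))
  write_mesh(mesh, paste0(out, ".vtu"),
             point_data = list(concentration = sol$c))
  jsonlite::write_json(list(mu = as.list(mu), qoi = q$qoi,
                            iterations = sol$iterations),
                       paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("solve: %d Picard iterations, QoI = %.2f%%",
                  sol$iterations, q$qoi))
  list(solution = sol, qoi = q, mesh = mesh)
}

#' Offline phase: snapshots and reduced basis
#'
#' Samples the configured training set (corner or grid), runs the
#' full-order solver at every point (cached, resumable) and builds the
#' global POD basis at the configured tolerance.
#'
#' @inheritParams cmd_gen_mesh
#' @return list with `snapshots` (a `snapshot_set`) and `basis` (a
#'   `reduced_basis`).
#' @export
cmd_offline <- function(cfg, force = FALSE) {
  p <- ws_paths(cfg)
  mesh <- cmd_gen_mesh(cfg)
  vb <- cmd_flow_basis(cfg)
  points <- if (cfg$rom$sampling == "corner") corner_sampling(cfg$ranges)
            else grid_sampling(cfg$ranges, cfg$rom$levels)
  key <- config_hash(cfg[c("geometry", "ranges", "rom", "seed")])
  rds <- file.path(p$snapshots, paste0("snapshots-", key, ".rds"))
  snaps <- if (file.exists(rds) && !force) readRDS(rds) else {
    s <- build_snapshots(mesh, points, vb, settings_from_config(cfg),
                         cache_dir = file.path(p$snapshots, "cache"))
    saveRDS(s, rds)
    s
  }
  rb <- pod_basis(snaps$X, cfg$rom$eps, centering = snaps$mean)
  saveRDS(rb, file.path(p$bases, paste0("basis-", key, ".rds")))
  message(sprintf("offline: %d snapshots, k = %d at eps = %g",
                  ncol(snaps$X), rb$k, cfg$rom$eps))
  list(snapshots = snaps, basis = rb)
}

#' Online phase: reduced solve at a new parameter point
#'
#' @param cfg a `run_config`.
#' @param mu parameter point.
#' @param variant ROM variant (defaults to the configured one).
#' @param n neighbourhood size for local variants.
#' @param eps truncation tolerance (defaults to the configured one).
#' @param compare also run the full-order solver and report the relative
#'   error.
#' @return list with the `reduced_solution`, its `qoi_result`, `k`, and
#'   (if `compare`) `Er` and the full-order solution.
#' @export
cmd_online <- function(cfg, mu, variant = NULL, n = NULL, eps = NULL,
                       compare = TRUE) {
  off <- cmd_offline(cfg)
  mesh <- cmd_gen_mesh(cfg)
  vb <- cmd_flow_basis(cfg)
  mu <- do.call(parameter_point, as.list(mu))
  variant <- variant %||% cfg$rom$variant
  rb <- train_basis(off$snapshots, variant, eps = eps %||% cfg$rom$eps,
                    mu = mu, n = n %||% cfg$rom$n, ranges = cfg$ranges)
  st <- settings_from_config(cfg)
  rs <- reduced_solve(mesh, mu, rb, vb, st)
  q <- qoi_volume_ratio(mesh, rs, cfg$qoi$threshold)
  out <- list(solution = rs, qoi = q, k = rb$k)
  if (compare) {
    fe <- picard_solve(mesh, mu, vb, st)
    out$Er <- relative_error(rs, fe)
    out$full_order <- fe
    message(sprintf("online (%s): k = %d, E_r = %.3e, QoI = %.2f%%",
                    rb$provenance, rb$k, out$Er, q$qoi))
  }
  out
}

#' QoI sweep over one parameter
#'
#' @param cfg a `run_config`.
#' @param parameter swept parameter name.
#' @param values numeric values.
#' @param variants ROM variants to include (may be empty).
#' @param fixed named values for the non-swept parameters; defaults to
#'   the mid-point of each configured range.
#' @return the `sweep_report` data.frame; also written as CSV under
#'   `reports/`.
#' @export
cmd_sweep <- function(cfg, parameter, values, variants = character(),
                      fixed = NULL) {
  p <- ws_paths(cfg)
  mesh <- cmd_gen_mesh(cfg)
  vb <- cmd_flow_basis(cfg)
  if (is.null(fixed))
    fixed <- vapply(cfg$ranges, function(rg) mean(unlist(rg)), numeric(1))
  fixed <- do.call(parameter_point, as.list(fixed))
  snaps <- if (length(variants)) cmd_offline(cfg)$snapshots else NULL
  rep <- sweep_qoi(mesh, vb, parameter, values, fixed,
                   variants = variants, snapshots = snaps,
                   eps = cfg$rom$eps, n = cfg$rom$n,
                   settings = settings_from_config(cfg),
                   threshold = cfg$qoi$threshold,
                   csv = file.path(p$reports,
                                   paste0("sweep-", parameter, "-",
                                          config_hash(cfg), ".csv")))
  rep
}
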