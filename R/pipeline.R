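# End-to-end pipeline: extract -> project -> regularize -> fit ->
# distance, with a validated configuration, deterministic artifact
# names, and a run manifest.

pipeline_schema <- list(
  seed = "integer",
  output_dir = "character",
  log_level = "character",
  input = list(
    phantom = list(type = "character", radius = "numeric",
                   bump_amplitude = "numeric", bump_frequency = "numeric",
                   protrusion_length = "numeric", protrusion_radius = "numeric",
                   spacing = "numeric", margin = "numeric",
                   blur_sigma = "numeric", seed = "integer"),
    volume = list(path = "character", spacing = "numeric"),
    mesh = list(path = "character")
  ),
  extract = list(threshold = "numeric", method = "character",
                 keep = "character", comparison = "character"),
  project = list(anchors = "anchors", inside = "numeric", domain = "numeric",
                 tol = "numeric", repair = "logical",
                 fuse_angle_tol = "numeric"),
  regularize = list(enabled = "logical", epsilon = "numeric",
                    max_iters = "integer", quadrature_order = "integer"),
  fit = list(n_bx = "integer", n_by = "integer", lambda = "numeric",
             sweep_lambda = "numeric", solver = "character",
             clamp = list(edge = "character", curve = "character")),
  distance = list(enabled = "logical", max_points = "integer")
)

pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "parasurf-run",
    log_level = "info",
    input = list(),
    extract = list(threshold = 100, method = "quads", keep = "largest",
                   comparison = ">="),
    # the 100-unit parametric axis mirrors the conventional choice for
    # heart-scale reconstructions; the extent is arbitrary
    project = list(anchors = "auto", domain = c(0, 100, 0, 100),
                   tol = 1e-10, repair = FALSE, fuse_angle_tol = 1e-3),
    regularize = list(enabled = TRUE, max_iters = 200L,
                      quadrature_order = 2L),
    fit = list(n_bx = 9L, n_by = 9L, lambda = 0.2, solver = "direct"),
    distance = list(enabled = TRUE, max_points = 500L)
  )
}

check_against_schema <- function(value, schema, path) {
  if (is.list(schema) && !is.character(schema)) {
    if (!is.list(value)) {
      psf_stop(sprintf("config field '%s' must be a mapping", path),
               "bad_config")
    }
    unknown <- setdiff(names(value), names(schema))
    if (length(unknown)) {
      psf_stop(sprintf("unknown config key '%s.%s'", path, unknown[1L]),
               "bad_config", list(key = unknown[1L]))
    }
    for (nm in names(value)) {
      check_against_schema(value[[nm]], schema[[nm]],
                           paste(path, nm, sep = "."))
    }
  } else {
    ok <- switch(schema,
      integer = is.numeric(value) && all(value == round(value)),
      numeric = is.numeric(value) || is.null(value),
      character = is.character(value),
      logical = is.logical(value),
      anchors = (is.character(value) && identical(value, "auto")) ||
        (is.numeric(value) && length(value) == 4L),
      TRUE)
    if (!ok) {
      psf_stop(sprintf("config field '%s' has the wrong type", path),
               "bad_config", list(key = path))
    }
  }
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' Checks the user configuration against the published schema (unknown
#' keys and type mismatches are rejected before any computation), then
#' fills in the documented defaults.
#'
#' @param config named list, or path to a YAML/JSON config file.
#' @return the completed configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  check_against_schema(config, pipeline_schema, "config")
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(cfg$fit$lambda) &&
      (cfg$fit$lambda < 0 || cfg$fit$lambda >= 1)) {
    psf_stop("config field 'config.fit.lambda' must lie in [0, 1)",
             "bad_config", list(lambda = cfg$fit$lambda))
  }
  if (length(cfg$input) == 0L) {
    psf_stop("config needs an input: phantom, volume or mesh", "bad_config")
  }
  cfg
}

build_phantom_from_config <- function(ph) {
  args <- ph[setdiff(names(ph), "type")]
  switch(ph$type,
    ball = do.call(make_ball, args),
    bumpy_hemisphere = do.call(make_bumpy_hemisphere, args),
    papillary = do.call(make_papillary_phantom, args),
    psf_stop(sprintf("unknown phantom type '%s'", ph$type), "bad_config"))
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in order (extraction, projection,
#' regularization, spline fitting, distance report), writing every stage
#' artifact under `config$output_dir` with deterministic names and
#' returning a manifest that records all parameters actually used,
#' output paths, and timings.  Stages not requested are resumed from the
#' artifacts already on disk, so running stages `k..end` manually equals
#' a full run.
#'
#' @param config a configuration list or file accepted by
#'   [validate_pipeline_config()].
#' @param stages character subset of
#'   `c("extract", "project", "regularize", "fit", "distance")`.
#' @return the manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("extract", "project", "regularize",
                                    "fit", "distance")) {
  cfg <- validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  pth <- function(f) file.path(out, f)
  manifest <- list(package = "parasurf",
                   version = as.character(utils::packageVersion("parasurf")),
                   config = cfg, stages = list(), outputs = list())
  t_all <- Sys.time()
  phantom <- NULL
  surface <- NULL
  patch <- NULL
  pmesh <- NULL
  spline <- NULL

  timed <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$stages[[name]] <<- c(manifest$stages[[name]],
                                  list(seconds = as.numeric(Sys.time() - t0)))
    res
  }

  if (!is.null(cfg$input$phantom)) {
    phantom <- build_phantom_from_config(cfg$input$phantom)
  }

  # ---- extract ----
  if ("extract" %in% stages) {
    surface <- timed("extract", {
      if (!is.null(cfg$input$mesh)) {
        read_obj(cfg$input$mesh$path)
      } else {
        vol <- if (!is.null(phantom)) phantom$volume
               else load_volume(cfg$input$volume$path, cfg$input$volume$spacing)
        if (cfg$extract$method == "quads") {
          extract_boundary_quads(vol, cfg$extract$threshold,
                                 comparison = cfg$extract$comparison,
                                 keep = cfg$extract$keep)
        } else {
          extract_isosurface_triangles(vol, cfg$extract$threshold,
                                       keep = cfg$extract$keep)
        }
      }
    })
    write_obj(surface, pth("surface.obj"))
    manifest$outputs$surface <- pth("surface.obj")
    manifest$stages$extract$vertices <- nrow(surface$vertices)
    manifest$stages$extract$faces <- nrow(surface$faces)
  } else if (file.exists(pth("surface.obj"))) {
    surface <- read_obj(pth("surface.obj"))
  }

  # ---- project ----
  domain <- as.numeric(cfg$project$domain)
  if ("project" %in% stages) {
    if (is.null(surface)) psf_stop("projection needs the extracted surface",
                                   "pipeline", list(stage = "project"))
    pmesh <- timed("project", {
      anchors <- cfg$project$anchors
      if (identical(anchors, "auto")) {
        anchors <- if (!is.null(phantom) &&
                       phantom$description$type != "ball") {
          pick_nearest_vertices(surface, phantom_equator_points(phantom))
        } else {
          suggest_anchors(surface)
        }
      }
      spec <- trace_patch(surface, anchors, inside = cfg$project$inside)
      pin <- pin_boundary(spec, domain)
      patch <- extract_patch(surface, spec)
      pin$vertex <- match(pin$vertex, patch$index_map)
      pm <- solve_projection(patch$surface, pin, domain,
                             tol = cfg$project$tol)
      if (isTRUE(cfg$project$repair)) {
        pm <- repair_collisions(pm, cfg$project$fuse_angle_tol)
      }
      pm
    })
    write_uv_table(pmesh, pth("uv_projected.csv"))
    write_obj(patch$surface, pth("patch.obj"))
    manifest$outputs$uv_projected <- pth("uv_projected.csv")
    manifest$outputs$patch <- pth("patch.obj")
    manifest$stages$project$flipped <- flipped_elements(pmesh)
    manifest$stages$project$stationarity <- max(stationarity_residual(pmesh))
  } else if (file.exists(pth("uv_projected.csv")) &&
             file.exists(pth("patch.obj"))) {
    psurf <- read_obj(pth("patch.obj"))
    pmesh <- read_uv_table(pth("uv_projected.csv"), psurf, domain)
  }

  # ---- regularize ----
  if ("regularize" %in% stages && isTRUE(cfg$regularize$enabled)) {
    if (is.null(pmesh)) psf_stop("regularization needs the projected mesh",
                                 "pipeline", list(stage = "regularize"))
    pmesh <- timed("regularize", {
      regularize(pmesh, epsilon = cfg$regularize$epsilon,
                 max_iters = cfg$regularize$max_iters,
                 quadrature_order = cfg$regularize$quadrature_order)
    })
    info <- attr(pmesh, "regularization")
    write_uv_table(pmesh, pth("uv_regularized.csv"))
    utils::write.csv(data.frame(iteration = seq_along(info$energy_trace) - 1L,
                                energy = info$energy_trace),
                     pth("energy_trace.csv"), row.names = FALSE)
    manifest$outputs$uv_regularized <- pth("uv_regularized.csv")
    manifest$outputs$energy_trace <- pth("energy_trace.csv")
    manifest$stages$regularize$status <- info$status
    manifest$stages$regularize$iterations <- info$iterations
    manifest$stages$regularize$flipped <- flipped_elements(pmesh)
  } else if (file.exists(pth("uv_regularized.csv")) &&
             !is.null(pmesh)) {
    pmesh <- read_uv_table(pth("uv_regularized.csv"), pmesh$surface, domain)
  }

  # ---- fit ----
  if ("fit" %in% stages) {
    if (is.null(pmesh)) psf_stop("fitting needs the parametrized mesh",
                                 "pipeline", list(stage = "fit"))
    clamp <- NULL
    if (!is.null(cfg$fit$clamp)) {
      clamp <- list(edge = cfg$fit$clamp$edge,
                    curve = read_spline_json_curve(cfg$fit$clamp$curve))
    }
    lambdas <- cfg$fit$sweep_lambda %||% cfg$fit$lambda
    fits <- timed("fit", {
      lapply(lambdas, function(lam) {
        fit_surface(pmesh, n_bx = cfg$fit$n_bx, n_by = cfg$fit$n_by,
                    lambda = lam, clamp = clamp, solver = cfg$fit$solver)
      })
    })
    spline <- fits[[which.min(abs(lambdas - cfg$fit$lambda))]]
    write_spline_json(spline, pth("spline.json"))
    write_obj(tessellate_surface(spline), pth("spline_tessellated.obj"))
    manifest$outputs$spline <- pth("spline.json")
    manifest$outputs$tessellated <- pth("spline_tessellated.obj")
    manifest$stages$fit$lambda <- lambdas
    manifest$stages$fit$rms_residual <-
      vapply(fits, function(f) attr(f, "fit")$rms_residual, numeric(1L))
  } else if (file.exists(pth("spline.json"))) {
    spline <- read_spline_json(pth("spline.json"))
  }

  # ---- distance ----
  if ("distance" %in% stages && isTRUE(cfg$distance$enabled)) {
    if (is.null(spline) || is.null(pmesh)) {
      psf_stop("distance stage needs the fitted spline and the data points",
               "pipeline", list(stage = "distance"))
    }
    rep <- timed("distance", {
      pts <- pmesh$surface$vertices
      if (nrow(pts) > cfg$distance$max_points) {
        sel <- with_seed(cfg$seed,
                         sort(sample.int(nrow(pts), cfg$distance$max_points)))
        pts <- pts[sel, , drop = FALSE]
      }
      distance_report(spline, pts)
    })
    write_distance_csv(rep, pth("distance_report.csv"))
    manifest$outputs$distance_report <- pth("distance_report.csv")
    manifest$stages$distance$summary <- as.list(rep$summary)
    manifest$stages$distance$n_points <- nrow(rep$per_point)
  }

  manifest$total_seconds <- as.numeric(Sys.time() - t_all)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

# clamp curves are stored in the spline JSON schema with n_by = 0; a
# plain 1D schema keeps the same fields minus the v axis
read_spline_json_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "parasurf-curve")) {
    psf_stop(sprintf("'%s' is not a parasurf curve file", path), "io")
  }
  spline_curve(obj$n_b, obj$domain, obj$coeffs)
}

#' Serialize a spline curve to JSON
#' @param curve a `spline_curve`.
#' @param path output file.
#' @export
write_curve_json <- function(curve, path) {
  obj <- list(format = "parasurf-curve", version = 1L, n_b = curve$n_b,
              domain = curve$domain, coeffs = curve$coeffs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
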