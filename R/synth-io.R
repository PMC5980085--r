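# Synthetic contour movies with known mode programs, and versioned CSV /
# structured-text I/O for every table the package exchanges.

#' Deformation program for a synthetic contour movie
#'
#' Prescribes the complex amplitude of each shape mode as a function of time,
#' plus the mean radius and per-vertex radial noise of the rendered contours.
#'
#' @param duration_h Movie duration in hours.
#' @param sample_min Frame interval in minutes.
#' @param r0 Mean radius in micrometres.
#' @param modes Named list of functions of `time_min` returning the complex
#'   amplitude of the mode; names are mode indices (`"2"`, `"3"`, ...).
#'   Constants are accepted and wrapped.
#' @param contour_noise_sd Radial noise per rendered vertex (micrometres).
#' @return A list of class `mode_program`.
#' @examples
#' mode_program(1, modes = list("2" = function(t) 0.002 * t, "3" = 0.5 + 0i))
#' @export
mode_program <- function(duration_h, sample_min = 5, r0 = 20,
                         modes = list(), contour_noise_sd = 0) {
  if (duration_h <= 0 || sample_min <= 0) abort("durations must be positive.")
  if (!length(modes) || is.null(names(modes)) || any(names(modes) == "")) {
    abort("`modes` must be a named list keyed by mode index.")
  }
  modes <- lapply(modes, function(m) {
    if (is.function(m)) m else (function(val) function(t) rep(val, length(t)))(m)
  })
  structure(
    list(
      duration_h = duration_h, sample_min = sample_min, r0 = r0,
      modes = modes, contour_noise_sd = contour_noise_sd
    ),
    class = "mode_program"
  )
}

#' Ground-truth mode table of a program
#'
#' @param program A [mode_program()] object.
#' @return Tibble `time_min` plus one complex column `c<n>` per mode.
#' @export
program_modes <- function(program) {
  tt <- seq(0, program$duration_h * 60, by = program$sample_min)
  out <- tibble::tibble(time_min = tt)
  for (nm in names(program$modes)) {
    out[[paste0("c", nm)]] <- as.complex(program$modes[[nm]](tt))
  }
  out
}

#' Render a synthetic contour movie from a mode program
#'
#' Evaluates `R(theta)` for each frame from the program's modes via
#' [reconstruct_profile()], adds independent radial noise per vertex, and
#' emits closed polygons. The noise-free radius must stay positive for every
#' frame (otherwise the program describes a self-intersecting radial shape
#' and an error is raised); noisy radii that dip below a small floor are
#' clipped with a warning.
#'
#' @param program A [mode_program()] object.
#' @param n_vertices Vertices per polygon.
#' @param seed Seed for the vertex noise.
#' @param cell_id Identifier stored in the output.
#' @return A list with `contours` (tibble `cell_id`, `frame`, `time_min`,
#'   `vertex_index`, `x_um`, `y_um`) and `truth` (the [program_modes()]
#'   table), so recovery errors can be computed without re-simulation.
#' @export
generate_contour_movie <- function(program, n_vertices = 120, seed = 1,
                                   cell_id = 1L) {
  truth <- program_modes(program)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  set.seed(seed)
  clipped <- 0L
  frames <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    amps <- vapply(
      names(program$modes),
      function(nm) truth[[paste0("c", nm)]][i], complex(1)
    )
    names(amps) <- names(program$modes)
    r <- reconstruct_profile(program$r0, amps, theta)
    if (any(r <= 0)) {
      abort(sprintf(
        "Program yields non-positive radius at frame %d: amplitudes too large for r0 = %g.",
        i, program$r0
      ))
    }
    if (program$contour_noise_sd > 0) {
      r <- r + rnorm(n_vertices, sd = program$contour_noise_sd)
    }
    floor_um <- 1e-3 * program$r0
    if (any(r < floor_um)) {
      clipped <<- clipped + sum(r < floor_um)
      r <- pmax(r, floor_um)
    }
    tibble::tibble(
      cell_id = cell_id, frame = i, time_min = truth$time_min[i],
      vertex_index = seq_len(n_vertices),
      x_um = r * cos(theta), y_um = r * sin(theta)
    )
  })
  if (clipped > 0L) {
    warn(sprintf("Clipped %d noisy vertex radius(es) to a positive floor.", clipped))
  }
  list(contours = frames, truth = truth)
}

# ---- versioned CSV I/O -----------------------------------------------------

.csv_version <- "v1"

.write_versioned_csv <- function(df, path, kind) {
  writeLines(sprintf("#prdcell,%s,%s", .csv_version, kind), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.read_versioned_csv <- function(path, kind, required) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#prdcell,")) {
    abort(sprintf("%s: missing '#prdcell' version header line.", path))
  }
  hdr <- strsplit(first, ",")[[1L]]
  if (length(hdr) >= 3L && hdr[3L] != kind) {
    abort(sprintf("%s: file kind is '%s', expected '%s'.", path, hdr[3L], kind))
  }
  df <- readr::read_csv(path, skip = 1L, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr)) {
    abort(sprintf(
      "%s: malformed row(s) at line(s) %s.",
      path, paste(unique(pr$row) + 1L, collapse = ", ")
    ))
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(sprintf(
      "%s: missing required column(s): %s.", path, paste(miss, collapse = ", ")
    ))
  }
  df
}

#' Read and write cell-track tables
#'
#' CSV with a `#prdcell` version header and columns `cell_id`, `time_min`,
#' `x_um`, `y_um`; unknown extra columns are preserved. Reading checks each
#' cell's time grid for uniform `tau_min` spacing.
#'
#' @param tracks Track tibble.
#' @param path File path.
#' @param tau_min Expected sampling interval in minutes (read only).
#' @param check_grid Verify the uniform grid on read.
#' @return `write_tracks()` returns the path; `read_tracks()` the tibble.
#' @export
write_tracks <- function(tracks, path) {
  .write_versioned_csv(tracks, path, "tracks")
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, tau_min = 5, check_grid = TRUE) {
  df <- .read_versioned_csv(path, "tracks", c("cell_id", "time_min", "x_um", "y_um"))
  if (check_grid) {
    for (id in unique(df$cell_id)) {
      .check_uniform_grid(sort(df$time_min[df$cell_id == id]), tau_min)
    }
  }
  df
}

#' Read and write shape-mode tables
#'
#' Complex mode columns `c2 ..` are stored as `c<n>_re` / `c<n>_im` pairs and
#' rebuilt on read. Columns `cell_id`, `time_min` are required; `r0_um` is
#' carried when present.
#'
#' @param modes Mode tibble with complex columns `c2`, `c3`, ...
#' @param path File path.
#' @return `write_modes()` returns the path; `read_modes()` the tibble with
#'   complex columns restored.
#' @export
write_modes <- function(modes, path) {
  out <- modes
  for (nm in names(out)) {
    if (is.complex(out[[nm]])) {
      out[[paste0(nm, "_re")]] <- Re(out[[nm]])
      out[[paste0(nm, "_im")]] <- Im(out[[nm]])
      out[[nm]] <- NULL
    }
  }
  .write_versioned_csv(out, path, "modes")
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  df <- .read_versioned_csv(path, "modes", c("cell_id", "time_min"))
  res <- grep("_re$", names(df), value = TRUE)
  for (nm in res) {
    base <- sub("_re$", "", nm)
    im <- paste0(base, "_im")
    if (im %in% names(df)) {
      df[[base]] <- complex(real = df[[nm]], imaginary = df[[im]])
      df[[nm]] <- NULL
      df[[im]] <- NULL
    }
  }
  df
}

#' Read and write contour-vertex tables
#'
#' @param contours Tibble `cell_id`, `frame`, `time_min`, `vertex_index`,
#'   `x_um`, `y_um`.
#' @param path File path.
#' @return `write_contours()` returns the path; `read_contours()` the tibble.
#' @export
write_contours <- function(contours, path) {
  .write_versioned_csv(contours, path, "contours")
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  .read_versioned_csv(
    path, "contours",
    c("cell_id", "time_min", "vertex_index", "x_um", "y_um")
  )
}

#' Read and write radial-profile tables
#'
#' Angles are stored in degrees in files and used in radians internally.
#'
#' @param profiles Tibble `cell_id`, `time_min`, `theta_deg`, `r_um`.
#' @param path File path.
#' @return `write_radial_profiles()` returns the path;
#'   `read_radial_profiles()` the tibble.
#' @export
write_radial_profiles <- function(profiles, path) {
  .write_versioned_csv(profiles, path, "radial")
}

#' @rdname write_radial_profiles
#' @export
read_radial_profiles <- function(path) {
  .read_versioned_csv(
    path, "radial", c("cell_id", "time_min", "theta_deg", "r_um")
  )
}

#' Read and write PRD parameter / configuration files
#'
#' Structured YAML with a `schema` field, a `params` block ([prd_params()])
#' and an optional `config` block ([sim_config()]).
#'
#' @param params A [prd_params()] object.
#' @param path File path.
#' @param config Optional [sim_config()] object.
#' @return `write_params()` returns the path; `read_params()` a list with
#'   elements `params` and (possibly `NULL`) `config`.
#' @export
write_params <- function(params, path, config = NULL) {
  doc <- list(schema = "prdcell-params-v1", params = unclass(params))
  if (!is.null(config)) doc$config <- unclass(config)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$params)) abort(sprintf("%s: no `params` block.", path))
  p <- do.call(prd_params, doc$params)
  cfg <- NULL
  if (!is.null(doc$config)) cfg <- do.call(sim_config, doc$config)
  list(params = p, config = cfg)
}

#' Write a fit result as JSON
#'
#' @param fit A `mobility_fit`, `prd_fit` or `prw_fit` object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "mobility_fit")) {
    list(
      type = "mobility_fit",
      coefficients = as.list(fit$coefficients), ci95 = as.list(fit$ci95),
      residual_s = fit$residual_s, n_obs = fit$n_obs,
      r_squared = fit$r_squared, aic = fit$aic
    )
  } else if (inherits(fit, "prd_fit")) {
    list(
      type = "prd_fit",
      estimate = as.list(fit$estimate), sd = as.list(fit$sd),
      best = unclass(fit$best), best_err = fit$best_err,
      n_restarts = nrow(fit$restarts)
    )
  } else if (inherits(fit, "prw_fit")) {
    list(
      type = "prw_fit", d = fit$d, p_h = fit$p_h, sigma0 = fit$sigma0,
      rss = fit$rss
    )
  } else {
    abort("unsupported fit object.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records seed, package version and parameters next to any generated
#' output, so a run can be reproduced exactly.
#'
#' @param path File path.
#' @param seed Seed used for the run.
#' @param params Optional [prd_params()] object.
#' @param extra Optional named list of additional fields.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, seed, params = NULL, extra = list()) {
  doc <- c(
    list(
      package = "prdcell",
      version = as.character(utils::packageVersion("prdcell")),
      schema = .csv_version,
      seed = seed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    if (!is.null(params)) list(params = unclass(params)),
    extra
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
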