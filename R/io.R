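#' Write a simulation history as a VTK legacy unstructured-grid time series
#'
#' One ASCII `.vtk` file per output frame (hexahedra plus beam line cells,
#' point displacements, cell stress/strain tensors in Voigt order and beam
#' axial stress as cell data) and a JSON series index. Values are printed
#' at full double precision so the paired reader round-trips losslessly.
#'
#' @param history a `sim_history`.
#' @param mesh the tissue `hex_mesh`.
#' @param beams optional `beam_mesh`.
#' @param path output directory (created if needed).
#' @param basename file prefix.
#' @return paths of the written frame files, invisibly.
#' @export
write_field_series <- function(history, mesh, beams = NULL, path,
                               basename = "frame") {
  if (length(history$times) == 0) stop("history is empty")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nf <- length(history$times)
  n_hex_nodes <- nrow(mesh$nodes)
  nb_nodes <- if (!is.null(beams)) nrow(beams$nodes) else 0L
  nE <- nrow(mesh$elements)
  nB <- if (!is.null(beams)) nrow(beams$elements) else 0L
  files <- character(nf)
  num <- function(x) sprintf("%.17g", x)
  for (f in seq_len(nf)) {
    fn <- file.path(path, sprintf("%s_%04d.vtk", basename, f - 1))
    files[f] <- fn
    con <- file(fn, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("time %.17g ms", history$times[f]),
                 "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
    pos <- matrix(history$positions[f, , ], n_hex_nodes, 3)
    if (nb_nodes > 0) {
      # beam nodes are slaved to their hosts: reconstruct their current
      # positions through the coupling weights when available
      if (!is.null(history$coupling)) {
        cpl <- history$coupling
        bpos <- matrix(0, nb_nodes, 3)
        for (bn in seq_len(nb_nodes)) {
          conn <- mesh$elements[cpl$elem[bn], ]
          w <- hex_shape(c(cpl$xi1[bn], cpl$xi2[bn], cpl$xi3[bn]))
          bpos[bn, ] <- crossprod(w, pos[conn, , drop = FALSE])
        }
      } else {
        bpos <- as.matrix(beams$nodes[, c("x", "y", "z")])
      }
      pos <- rbind(pos, bpos)
    }
    writeLines(sprintf("POINTS %d double", nrow(pos)), con)
    writeLines(apply(pos, 1, function(r) paste(num(r), collapse = " ")), con)
    ncells <- nE + nB
    writeLines(sprintf("CELLS %d %d", ncells, 9 * nE + 3 * nB), con)
    writeLines(apply(mesh$elements, 1, function(r) {
      paste(c(8, r - 1), collapse = " ")
    }), con)
    if (nB > 0) {
      writeLines(apply(beams$elements[, c("node_a", "node_b")], 1,
                       function(r) {
        paste(c(2, r - 1 + n_hex_nodes), collapse = " ")
      }), con)
    }
    writeLines(sprintf("CELL_TYPES %d", ncells), con)
    writeLines(c(rep("12", nE), rep("3", nB)), con)
    writeLines(sprintf("POINT_DATA %d", nrow(pos)), con)
    writeLines("VECTORS displacement double", con)
    ref <- rbind(mesh$nodes,
                 if (nb_nodes > 0) as.matrix(beams$nodes[, c("x", "y", "z")]))
    disp <- pos - ref
    writeLines(apply(disp, 1, function(r) paste(num(r), collapse = " ")), con)
    writeLines(sprintf("CELL_DATA %d", ncells), con)
    writeLines("FIELD mechanics 3", con)
    writeLines(sprintf("cauchy_stress 6 %d double", ncells), con)
    sig <- matrix(history$stress[f, , ], nE, 6)
    pad <- matrix(0, nB, 6)
    writeLines(apply(rbind(sig, pad), 1,
                     function(r) paste(num(r), collapse = " ")), con)
    writeLines(sprintf("green_strain 6 %d double", ncells), con)
    eps <- matrix(history$strain[f, , ], nE, 6)
    writeLines(apply(rbind(eps, pad), 1,
                     function(r) paste(num(r), collapse = " ")), con)
    writeLines(sprintf("axial_stress 1 %d double", ncells), con)
    bstr <- if (nB > 0) history$beam_stress[f, ] else numeric(0)
    writeLines(num(c(rep(0, nE), bstr)), con)
    close(con)
    on.exit()
  }
  idx <- file.path(path, paste0(basename, ".series.json"))
  jsonlite::write_json(
    list(`file-series-version` = "1.0",
         files = data.frame(name = base::basename(files),
                            time = history$times)),
    idx, auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read back a VTK series written by [write_field_series()]
#' @param path directory of the series.
#' @param basename file prefix used at write time.
#' @return list with `times` and per-frame lists holding `points`,
#'   `cells` (hex connectivity), `lines`, `displacement`, `cauchy_stress`,
#'   `green_strain`, `axial_stress`.
#' @export
read_field_series <- function(path, basename = "frame") {
  idx <- jsonlite::read_json(file.path(path,
                                       paste0(basename, ".series.json")),
                             simplifyVector = TRUE)
  frames <- lapply(idx$files$name, function(fn) {
    read_vtk_frame(file.path(path, fn))
  })
  list(times = idx$files$time, frames = frames)
}

read_vtk_frame <- function(fn) {
  ln <- readLines(fn)
  grab <- function(pattern) grep(pattern, ln)[1]
  nums <- function(from, count_rows) {
    vals <- scan(text = ln[(from + 1):(from + count_rows)], quiet = TRUE)
    vals
  }
  ip <- grab("^POINTS")
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- matrix(nums(ip, np), np, 3, byrow = TRUE)
  ic <- grab("^CELLS")
  ncells <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cell_rows <- strsplit(trimws(ln[(ic + 1):(ic + ncells)]), "\\s+")
  hex <- do.call(rbind, lapply(cell_rows[vapply(cell_rows, `[`, "", 1) == "8"],
                               function(r) as.integer(r[-1]) + 1L))
  lines <- do.call(rbind,
                   lapply(cell_rows[vapply(cell_rows, `[`, "", 1) == "2"],
                          function(r) as.integer(r[-1]) + 1L))
  iv <- grab("^VECTORS displacement")
  disp <- matrix(nums(iv, np), np, 3, byrow = TRUE)
  field <- function(name, comps) {
    i <- grab(paste0("^", name, " "))
    cnt <- as.integer(strsplit(ln[i], " ")[[1]][3])
    matrix(nums(i, cnt), cnt, comps, byrow = TRUE)
  }
  list(points = pts, cells = hex, lines = lines, displacement = disp,
       cauchy_stress = field("cauchy_stress", 6),
       green_strain = field("green_strain", 6),
       axial_stress = as.vector(field("axial_stress", 1)))
}

#' Export the analysis tables as CSV
#'
#' Writes the vessel stress records (one row per beam x frame), the
#' per-threshold exceedance areas, the stress map and a flat statistics
#' summary, plus a column-documentation file.
#' @param records data.frame from [build_records()] (or NULL).
#' @param map a `vessel_stress_map` (or NULL).
#' @param areas threshold-area data.frame (or NULL).
#' @param stats named list of scalar statistics (or NULL).
#' @param path output directory.
#' @return written file paths, invisibly.
#' @export
export_tables <- function(records = NULL, map = NULL, areas = NULL,
                          stats = NULL, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    fn <- file.path(path, name)
    write.csv(df, fn, row.names = FALSE)
    written <<- c(written, fn)
  }
  if (!is.null(records)) wr(records, "vessel_stress_records.csv")
  if (!is.null(map)) wr(as.data.frame(map), "vessel_stress_map.csv")
  if (!is.null(areas)) wr(areas, "threshold_areas.csv")
  if (!is.null(stats)) {
    flat <- unlist(stats)
    wr(data.frame(statistic = names(flat), value = as.numeric(flat)),
       "stats_summary.csv")
  }
  doc <- c(
    "vessel_stress_records.csv: one row per beam element and output frame;",
    "  axial_stress kPa (tension > 0); dir_* current unit direction;",
    "  p1_* first principal (deviatoric) stress kPa / Green-Lagrange strain",
    "  of the host tissue element; angle_* degrees in [0, 90].",
    "vessel_stress_map.csv: per tissue element peak neighbourhood vessel",
    "  stress, kPa; has_vessel FALSE means no beam in the neighbourhood.",
    "threshold_areas.csv: exceedance areas (mm^2) per stress threshold on",
    "  the analysis slice.",
    "stats_summary.csv: flat key/value summary statistics.")
  writeLines(doc, file.path(path, "COLUMNS.txt"))
  invisible(written)
}

#' Default pipeline configuration
#'
#' One hierarchical document holding every stage's parameters (materials,
#' scenario, meshing, mapping, analysis, seeds). Runs should write their
#' resolved configuration next to their outputs ([write_run_config()]).
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seeds = list(network = 1L, image = 1L, bootstrap = 1L),
    domain = list(size = c(2000, 2000, 2000), spacing = 5.92),
    network = unclass(vessel_calibration())[
      c("volume_fraction", "diameter_mean", "diameter_range",
        "diameter_sdlog", "segment_length_mean", "bifurcation_prob")],
    meshing = list(threshold = 100, coarsen = 17, beam_max_len = 60),
    materials = list(
      tissue = list(ogden_mu = 1.2, ogden_alpha = 4.5,
                    prony_G = c(2.4, 1.2), prony_tau = c(0.1, 1.0),
                    density = 1040, bulk_modulus = 1e5),
      vessel = list(elastic_modulus = 1400, poisson_ratio = 0.38,
                    density = 104)),
    scenario = list(impact_depth = 2000, impact_velocity = 4000,
                    impactor_radius = 2500, dwell_time = 0.1,
                    retract = TRUE),
    mapping = list(radius = NULL, thresholds = c(150, 200, 250, 300)),
    analysis = list(roc_bootstrap = 2000))
}

#' Read, validate and write pipeline configurations (YAML)
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("seeds", "domain", "network", "meshing", "materials",
                "scenario")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("config validation failed; missing section(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(cfg$seeds$network)) {
    stop("config validation failed: seeds$network is mandatory")
  }
  cfg
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
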