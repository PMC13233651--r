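# Readers/writers for all artifact formats. Conventions: coordinates in
# mm, times in ms; vertex and neuron ids are written 0-based in files
# (and 1-based inside R); Matrix Market files use that format's 1-based
# indices. CSV files carry headers; malformed rows are reported with file
# line numbers (header = line 1).

read_checked_csv <- function(path, required, numeric_cols = required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(path, ": malformed value in column '", cl, "' at line ",
           bad[1] + 1L)
    df[[cl]] <- v
  }
  df
}

#' Write / read a surface mesh as plain CSV tables
#'
#' Four files in `dir`: `vertices.csv` (`vertex_id`, `x`, `y`, `z`),
#' `triangles.csv` (`v1`, `v2`, `v3`), `labels.csv` (`vertex_id`, `label`,
#' `cortical`) and `apd.csv` (`vertex_id`, `ap`, `pd`). Ids are 0-based on
#' disk.
#'
#' @param mesh a `surface_model`.
#' @param dir output directory (created if needed).
#' @return `write_mesh_csv`: the directory, invisibly. `read_mesh_csv`:
#'   the `surface_model`.
#' @export
write_mesh_csv <- function(mesh, dir) {
  validate_surface_model(mesh)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- data.frame(vertex_id = seq_len(nrow(mesh$vertices)) - 1L,
                  x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                  z = mesh$vertices[, 3])
  utils::write.csv(v, file.path(dir, "vertices.csv"), row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$triangles[, 1] - 1L,
                              v2 = mesh$triangles[, 2] - 1L,
                              v3 = mesh$triangles[, 3] - 1L),
                   file.path(dir, "triangles.csv"), row.names = FALSE)
  utils::write.csv(data.frame(vertex_id = v$vertex_id, label = mesh$labels,
                              cortical = mesh$cortical),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(vertex_id = v$vertex_id,
                              ap = mesh$apd[, "ap"], pd = mesh$apd[, "pd"]),
                   file.path(dir, "apd.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mesh_csv
#' @export
read_mesh_csv <- function(dir) {
  v <- read_checked_csv(file.path(dir, "vertices.csv"),
                        c("vertex_id", "x", "y", "z"))
  o <- order(v$vertex_id)
  v <- v[o, ]
  tr <- read_checked_csv(file.path(dir, "triangles.csv"), c("v1", "v2", "v3"))
  lb <- read_checked_csv(file.path(dir, "labels.csv"), c("vertex_id", "label"),
                         numeric_cols = "vertex_id")
  lb <- lb[order(lb$vertex_id), ]
  ap <- read_checked_csv(file.path(dir, "apd.csv"), c("vertex_id", "ap", "pd"))
  ap <- ap[order(ap$vertex_id), ]
  tri <- as.matrix(tr[, c("v1", "v2", "v3")]) + 1L
  dimnames(tri) <- NULL
  storage.mode(tri) <- "integer"
  mesh <- structure(list(
    vertices = unname(as.matrix(v[, c("x", "y", "z")])),
    triangles = tri,
    labels = as.character(lb$label),
    cortical = if ("cortical" %in% names(lb)) as.logical(lb$cortical)
               else rep(TRUE, nrow(v)),
    apd = cbind(ap = ap$ap, pd = ap$pd)
  ), class = "surface_model")
  validate_surface_model(mesh)
}

#' Write / read a surface mesh in OFF format
#'
#' The Object File Format: a standard plain-text surface representation
#' (`OFF`, counts line, vertex lines, triangle lines with 0-based
#' indices). Labels and AP-PD coordinates are not part of OFF and travel
#' in the CSV sidecars.
#'
#' @param mesh a `surface_model`.
#' @param path file path.
#' @return `read_mesh_off`: list with `vertices` and `triangles` (1-based).
#' @export
write_mesh_off <- function(mesh, path) {
  validate_surface_model(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 2L || trimws(ln[1]) != "OFF")
    stop(path, ": not an OFF file (line 1)")
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vx <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(ln[2 + i]), "\\s+")[[1]]))
    if (length(parts) < 3 || anyNA(parts))
      stop(path, ": malformed vertex at line ", 2 + i)
    vx[i, ] <- parts[1:3]
  }
  tri <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    parts <- suppressWarnings(as.integer(strsplit(trimws(ln[2 + nv + i]), "\\s+")[[1]]))
    if (length(parts) < 4 || parts[1] != 3L || anyNA(parts[1:4]))
      stop(path, ": malformed (non-triangle) face at line ", 2 + nv + i)
    tri[i, ] <- parts[2:4] + 1L
  }
  list(vertices = vx, triangles = tri)
}

#' Write / read connectome matrices in Matrix Market format
#'
#' Weights and tract lengths as coordinate-format Matrix Market files.
#' Explicit zeros in a weight file are dropped on read with a warning
#' (canonical form stores structural nonzeros only).
#'
#' @param conn a `sparse_connectome`.
#' @param weights_path,lengths_path file paths.
#' @param conduction_speed mm/ms used to derive delays on read.
#' @return `read_connectome_mm`: a `sparse_connectome`.
#' @export
write_connectome_mm <- function(conn, weights_path, lengths_path) {
  stopifnot(inherits(conn, "sparse_connectome"))
  Matrix::writeMM(conn$weights, weights_path)
  Matrix::writeMM(conn$tract_lengths, lengths_path)
  invisible(c(weights_path, lengths_path))
}

#' @rdname write_connectome_mm
#' @export
read_connectome_mm <- function(weights_path, lengths_path,
                               conduction_speed = 3) {
  w <- methods::as(Matrix::readMM(weights_path), "CsparseMatrix")
  l <- methods::as(Matrix::readMM(lengths_path), "CsparseMatrix")
  nz <- length(methods::slot(w, "x"))
  wd <- Matrix::drop0(w)
  if (length(methods::slot(wd, "x")) < nz)
    warning(weights_path, ": explicit zero weights dropped")
  sparse_connectome(wd, l * (wd != 0), conduction_speed)
}

#' Write / read neuron and connection tables
#'
#' Neuron table: `id` (0-based), `x`, `y`, `z`, `ap`, `pd`. Connection
#' table: `pre`, `post` (0-based), `weight`, `U`, `tau_rec`, `tau_fac`,
#' `delay`, `length`.
#'
#' @param net a `spiking_network`.
#' @param neurons_path,connections_path file paths.
#' @param neuron_params an `ht_parameters` attached on read.
#' @return `read_network_csv`: a `spiking_network`.
#' @export
write_network_csv <- function(net, neurons_path, connections_path) {
  stopifnot(inherits(net, "spiking_network"))
  cl <- net$cloud
  utils::write.csv(data.frame(id = cl$ids - 1L,
                              x = cl$positions[, 1], y = cl$positions[, 2],
                              z = cl$positions[, 3],
                              ap = cl$apd[, "ap"], pd = cl$apd[, "pd"]),
                   neurons_path, row.names = FALSE)
  cc <- net$connections
  out <- cc
  out$pre <- out$pre - 1L
  out$post <- out$post - 1L
  utils::write.csv(out, connections_path, row.names = FALSE)
  invisible(c(neurons_path, connections_path))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(neurons_path, connections_path,
                             neuron_params = ht_parameters()) {
  nd <- read_checked_csv(neurons_path, c("id", "x", "y", "z", "ap", "pd"))
  nd <- nd[order(nd$id), ]
  if (!identical(as.integer(nd$id), seq_len(nrow(nd)) - 1L))
    stop(neurons_path, ": neuron ids must be contiguous from 0")
  cloud <- structure(list(
    positions = unname(as.matrix(nd[, c("x", "y", "z")])),
    apd = cbind(ap = nd$ap, pd = nd$pd),
    ids = seq_len(nrow(nd))
  ), class = "neuron_cloud")
  cc <- read_checked_csv(connections_path,
                         c("pre", "post", "weight", "U", "tau_rec",
                           "tau_fac", "delay", "length"))
  cc$pre <- as.integer(cc$pre) + 1L
  cc$post <- as.integer(cc$post) + 1L
  if (nrow(cc) && (any(cc$pre < 1L) || any(cc$pre > nrow(nd)) ||
                   any(cc$post < 1L) || any(cc$post > nrow(nd))))
    stop(connections_path, ": connection endpoint outside neuron table")
  structure(list(cloud = cloud, neuron_params = neuron_params,
                 connections = cc), class = "spiking_network")
}

#' Write / read spike records
#'
#' Events as a two-column CSV (`neuron` 0-based, `time` ms) plus the
#' per-vertex count matrix (`spike_counts.csv`, one column per device in
#' device order) and the device order (`device_order.csv`, 0-based vertex
#' ids).
#'
#' @param rec a `spike_record`.
#' @param dir output directory.
#' @param max_time optional duration bound; on read, spike times outside
#'   `[0, max_time]` raise an error naming the offending line.
#' @return `read_spikes_csv`: a `spike_record`.
#' @export
write_spikes_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "spike_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(neuron = rec$events$neuron - 1L,
                              time = rec$events$time),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  cm <- as.data.frame(rec$counts)
  names(cm) <- sprintf("v%d", rec$device_order - 1L)
  utils::write.csv(cm, file.path(dir, "spike_counts.csv"), row.names = FALSE)
  dm <- as.data.frame(rec$device_counts)
  names(dm) <- names(cm)
  utils::write.csv(dm, file.path(dir, "device_counts.csv"), row.names = FALSE)
  utils::write.csv(data.frame(vertex_id = rec$device_order - 1L),
                   file.path(dir, "device_order.csv"), row.names = FALSE)
  utils::write.csv(data.frame(dt = rec$dt, duration = rec$duration),
                   file.path(dir, "spike_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(dir, max_time = NULL) {
  ev <- read_checked_csv(file.path(dir, "spikes.csv"), c("neuron", "time"))
  meta <- read_checked_csv(file.path(dir, "spike_meta.csv"), c("dt", "duration"))
  bound <- if (is.null(max_time)) meta$duration[1] else max_time
  bad <- which(ev$time < 0 | ev$time > bound)
  if (length(bad))
    stop(file.path(dir, "spikes.csv"), ": spike time out of range at line ",
         bad[1] + 1L)
  cm <- as.matrix(utils::read.csv(file.path(dir, "spike_counts.csv")))
  dm <- as.matrix(utils::read.csv(file.path(dir, "device_counts.csv")))
  dev <- read_checked_csv(file.path(dir, "device_order.csv"), "vertex_id")
  structure(list(events = data.frame(neuron = as.integer(ev$neuron) + 1L,
                                     time = ev$time),
                 counts = unname(cm), device_counts = unname(dm),
                 device_order = as.integer(dev$vertex_id) + 1L,
                 dt = meta$dt[1], duration = meta$duration[1]),
            class = "spike_record")
}

#' Write / read field recordings
#'
#' One CSV per state variable (`x1.csv` ... `g.csv`; nodes as columns,
#' samples as rows) plus `times.csv` and `recording_meta.csv`. A plain-text
#' array container chosen for portability of the recorded trajectories.
#'
#' @param rec a `field_recording`.
#' @param dir output directory.
#' @return `read_recording_csv`: a `field_recording` (without `final`
#'   state or running maxima, which are simulation-time products).
#' @export
write_recording_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "field_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(time = rec$times),
                   file.path(dir, "times.csv"), row.names = FALSE)
  for (f in c("x1", "y1", "z", "x2", "y2", "g")) {
    m <- as.data.frame(t(rec[[f]]))
    names(m) <- sprintf("n%d", seq_len(nrow(rec[[f]])) - 1L)
    utils::write.csv(m, file.path(dir, paste0(f, ".csv")), row.names = FALSE)
  }
  utils::write.csv(data.frame(dt = rec$dt, monitor_stride = rec$monitor_stride),
                   file.path(dir, "recording_meta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node = seq_along(rec$x1_max) - 1L,
                              x1_max = rec$x1_max, x2_max = rec$x2_max),
                   file.path(dir, "state_maxima.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(dir) {
  tm <- read_checked_csv(file.path(dir, "times.csv"), "time")
  meta <- read_checked_csv(file.path(dir, "recording_meta.csv"),
                           c("dt", "monitor_stride"))
  out <- list(times = tm$time)
  for (f in c("x1", "y1", "z", "x2", "y2", "g"))
    out[[f]] <- unname(t(as.matrix(utils::read.csv(file.path(dir, paste0(f, ".csv"))))))
  mx <- read_checked_csv(file.path(dir, "state_maxima.csv"),
                         c("node", "x1_max", "x2_max"))
  out$x1_max <- mx$x1_max
  out$x2_max <- mx$x2_max
  out$dt <- meta$dt[1]
  out$monitor_stride <- as.integer(meta$monitor_stride[1])
  out$final <- NULL
  class(out) <- "field_recording"
  out
}

#' Write / read AP-PD coordinate tables
#'
#' Two-axis intrinsic coordinate tables (`id` 0-based, `ap`, `pd`).
#'
#' @param apd n x 2 matrix with columns `ap`, `pd`.
#' @param path file path.
#' @return `read_apd_csv`: data frame with 1-based `id`, `ap`, `pd`
#'   (suitable for [flatmap_ap_pd()]).
#' @export
write_apd_csv <- function(apd, path) {
  utils::write.csv(data.frame(id = seq_len(nrow(apd)) - 1L,
                              ap = apd[, 1], pd = apd[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_apd_csv
#' @export
read_apd_csv <- function(path) {
  df <- read_checked_csv(path, c("id", "ap", "pd"))
  df$id <- as.integer(df$id) + 1L
  df
}

# ---- configuration --------------------------------------------------------

CONFIG_KEYS <- c(
  "schema_version", "include", "seed", "dt", "duration", "monitor_stride",
  "n_ap", "n_pd", "length_ap", "length_pd", "curvature", "thickness",
  "n_neurons", "mean_degree", "length_scale", "sigma", "cutoff",
  "conduction_speed", "onset_nodes", "x0_default", "x0_map",
  "sem", "conversion", "relay_weight", "relay_delay", "connectivity",
  "feedback_gain", "threshold", "hysteresis", "n_bins", "phase_source")

#' Read / write run configuration
#'
#' YAML key-value configuration with one level of `include` support (the
#' included file is read first and overridden by the including file).
#' Unknown top-level keys are rejected; every run writes the resolved
#' configuration alongside its outputs for reproducibility.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$include)) {
    base <- read_config(file.path(dirname(path), cfg$include))
    cfg$include <- NULL
    base[names(cfg)] <- cfg
    cfg <- base
  }
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop(path, ": unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_config
#' @param cfg named configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
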