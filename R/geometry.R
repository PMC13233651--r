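#' Generate a synthetic hippocampus-like surface mesh
#'
#' Builds a curved rectangular sheet parameterized analytically by intrinsic
#' anterior-posterior (AP) and proximal-distal (PD) coordinates, standing in
#' for an MRI-derived hippocampal surface. The sheet is rolled along the PD
#' axis with constant curvature, which is an isometric embedding: intrinsic
#' (AP, PD) distances along the surface are preserved exactly, so the stored
#' `apd` coordinates are ground truth for flat-mapping. PD bands are labeled
#' `subiculum` / `CA1` / `CA2` in order, mimicking hippocampal lamination and
#' exercising the relabeling rule at band boundaries.
#'
#' @param n_ap,n_pd number of grid vertices along the AP and PD axes
#'   (both >= 4).
#' @param length_ap,length_pd physical extent of the sheet in mm
#'   (defaults 40 x 10 mm, a human hippocampus scale).
#' @param curvature curvature (1/mm) of the roll along PD; 0 gives a planar
#'   sheet whose 3D Euclidean distances equal AP-PD distances.
#' @param band_fractions length-3 numeric summing to 1: PD fractions of the
#'   subiculum, CA1 and CA2 bands.
#' @param jitter standard deviation (mm) of optional in-plane vertex jitter;
#'   0 (default) gives the exact analytic grid.
#' @param seed integer seed (used only when `jitter > 0`).
#' @return an object of class `surface_model`: a list with `vertices`
#'   (n x 3, mm), `triangles` (m x 3, 1-based vertex indices), `labels`
#'   (character), `cortical` (logical), `apd` (n x 2, columns `ap`, `pd`).
#' @export
generate_synthetic_hippocampus <- function(n_ap, n_pd,
                                           length_ap = 40, length_pd = 10,
                                           curvature = 0.15,
                                           band_fractions = c(0.25, 0.5, 0.25),
                                           jitter = 0, seed = 1L) {
  stopifnot(length(n_ap) == 1L, length(n_pd) == 1L)
  n_ap <- as.integer(n_ap); n_pd <- as.integer(n_pd)
  if (is.na(n_ap) || is.na(n_pd) || n_ap < 4L || n_pd < 4L)
    stop("degenerate grid: n_ap and n_pd must both be >= 4")
  stopifnot(length_ap > 0, length_pd > 0, curvature >= 0, jitter >= 0,
            length(band_fractions) == 3L, all(band_fractions > 0),
            abs(sum(band_fractions) - 1) < 1e-8)

  ap <- seq(0, length_ap, length.out = n_ap)
  pd <- seq(0, length_pd, length.out = n_pd)
  grid <- expand.grid(ap = ap, pd = pd, KEEP.OUT.ATTRS = FALSE)  # ap fastest
  u <- grid$ap; v <- grid$pd
  if (jitter > 0) {
    set.seed(as.integer(seed))
    u <- pmin(length_ap, pmax(0, u + stats::rnorm(length(u), sd = jitter)))
    v <- pmin(length_pd, pmax(0, v + stats::rnorm(length(v), sd = jitter)))
  }
  verts <- embed_apd(u, v, curvature)

  # two triangles per grid cell
  n <- n_ap * n_pd
  ia <- rep(seq_len(n_ap - 1L), times = n_pd - 1L)
  ip <- rep(seq_len(n_pd - 1L), each = n_ap - 1L)
  v00 <- (ip - 1L) * n_ap + ia
  v10 <- v00 + 1L
  v01 <- v00 + n_ap
  v11 <- v01 + 1L
  tri <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  dimnames(tri) <- NULL
  storage.mode(tri) <- "integer"

  cuts <- cumsum(band_fractions)[1:2] * length_pd
  labels <- ifelse(v < cuts[1], "subiculum", ifelse(v < cuts[2], "CA1", "CA2"))

  structure(list(
    vertices = verts,
    triangles = tri,
    labels = labels,
    cortical = rep(TRUE, n),
    apd = cbind(ap = u, pd = v)
  ), class = "surface_model")
}

# Isometric embedding of intrinsic (ap, pd) into 3D: roll along PD with
# constant curvature. kappa = 0 is the planar limit.
embed_apd <- function(u, v, kappa) {
  if (kappa <= 0) {
    out <- cbind(x = u, y = v, z = rep(0, length(u)))
  } else {
    r <- 1 / kappa
    out <- cbind(x = u, y = r * sin(kappa * v), z = r * (1 - cos(kappa * v)))
  }
  out
}

# Outward unit normal of the rolled sheet at intrinsic coordinate pd.
apd_normal <- function(v, kappa) {
  if (kappa <= 0) return(cbind(0, 0, rep(1, length(v))))
  cbind(0, -sin(kappa * v), cos(kappa * v))
}

#' @export
print.surface_model <- function(x, ...) {
  cat("<surface_model> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))),
                         collapse = ", "), "\n")
  invisible(x)
}

validate_surface_model <- function(mesh) {
  stopifnot(inherits(mesh, "surface_model"))
  n <- nrow(mesh$vertices)
  if (any(mesh$triangles < 1L) || any(mesh$triangles > n))
    stop("triangle indices out of range")
  if (!all(seq_len(n) %in% mesh$triangles))
    stop("every vertex must be referenced by at least one triangle")
  if (!all(is.finite(mesh$apd))) stop("apd coordinates must be finite")
  invisible(mesh)
}

#' Sample a synthetic neuron point cloud above the surface
#'
#' Emulates data-driven 3D soma positioning: somata are drawn uniformly in
#' intrinsic (AP, PD) over the pyramidal-layer band and displaced along the
#' outward surface normal by a uniform depth in `[0, thickness]`. Each
#' neuron carries the AP-PD coordinate of its generating surface point, the
#' ground truth used by the assignment step.
#'
#' @param mesh a `surface_model` from [generate_synthetic_hippocampus()].
#' @param n_neurons number of neurons (>= 1).
#' @param thickness layer thickness in mm (>= 0; 0 puts all somata exactly
#'   on the surface).
#' @param pd_range fraction of the PD extent covered by the layer
#'   (default `c(0.2, 0.8)`, straddling the CA1 band so that some CA2 /
#'   subiculum vertices receive neurons).
#' @param curvature curvature used to embed the somata; taken from the mesh
#'   attribute when available.
#' @param seed integer seed.
#' @return an object of class `neuron_cloud`: list with `positions`
#'   (n x 3 mm), `apd` (n x 2), `ids` (1-based contiguous integers).
#' @export
generate_neuron_cloud <- function(mesh, n_neurons, thickness = 0.5,
                                  pd_range = c(0.2, 0.8), seed = 1L) {
  validate_surface_model(mesh)
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L) stop("n_neurons must be >= 1")
  if (thickness < 0) stop("thickness must be non-negative")
  stopifnot(length(pd_range) == 2L, pd_range[1] < pd_range[2],
            pd_range[1] >= 0, pd_range[2] <= 1)

  ap_max <- max(mesh$apd[, "ap"]); pd_max <- max(mesh$apd[, "pd"])
  kappa <- infer_curvature(mesh)
  set.seed(as.integer(seed))
  u <- runif(n_neurons, 0, ap_max)
  v <- runif(n_neurons, pd_range[1] * pd_max, pd_range[2] * pd_max)
  depth <- runif(n_neurons, 0, thickness)
  pos <- embed_apd(u, v, kappa) + depth * apd_normal(v, kappa)
  colnames(pos) <- c("x", "y", "z")

  structure(list(
    positions = pos,
    apd = cbind(ap = u, pd = v),
    ids = seq_len(n_neurons)
  ), class = "neuron_cloud")
}

# Recover the roll curvature of a synthetic mesh from its embedding:
# a planar sheet has all z = 0.
infer_curvature <- function(mesh) {
  z <- mesh$vertices[, 3]
  if (all(abs(z) < 1e-12)) return(0)
  # max height of the roll: z_max = r * (1 - cos(kappa * pd_max))
  pdm <- max(mesh$apd[, "pd"])
  f <- function(k) (1 / k) * (1 - cos(min(k * pdm, pi))) - max(z)
  stats::uniroot(f, c(1e-6, pi / pdm))$root
}

#' @export
print.neuron_cloud <- function(x, ...) {
  cat("<neuron_cloud> ", length(x$ids), " neurons\n", sep = "")
  invisible(x)
}

#' Geodesic distances along the mesh edge graph
#'
#' Shortest-path distances on the edge-weighted graph of the mesh
#' (edge weight = 3D Euclidean edge length), truncated beyond `cutoff`.
#' This is the standard graph approximation to polyhedral geodesics,
#' adequate at the mesh resolutions used here. Disconnected vertex pairs
#' are simply absent from each other's neighborhoods.
#'
#' @param mesh a `surface_model`.
#' @param cutoff truncation distance in mm (> 0, may be `Inf`).
#' @return a sparse symmetric `dgCMatrix` of distances (mm) with zero
#'   diagonal; entries beyond `cutoff` are structurally absent.
#' @export
geodesic_distances <- function(mesh, cutoff = Inf) {
  validate_surface_model(mesh)
  if (!(cutoff > 0)) stop("cutoff must be > 0")
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e$edges, directed = FALSE)
  d <- igraph::distances(g, weights = e$lengths, algorithm = "dijkstra")
  d[!is.finite(d)] <- 0
  d[d > cutoff] <- 0
  methods::as(Matrix::drop0(Matrix::Matrix(d, sparse = TRUE)), "generalMatrix")
}

# Unique undirected edges of the triangulation with Euclidean lengths.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- t(apply(e, 1L, sort))
  e <- unique(e)
  dv <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  list(edges = e, lengths = sqrt(rowSums(dv^2)))
}

#' Common 2D intrinsic (AP-PD) coordinates for flat-mapping
#'
#' Returns the AP-PD coordinates used to co-register mesh vertices and
#' neuron somata. For synthetic geometry these are the generating
#' parameters (no registration is computed); alternatively an external
#' per-point table (`id`, `ap`, `pd`) may be supplied, e.g. coordinates
#' precomputed by a hippocampal unfolding tool.
#'
#' @param model a `surface_model` or `neuron_cloud`.
#' @param source `NULL` (use the stored ground-truth coordinates) or a
#'   data frame with columns `id` (1-based), `ap`, `pd`.
#' @return an n x 2 matrix with columns `ap`, `pd`.
#' @export
flatmap_ap_pd <- function(model, source = NULL) {
  n <- if (inherits(model, "surface_model")) nrow(model$vertices)
       else if (inherits(model, "neuron_cloud")) length(model$ids)
       else stop("model must be a surface_model or neuron_cloud")
  if (is.null(source)) {
    out <- model$apd
  } else {
    stopifnot(is.data.frame(source), all(c("id", "ap", "pd") %in% names(source)))
    idx <- match(seq_len(n), source$id)
    if (anyNA(idx)) {
      missing_ids <- which(is.na(idx))
      stop("missing AP-PD coordinates for point id(s): ",
           paste(utils::head(missing_ids, 20L), collapse = ", "))
    }
    out <- cbind(ap = source$ap[idx], pd = source$pd[idx])
  }
  if (!all(is.finite(out))) stop("AP-PD coordinates must be finite")
  out
}

ASSIGNABLE_LABELS <- c("CA1", "CA2", "subiculum")

#' Assign each neuron to its nearest eligible mesh vertex
#'
#' Partitions the neuron cloud over the mesh: every neuron is attached to
#' the nearest vertex in AP-PD space among vertices labeled CA1, CA2 or
#' subiculum (ties broken by lowest vertex id). The resulting per-vertex
#' subpopulations are pairwise disjoint, as required for unambiguous
#' per-vertex spike counts; vertices may have empty lists.
#'
#' @param mesh a `surface_model`.
#' @param cloud a `neuron_cloud`.
#' @param mesh_apd,cloud_apd optional AP-PD overrides (see
#'   [flatmap_ap_pd()]).
#' @return an object of class `vertex_assignment`: list with
#'   `neuron_vertex` (the assigned vertex of each neuron),
#'   `vertex_to_neurons` (list over all vertices, ordered neuron ids) and
#'   `device_order` (ascending ids of CA1-labeled vertices of `mesh`).
#' @export
assign_neurons_to_vertices <- function(mesh, cloud,
                                       mesh_apd = NULL, cloud_apd = NULL) {
  validate_surface_model(mesh)
  va <- if (is.null(mesh_apd)) flatmap_ap_pd(mesh) else mesh_apd
  na <- if (is.null(cloud_apd)) flatmap_ap_pd(cloud) else cloud_apd
  eligible <- which(mesh$labels %in% ASSIGNABLE_LABELS)
  if (length(eligible) == 0L)
    stop("no eligible vertices: none labeled ", paste(ASSIGNABLE_LABELS, collapse = "/"))

  nearest <- nearest_index(na, va[eligible, , drop = FALSE])
  neuron_vertex <- eligible[nearest]

  v2n <- split(seq_len(nrow(na)), factor(neuron_vertex, levels = seq_len(nrow(va))))
  v2n <- lapply(v2n, as.integer)

  structure(list(
    neuron_vertex = neuron_vertex,
    vertex_to_neurons = v2n,
    device_order = device_order(mesh)
  ), class = "vertex_assignment")
}

# Index of the nearest row of `ref` for each row of `pts` (2D, exact scan);
# ties resolved to the lowest reference index. Chunked to bound memory.
nearest_index <- function(pts, ref, chunk = 2048L) {
  out <- integer(nrow(pts))
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    d2 <- outer(pts[s:e, 1], ref[, 1], "-")^2 + outer(pts[s:e, 2], ref[, 2], "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Device order: CA1 vertices in ascending id
#'
#' The bridge exchanges per-vertex vectors whose ordering must match the
#' order of creation of the per-vertex input/output devices. Devices are
#' created in ascending CA1 vertex id, so this order is the exchange
#' contract.
#'
#' @param mesh a `surface_model` (after relabeling, for the final order).
#' @return integer vector of CA1 vertex ids, ascending.
#' @export
device_order <- function(mesh) {
  sort(which(mesh$labels == "CA1"))
}

#' Refine anatomical labels from the neuron assignment
#'
#' Applies the anatomical relabeling rule: vertices originally labeled CA2
#' or subiculum that received any neuron become CA1; vertices originally
#' labeled CA1 that received none take the label of the nearest non-CA1
#' vertex (in AP-PD space, after the first rule; ties to the lowest id).
#' Afterwards every CA1 vertex has at least one assigned neuron and every
#' vertex with a neuron is CA1. The operation is idempotent.
#'
#' @param mesh a `surface_model`.
#' @param assignment a `vertex_assignment` computed on the same mesh.
#' @return the relabeled `surface_model`.
#' @export
relabel_vertices <- function(mesh, assignment) {
  validate_surface_model(mesh)
  stopifnot(inherits(assignment, "vertex_assignment"))
  counts <- lengths(assignment$vertex_to_neurons)
  if (length(counts) != nrow(mesh$vertices))
    stop("assignment does not match mesh")
  labels <- mesh$labels

  # rule 1: assigned CA2/subiculum vertices become CA1
  gain <- which(labels %in% c("CA2", "subiculum") & counts > 0)
  labels[gain] <- "CA1"

  # rule 2: unassigned CA1 vertices inherit the nearest non-CA1 label
  lose <- which(mesh$labels == "CA1" & counts == 0)
  if (length(lose)) {
    non_ca1 <- which(labels != "CA1")
    if (length(non_ca1) == 0L)
      stop("unassigned CA1 vertex has no non-CA1 vertex to inherit from")
    apd <- flatmap_ap_pd(mesh)
    nn <- nearest_index(apd[lose, , drop = FALSE], apd[non_ca1, , drop = FALSE])
    labels[lose] <- labels[non_ca1[nn]]
  }
  mesh$labels <- labels
  mesh
}

#' Build the full synthetic co-registration fixture
#'
#' Convenience pipeline: generate the mesh and neuron cloud, assign
#' neurons to vertices, relabel, and compute the final device order.
#'
#' @inheritParams generate_synthetic_hippocampus
#' @inheritParams generate_neuron_cloud
#' @param curvature roll curvature (1/mm).
#' @param seed global seed; split into independent per-stage streams via
#'   [seed_stream()].
#' @return list with `mesh` (relabeled), `cloud`, `assignment` (with
#'   `device_order` updated to the relabeled mesh).
#' @export
build_geometry <- function(n_ap = 20, n_pd = 10, n_neurons = 400,
                           length_ap = 40, length_pd = 10,
                           curvature = 0.15, thickness = 0.5, seed = 1L) {
  mesh <- generate_synthetic_hippocampus(n_ap, n_pd, length_ap, length_pd,
                                         curvature, seed = seed_stream(seed, 0))
  cloud <- generate_neuron_cloud(mesh, n_neurons, thickness,
                                 seed = seed_stream(seed, 1))
  assignment <- assign_neurons_to_vertices(mesh, cloud)
  mesh <- relabel_vertices(mesh, assignment)
  assignment$device_order <- device_order(mesh)
  list(mesh = mesh, cloud = cloud, assignment = assignment)
}
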