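# Per-residue geometric descriptors: solvent accessibility, Voronoi cell
# volume and buriedness. These are the three geometric node features.

# Theoretical maximum accessible surface areas (A^2), Tien et al. 2013,
# used to convert absolute SASA into relative accessibility.
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

# van der Waals radii (A) for the atom types we carry
VDW_RADIUS <- c(N = 1.55, CA = 1.70, C = 1.70, CB = 1.70)

# Canonical principal-axes orientation of a point cloud. Discretized
# geometry (sphere sampling, the axis-aligned clipping box) is computed in
# this frame so the descriptors are invariant under rigid motions of the
# input: the frame co-rotates with the molecule. Axis signs are fixed by
# intrinsic quantities (third moment of the projections, falling back to
# sequence-order correlation near symmetry); the third axis is the cross
# product of the first two, so the frame is right-handed and unambiguous
# for generic structures.
canonical_orientation <- function(pts) {
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  V <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors
  scale3 <- mean(rowSums(X^2))^1.5
  for (j in 1:2) {
    proj <- X %*% V[, j]
    s <- sum(proj^3)
    if (abs(s) < 1e-9 * scale3 * nrow(X)) s <- sum(seq_len(nrow(X)) * proj)
    if (s < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  X %*% V
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(ga * i), r * sin(ga * i), z)
}

model_atoms <- function(model) {
  L <- model_length(model)
  xyz <- rbind(model$coords_n, model$coords_ca, model$coords_c, model$coords_cb)
  list(
    xyz = xyz,
    radius = rep(VDW_RADIUS[c("N", "CA", "C", "CB")], each = L),
    residue = rep(seq_len(L), times = 4)
  )
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley SASA on the backbone + beta-carbon representation (atoms
#' N, Ca, C, Cb with van der Waals radii 1.55/1.70 A) with a water probe of
#' radius 1.4 A. Each atom's sphere is sampled on a deterministic Fibonacci
#' lattice oriented in the structure's canonical principal-axes frame, so
#' results are exactly reproducible for a fixed point count and invariant
#' under rigid motions of the input; areas are summed per residue.
#'
#' @param model a [protein_model()].
#' @param probe_radius probe radius in A (default 1.4).
#' @param n_points sphere sample points per atom (default 120).
#' @return numeric vector of per-residue areas (A^2).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 120L) {
  at <- model_atoms(model)
  at$xyz <- canonical_orientation(at$xyz)
  n <- nrow(at$xyz)
  sphere <- fibonacci_sphere(n_points)
  rr <- at$radius + probe_radius
  area_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(at$xyz, 2, at$xyz[i, ])^2)
    nb <- which(d2 < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- sweep(sphere * rr[i], 2, at$xyz[i, ], "+")
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, at$xyz[j, ])^2)
        free <- free & dj2 >= rr[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    area_atom[i] <- 4 * pi * rr[i]^2 * frac
  }
  as.numeric(rowsum(area_atom, at$residue))
}

#' Relative solvent accessibility
#'
#' SASA divided by the residue type's theoretical maximum accessible area
#' (Tien et al. values).
#' @param model a [protein_model()].
#' @param sasa per-residue SASA; computed if missing.
#' @inheritParams compute_sasa
#' @return numeric vector in \[0, ~1\].
#' @export
relative_sasa <- function(model, sasa = NULL, probe_radius = 1.4,
                          n_points = 120L) {
  if (is.null(sasa)) sasa <- compute_sasa(model, probe_radius, n_points)
  sasa / MAX_ASA[model$sequence]
}

# --- exact clipped Voronoi volumes -----------------------------------------

# Volume of the convex polytope {x : A x <= b} (rows of A unit-norm) by
# vertex enumeration over all constraint triples + facet pyramids.
halfspace_volume <- function(A, b, tol = 1e-7) {
  m <- nrow(A)
  tr <- utils::combn(m, 3L)
  a1 <- A[tr[1, ], , drop = FALSE]
  a2 <- A[tr[2, ], , drop = FALSE]
  a3 <- A[tr[3, ], , drop = FALSE]
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  c23 <- cross3(a2, a3); c31 <- cross3(a3, a1); c12 <- cross3(a1, a2)
  det <- rowSums(a1 * c23)
  ok <- abs(det) > 1e-10
  if (!any(ok)) return(0)
  V <- (b[tr[1, ok]] * c23[ok, , drop = FALSE] +
          b[tr[2, ok]] * c31[ok, , drop = FALSE] +
          b[tr[3, ok]] * c12[ok, , drop = FALSE]) / det[ok]
  feas <- V %*% t(A) <= matrix(b + tol, nrow(V), m, byrow = TRUE)
  V <- V[rowSums(feas) == m, , drop = FALSE]
  if (nrow(V) < 4L) return(0)
  V <- V[!duplicated(round(V, 6)), , drop = FALSE]
  if (nrow(V) < 4L) return(0)
  ctr <- colMeans(V)
  vol <- 0
  slack <- V %*% t(A) - matrix(b, nrow(V), m, byrow = TRUE)
  for (h in seq_len(m)) {
    on <- which(abs(slack[, h]) < 1e-5)
    if (length(on) < 3L) next
    nrm <- A[h, ]
    e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    P <- V[on, , drop = FALSE] %*% cbind(e1, e2)
    P <- sweep(P, 2, colMeans(P))
    o <- order(atan2(P[, 2], P[, 1]))
    P <- P[o, , drop = FALSE]
    k <- nrow(P)
    area <- abs(sum(P[, 1] * P[c(2:k, 1), 2] - P[c(2:k, 1), 1] * P[, 2])) / 2
    height <- b[h] - sum(nrm * ctr)
    vol <- vol + area * height / 3
  }
  vol
}

#' Voronoi cell volume per residue
#'
#' Volume of each residue's Voronoi cell in the tessellation of the alpha
#' carbons, clipped to the model's bounding box inflated by `pad` on every
#' side (unbounded outer cells take their clipped volume). The box is
#' axis-aligned in the structure's canonical principal-axes frame, so the
#' clipping region co-rotates with the molecule and the volumes are
#' invariant under rigid motions. Cells are computed exactly as half-space
#' intersections (perpendicular bisector planes plus the six box walls)
#' via vertex enumeration.
#'
#' @param model a [protein_model()].
#' @param pad bounding-box inflation in A (default 10).
#' @return numeric vector of per-residue volumes (A^3).
#' @export
compute_voronoi_volume <- function(model, pad = 10) {
  pts <- canonical_orientation(model$coords_ca)
  L <- nrow(pts)
  if (L < 5L) stop("need at least 5 residues for a Voronoi tessellation")
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate geometry: all Ca atoms are coplanar")
  }
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  box_A <- rbind(diag(3), -diag(3))
  box_b <- c(hi, -lo)
  vapply(seq_len(L), function(i) {
    diff <- sweep(pts[-i, , drop = FALSE], 2, pts[i, ])
    nn <- sqrt(rowSums(diff^2))
    A <- diff / nn
    # bisector plane: a . x <= a . (p_i + p_j)/2
    mid <- (sweep(pts[-i, , drop = FALSE], 2, pts[i, ], "+")) / 2
    b <- rowSums(A * mid)
    halfspace_volume(rbind(A, box_A), c(b, box_b))
  }, numeric(1))
}

#' Buriedness: hop distance to the nearest accessible residue
#'
#' Residues with relative SASA at least `access_threshold` are classified
#' solvent-accessible and get buriedness 0. Every other residue gets its
#' breadth-first hop distance to the nearest accessible residue on the
#' residue contact graph (Ca-Ca distance <= `contact_cutoff`); residues
#' that cannot reach any accessible residue get L.
#'
#' @param model a [protein_model()].
#' @param sasa per-residue SASA from [compute_sasa()]; computed if missing.
#' @param access_threshold relative-accessibility cutoff (default 0.05).
#' @param contact_cutoff Ca-Ca contact distance in A (default 10).
#' @return integer vector of hop distances.
#' @export
compute_buriedness <- function(model, sasa = NULL, access_threshold = 0.05,
                               contact_cutoff = 10) {
  L <- model_length(model)
  rel <- relative_sasa(model, sasa)
  src <- which(rel >= access_threshold)
  if (length(src) == L) return(rep(0L, L))
  adj <- as.matrix(stats::dist(model$coords_ca)) <= contact_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  out <- rep(L, L)
  if (length(src) > 0L) {
    d <- igraph::distances(g, v = seq_len(L), to = src)
    mind <- apply(d, 1, min)
    out <- ifelse(is.finite(mind), as.integer(mind), L)
  }
  as.integer(out)
}

#' All three geometric descriptors at once
#'
#' @param model a [protein_model()].
#' @param ... passed to [compute_sasa()].
#' @return object of class `geometric_descriptors` with numeric fields
#'   `sasa`, `voronoi_volume` and integer `buriedness`.
#' @export
compute_descriptors <- function(model, ...) {
  sasa <- compute_sasa(model, ...)
  structure(list(
    sasa = sasa,
    voronoi_volume = compute_voronoi_volume(model),
    buriedness = compute_buriedness(model, sasa = sasa)
  ), class = "geometric_descriptors")
}
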