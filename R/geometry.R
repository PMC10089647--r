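#' Local backbone coordinate frames
#'
#' For every residue, builds the right-handed orthonormal frame anchored at
#' the alpha carbon: the x-axis is the normalized Ca->N vector; the y-axis
#' lies in the C-Ca-N plane, orthogonal to x, oriented to have positive dot
#' product with the Ca->C vector; the z-axis is x cross y. Inter-residue
#' directions expressed in these frames are invariant under global rigid
#' motions, which is what makes the spherical-harmonic edge embedding
#' rotation-invariant.
#'
#' @param model a [protein_model()].
#' @return list of `local_frame` objects (fields `origin`, `x_axis`,
#'   `y_axis`, `z_axis`), one per residue.
#' @export
build_local_frames <- function(model) {
  L <- model_length(model)
  lapply(seq_len(L), function(i) {
    n <- model$coords_n[i, ]; ca <- model$coords_ca[i, ]; cc <- model$coords_c[i, ]
    vx <- n - ca
    nx <- sqrt(sum(vx^2))
    if (nx == 0) stop("geometry error: N coincides with Ca at residue ", i)
    vx <- vx / nx
    vc <- cc - ca
    vy <- vc - sum(vc * vx) * vx
    ny <- sqrt(sum(vy^2))
    if (ny < 1e-8) {
      # collinear backbone: nudge C off the axis so a frame still exists
      warning("near-collinear N-Ca-C at residue ", i, "; perturbing frame")
      vc <- vc + c(1e-6, 0, 0)
      vy <- vc - sum(vc * vx) * vx
      ny <- sqrt(sum(vy^2))
      if (ny < 1e-12) stop("geometry error: collinear N-Ca-C at residue ", i)
    }
    vy <- vy / ny
    vz <- c(vx[2] * vy[3] - vx[3] * vy[2],
            vx[3] * vy[1] - vx[1] * vy[3],
            vx[1] * vy[2] - vx[2] * vy[1])
    structure(list(origin = ca, x_axis = vx, y_axis = vy, z_axis = vz),
              class = "local_frame")
  })
}

#' Spherical angles of inter-residue directions in local frames
#'
#' Expresses the vector from residue i's Ca to residue j's Ca in residue
#' i's local frame and returns its spherical coordinates: the polar angle
#' theta measured from the local z-axis (in \[0, pi\]), the azimuth phi
#' measured from the x-axis toward the y-axis (in (-pi, pi\]), and the
#' radial distance. Diagonal entries are 0 by convention.
#'
#' @param frames list of frames from [build_local_frames()].
#' @param model the same [protein_model()].
#' @return list with L x L matrices `theta`, `phi`, `radius`.
#' @export
spherical_angles <- function(frames, model) {
  L <- model_length(model)
  stopifnot(length(frames) == L)
  ca <- model$coords_ca
  theta <- phi <- r <- matrix(0, L, L)
  for (i in seq_len(L)) {
    v <- sweep(ca, 2, ca[i, ])            # rows: Ca_j - Ca_i
    f <- frames[[i]]
    a <- v %*% cbind(f$x_axis, f$y_axis, f$z_axis)
    ri <- sqrt(rowSums(a^2))
    th <- ifelse(ri > 0, acos(pmin(pmax(a[, 3] / pmax(ri, 1e-300), -1), 1)), 0)
    ph <- atan2(a[, 2], a[, 1])
    th[i] <- 0; ph[i] <- 0
    theta[i, ] <- th; phi[i, ] <- ph; r[i, ] <- ri
  }
  list(theta = theta, phi = phi, radius = r)
}

# Associated Legendre functions P_lm(x) for l = 0..lmax, m = 0..l, with the
# Condon-Shortley phase, by the standard stable recursions.
assoc_legendre <- function(x, lmax) {
  n <- length(x)
  out <- vector("list", lmax + 1L)
  for (l in 0:lmax) out[[l + 1L]] <- matrix(0, n, l + 1L)
  s <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, n)
  for (m in 0:lmax) {
    if (m > 0) pmm <- pmm * (-(2 * m - 1)) * s
    out[[m + 1L]][, m + 1L] <- pmm
    if (m < lmax) {
      pm1 <- x * (2 * m + 1) * pmm
      out[[m + 2L]][, m + 1L] <- pm1
      if (m + 2L <= lmax) {
        pprev <- pmm; pcur <- pm1
        for (l in (m + 2L):lmax) {
          pnew <- ((2 * l - 1) * x * pcur - (l + m - 1) * pprev) / (l - m)
          out[[l + 1L]][, m + 1L] <- pnew
          pprev <- pcur; pcur <- pnew
        }
      }
    }
  }
  out
}

#' Real spherical harmonics of pair directions
#'
#' Evaluates real-form spherical harmonics Y_lm(theta, phi) for degrees
#' l = 0..`max_degree` on each pair of angles. The complex harmonics use
#' the orthonormal physics normalization sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!)
#' with the Condon-Shortley phase inside the associated Legendre functions;
#' real forms are sqrt(2) Re(Y_l^m) for m > 0, Y_l^0 for m = 0 and
#' -sqrt(2) Im(Y_l^m) for m < 0. Channels are ordered
#' (0,0), (1,-1), (1,0), (1,1), ..., (l, -l..l); with the default degree 4
#' there are exactly 25 channels and channel 1 is the constant
#' 1/(2 sqrt(pi)).
#'
#' @param theta,phi angle matrices (any common shape).
#' @param max_degree highest degree l (default 4).
#' @return array of dimension `c(dim(theta), (max_degree+1)^2)`.
#' @export
real_spherical_harmonics <- function(theta, phi, max_degree = 4L) {
  if (max_degree < 0L) stop("contract error: max_degree must be >= 0")
  dm <- dim(theta)
  if (is.null(dm)) dm <- length(theta)
  th <- as.numeric(theta); ph <- as.numeric(phi)
  stopifnot(length(th) == length(ph), all(is.finite(th)), all(is.finite(ph)))
  P <- assoc_legendre(cos(th), max_degree)
  nch <- (max_degree + 1L)^2
  out <- matrix(0, length(th), nch)
  ch <- 0L
  for (l in 0:max_degree) {
    for (m in (-l):l) {
      ch <- ch + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- P[[l + 1L]][, am + 1L]
      out[, ch] <- if (m > 0) {
        sqrt(2) * nrm * p * cos(m * ph)
      } else if (m == 0) {
        nrm * p
      } else {
        # -sqrt(2) Im(Y_l^{-|m|}) with Y_l^{-m} = (-1)^m conj(Y_l^m)
        (-1)^am * sqrt(2) * nrm * p * sin(am * ph)
      }
    }
  }
  array(out, dim = c(dm, nch))
}

#' Spherical-harmonic pair embedding of a model
#'
#' Convenience wrapper: local frames -> spherical angles -> real spherical
#' harmonics, returning the full `spherical_embedding` used as the
#' geometric edge feature block.
#'
#' @param model a [protein_model()].
#' @param max_degree highest harmonic degree (default 4, i.e. 25 channels).
#' @return object of class `spherical_embedding` with fields `theta`,
#'   `phi`, `radius` (L x L) and `harmonics` (L x L x 25).
#' @export
spherical_embedding <- function(model, max_degree = 4L) {
  fr <- build_local_frames(model)
  ang <- spherical_angles(fr, model)
  h <- real_spherical_harmonics(ang$theta, ang$phi, max_degree)
  structure(list(theta = ang$theta, phi = ang$phi, radius = ang$radius,
                 harmonics = h), class = "spherical_embedding")
}

#' Local Distance Difference Test (Ca-lDDT)
#'
#' Superposition-free per-residue accuracy of `model` against `reference`.
#' For residue i, all pairs (i, j), j != i, whose reference Ca-Ca distance
#' is at most `inclusion_radius` are scored: each of the four thresholds
#' (0.5, 1, 2, 4 A by default) is passed when |d_model - d_reference| is
#' within it, and the score is the mean pass fraction over the thresholds.
#' Residues with an empty inclusion set score 1. The global score is the
#' mean over residues.
#'
#' @param model,reference `protein_model`s of identical length and sequence.
#' @param inclusion_radius reference-distance cutoff (A), default 15.
#' @param thresholds distance-error thresholds (A).
#' @return object of class `lddt_result`: `per_residue` in \[0,1\] and
#'   `global` (their mean).
#' @export
compute_lddt <- function(model, reference, inclusion_radius = 15,
                         thresholds = c(0.5, 1, 2, 4)) {
  L <- model_length(model)
  if (L != model_length(reference)) {
    stop("contract error: model and reference lengths differ")
  }
  if (!identical(model$sequence, reference$sequence)) {
    stop("contract error: model and reference sequences differ")
  }
  dm <- as.matrix(stats::dist(model$coords_ca))
  dr <- as.matrix(stats::dist(reference$coords_ca))
  incl <- dr <= inclusion_radius
  diag(incl) <- FALSE
  err <- abs(dm - dr)
  per <- vapply(seq_len(L), function(i) {
    j <- which(incl[i, ])
    if (length(j) == 0L) return(1)
    mean(vapply(thresholds, function(t) mean(err[i, j] <= t), numeric(1)))
  }, numeric(1))
  structure(list(per_residue = per, global = mean(per)),
            class = "lddt_result")
}
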