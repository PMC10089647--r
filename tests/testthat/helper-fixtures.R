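# Shared test helpers: random rigid transforms, a chain builder from Ca
# positions, and independent oracles (table-form spherical harmonics,
# brute-force lDDT, brute-force error binning, brute-force initial score).

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal valid chain with given Ca positions (constant N/C offsets keep
# every backbone frame well defined; fine when only Ca geometry matters)
model_from_ca <- function(ca, sequence = NULL) {
  L <- nrow(ca)
  if (is.null(sequence)) sequence <- rep("A", L)
  protein_model(
    sequence = sequence,
    coords_n = sweep(ca, 2, c(1.458, 0, 0), "+"),
    coords_ca = ca,
    coords_c = sweep(ca, 2, c(0, 1.525, 0), "+"),
    bfactor = rep(0.9, L)
  )
}

# Real spherical harmonics up to degree 4 from explicit trigonometric
# polynomial formulas (standard tables), adjusted by (-1)^m for m > 0 to
# match the stated convention (Condon-Shortley phase inside P_lm, real
# forms sqrt(2) Re / -sqrt(2) Im on top). Independent of the package's
# Legendre-recursion implementation.
sh_table_oracle <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  x <- st * cos(phi); y <- st * sin(phi); z <- ct
  v <- c(
    0.5 / sqrt(pi),
    # l = 1: (1,-1), (1,0), (1,1)
    sqrt(3 / (4 * pi)) * y,
    sqrt(3 / (4 * pi)) * z,
    -sqrt(3 / (4 * pi)) * x,
    # l = 2
    0.5 * sqrt(15 / pi) * x * y,
    0.5 * sqrt(15 / pi) * y * z,
    0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
    -0.5 * sqrt(15 / pi) * x * z,
    0.25 * sqrt(15 / pi) * (x^2 - y^2),
    # l = 3
    0.25 * sqrt(35 / (2 * pi)) * y * (3 * x^2 - y^2),
    0.5 * sqrt(105 / pi) * x * y * z,
    0.25 * sqrt(21 / (2 * pi)) * y * (5 * z^2 - 1),
    0.25 * sqrt(7 / pi) * z * (5 * z^2 - 3),
    -0.25 * sqrt(21 / (2 * pi)) * x * (5 * z^2 - 1),
    0.25 * sqrt(105 / pi) * (x^2 - y^2) * z,
    -0.25 * sqrt(35 / (2 * pi)) * x * (x^2 - 3 * y^2),
    # l = 4
    0.75 * sqrt(35 / pi) * x * y * (x^2 - y^2),
    0.75 * sqrt(35 / (2 * pi)) * y * z * (3 * x^2 - y^2),
    0.75 * sqrt(5 / pi) * x * y * (7 * z^2 - 1),
    0.75 * sqrt(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
    (3 / 16) * sqrt(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
    -0.75 * sqrt(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
    (3 / 8) * sqrt(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
    -0.75 * sqrt(35 / (2 * pi)) * x * z * (x^2 - 3 * y^2),
    (3 / 16) * sqrt(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4)
  )
  v
}

# naive double-loop Ca-lDDT
lddt_oracle <- function(model, reference, radius = 15,
                        thresholds = c(0.5, 1, 2, 4)) {
  L <- model_length(model)
  dm <- as.matrix(dist(model$coords_ca))
  dr <- as.matrix(dist(reference$coords_ca))
  per <- numeric(L)
  for (i in seq_len(L)) {
    hits <- 0; npairs <- 0
    for (j in seq_len(L)) {
      if (j == i || dr[i, j] > radius) next
      npairs <- npairs + 1
      for (t in thresholds) {
        if (abs(dm[i, j] - dr[i, j]) <= t) hits <- hits + 1
      }
    }
    per[i] <- if (npairs == 0) 1 else hits / (4 * npairs)
  }
  per
}

# naive triple-loop signed-error binning
error_bin_oracle <- function(disto, model) {
  L <- model_length(model)
  mid <- (disto$lower_bounds + disto$upper_bounds) / 2
  edges <- c(-Inf, -4, -2, -1, -0.5, 0.5, 1, 2, 4, Inf)
  dcb <- as.matrix(dist(model$coords_cb))
  out <- array(0, c(L, L, 9))
  for (i in seq_len(L)) for (j in seq_len(L)) for (k in seq_along(mid)) {
    e <- mid[k] - dcb[i, j]
    n <- max(which(e > edges[1:9]))
    out[i, j, n] <- out[i, j, n] + disto$probs[i, j, k]
  }
  out
}

# naive double-loop contact-weighted initial score
initial_score_oracle <- function(error_probs, contact) {
  L <- dim(error_probs)[1]
  w <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)
  out <- numeric(L)
  for (n in seq_len(L)) {
    num <- 0; den <- 0
    for (i in seq_len(L)) {
      num <- num + contact[n, i] * sum(error_probs[n, i, ] * w)
      den <- den + contact[n, i]
    }
    out[n] <- if (den > 0) num / den else 0
  }
  out
}
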