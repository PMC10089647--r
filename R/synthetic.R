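# Self-contained synthetic fixtures: ideal-helix natives, smoothly
# perturbed decoys with known true lDDT, discretized-Gaussian distograms
# and random symmetric attention tensors. Everything is deterministic for
# a fixed seed, so the whole pipeline is testable with no external data.

#' Generate an ideal alpha-helical native structure
#'
#' Places Ca atoms on an ideal alpha helix (radius 2.3 A, rise 1.5 A per
#' residue, 100 degree turn) and builds N and C atoms from the local helix
#' frame with realistic bond lengths (1.458 / 1.525 A) so every residue has
#' a well-defined, non-collinear backbone frame. Beta carbons are placed by
#' ideal tetrahedral geometry. The sequence is uniform over the 20 standard
#' amino acids.
#'
#' @param length chain length (>= 5).
#' @param seed RNG seed (sequence only; geometry is deterministic).
#' @return a [protein_model()].
#' @export
make_native <- function(length, seed = 1L) {
  stopifnot(length >= 5L)
  L <- as.integer(length)
  k <- seq_len(L)
  turn <- 100 * pi / 180
  ca <- cbind(2.3 * cos(k * turn), 2.3 * sin(k * turn), 1.5 * k)
  # local helix frame: tangent along the chain, outward normal from the axis
  tang <- ca[pmin(k + 1, L), , drop = FALSE] - ca[pmax(k - 1, 1), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  outward <- cbind(cos(k * turn), sin(k * turn), 0)
  dirn <- -tang + 0.8 * outward
  dirn <- dirn / sqrt(rowSums(dirn^2))
  dirc <- tang + 0.8 * outward
  dirc <- dirc / sqrt(rowSums(dirc^2))
  n <- ca + 1.458 * dirn
  cc <- ca + 1.525 * dirc
  sq <- with_seed(seed, sample(AA1, L, replace = TRUE))
  protein_model(sequence = sq, coords_n = n, coords_ca = ca, coords_c = cc,
                bfactor = rep(1, L))
}

#' Perturb a native into a decoy with known per-residue accuracy
#'
#' Adds a smooth, chain-correlated Gaussian displacement field (white noise
#' convolved with a Gaussian window along the sequence, then rescaled to
#' RMS `noise_scale`) rigidly to all atoms of each residue. Chain-smoothed
#' noise makes the true per-residue lDDT vary along the chain, which is
#' what residue-level learning needs; i.i.d. noise would not. The decoy's
#' b-factor column is set to its true lDDT plus `confidence_bias`
#' (clamped), emulating a (mis)calibrated self-estimate.
#'
#' @param native a [protein_model()].
#' @param noise_scale RMS displacement in A (>= 0).
#' @param seed RNG seed.
#' @param smooth_window Gaussian smoothing bandwidth in residues (default 4).
#' @param confidence_bias additive bias of the self-reported confidence
#'   relative to the true lDDT (default 0 = well calibrated).
#' @return list with `model` (the decoy) and `true_lddt` (per residue, via
#'   [compute_lddt()] against the native).
#' @export
make_decoy <- function(native, noise_scale, seed = 1L, smooth_window = 4,
                       confidence_bias = 0) {
  stopifnot(noise_scale >= 0)
  L <- model_length(native)
  disp <- with_seed(seed, matrix(stats::rnorm(L * 3), L, 3))
  if (noise_scale > 0) {
    w <- stats::dnorm(seq(-3 * smooth_window, 3 * smooth_window),
                      sd = smooth_window)
    smooth1 <- function(v) {
      padded <- c(rep(v[1], length(w)), v, rep(v[L], length(w)))
      stats::filter(padded, w / sum(w), sides = 2)[length(w) + seq_len(L)]
    }
    disp <- apply(disp, 2, smooth1)
    rms <- sqrt(mean(rowSums(disp^2)))
    disp <- disp * (noise_scale / rms)
  } else {
    disp <- disp * 0
  }
  decoy <- protein_model(
    sequence = native$sequence,
    coords_n = native$coords_n + disp,
    coords_ca = native$coords_ca + disp,
    coords_c = native$coords_c + disp,
    coords_cb = native$coords_cb + disp,
    bfactor = rep(1, L),
    chain_id = native$chain_id
  )
  tl <- compute_lddt(decoy, native)$per_residue
  decoy$bfactor <- pmin(pmax(tl + confidence_bias, 0), 1)
  list(model = decoy, true_lddt = tl)
}

#' Synthesize a distogram prediction around a structure's distances
#'
#' Emulates a structure predictor's distogram: for every residue pair, a
#' Gaussian over the 64 standard distance bins centered on the structure's
#' Cb-Cb distance (jittered slightly) with spread 1/`concentration`,
#' discretized by integrating the density over each bin (open end bins take
#' the tails) and renormalized. Symmetric by construction.
#'
#' @param truth the [protein_model()] whose distances the distogram
#'   believes in.
#' @param concentration inverse spread (1/A); larger = sharper (> 0).
#' @param seed RNG seed for the center jitter.
#' @param source_id identifier for channel ordering.
#' @return a [distogram_prediction()].
#' @export
make_distogram <- function(truth, concentration = 2, seed = 1L,
                           source_id = "synthetic") {
  stopifnot(concentration > 0)
  L <- model_length(truth)
  sdev <- 1 / concentration
  d <- as.matrix(stats::dist(truth$coords_cb))
  jit <- with_seed(seed, matrix(stats::rnorm(L * L, sd = sdev / 4), L, L))
  jit <- (jit + t(jit)) / 2
  ctr <- d + jit
  bins <- distogram_bins()
  edges <- c(-Inf, bins$upper[-64L], Inf)
  probs <- array(0, dim = c(L, L, 64L))
  for (k in seq_len(64L)) {
    probs[, , k] <- stats::pnorm(edges[k + 1L], mean = ctr, sd = sdev) -
      stats::pnorm(edges[k], mean = ctr, sd = sdev)
  }
  s <- apply(probs, c(1, 2), sum)
  probs <- sweep(probs, c(1, 2), pmax(s, 1e-300), "/")
  distogram_prediction(probs, source_id = source_id)
}

#' Random symmetric attention tensor
#'
#' Stands in for a protein-language-model attention map (synthetic: it
#' carries no signal, only the right shape and symmetry).
#'
#' @param L chain length.
#' @param seed RNG seed.
#' @param heads channel count (default 120).
#' @return L x L x heads array, symmetric in the pair axes.
#' @export
make_attention <- function(L, seed = 1L, heads = 120L) {
  a <- with_seed(seed, array(stats::runif(L * L * heads), dim = c(L, L, heads)))
  (a + aperm(a, c(2, 1, 3))) / 2
}

#' Bundle a complete synthetic QA target
#'
#' Generates a native, four decoys at noise scales 0.5/1/2/4 A with their
#' true per-residue lDDT, five reference predictions (small-noise decoys at
#' 0.4-0.8 A, each with a matching distogram centered on its own distances
#' and a confidence equal to its own true lDDT — a well-calibrated
#' predictor), and a random symmetric attention tensor. Fully deterministic
#' per seed.
#'
#' @param length chain length (>= 10).
#' @param seed integer seed.
#' @param decoy_noise noise scales for the decoy set (A).
#' @param reference_noise noise scales for the 5 references (A).
#' @param reference_concentration distogram sharpness for references.
#' @param confidence_bias miscalibration bias applied to the references'
#'   self-confidence (default 0).
#' @return object of class `synthetic_target` with fields `native`,
#'   `decoys` (list of `model` + `true_lddt`), `references` (5 entries of
#'   `model`, `distogram`, `confidence`, `source_id`), `attention`,
#'   `rng_seed`.
#' @export
make_target <- function(length, seed = 1L,
                        decoy_noise = c(0.5, 1, 2, 4),
                        reference_noise = seq(0.4, 0.8, length.out = 5),
                        reference_concentration = 2,
                        confidence_bias = 0) {
  stopifnot(length >= 10L)
  native <- make_native(length, seed = seed)
  decoys <- lapply(seq_along(decoy_noise), function(i) {
    make_decoy(native, decoy_noise[i], seed = seed * 1000L + i)
  })
  references <- lapply(seq_len(5L), function(i) {
    ref <- make_decoy(native, reference_noise[i], seed = seed * 2000L + i,
                      confidence_bias = confidence_bias)
    disto <- make_distogram(ref$model, concentration = reference_concentration,
                            seed = seed * 3000L + i,
                            source_id = sprintf("ref%02d", i))
    list(model = ref$model, distogram = disto,
         confidence = ref$model$bfactor, source_id = sprintf("ref%02d", i))
  })
  structure(list(
    native = native, decoys = decoys, references = references,
    attention = make_attention(length, seed = seed * 4000L + 1L),
    rng_seed = as.integer(seed)
  ), class = "synthetic_target")
}

#' Materialize a synthetic target bundle on disk
#'
#' Writes the native and decoy PDBs, the five reference PDBs with their
#' distogram archives, and the attention archive, for end-to-end
#' command-line tests.
#'
#' @param target a [make_target()] bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_fixture_bundle <- function(target, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_pdb(target$native, file.path(dir, "native.pdb"))
  for (i in seq_along(target$decoys)) {
    write_model_pdb(target$decoys[[i]]$model,
                    file.path(dir, sprintf("decoy%02d.pdb", i)))
  }
  for (i in seq_along(target$references)) {
    r <- target$references[[i]]
    write_model_pdb(r$model, file.path(dir, sprintf("ref%02d.pdb", i)))
    write_distogram(r$distogram, file.path(dir, sprintf("disto%02d.rds", i)))
  }
  write_attention_tensor(target$attention, file.path(dir, "attention.rds"))
  invisible(dir)
}

#' Read a synthetic target bundle back from disk
#'
#' Inverse of [write_fixture_bundle()] (up to PDB fixed-width precision):
#' reads the native, decoys, references with distograms, and the attention
#' tensor; decoy true-lDDT values are recomputed against the native.
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return a `synthetic_target`.
#' @export
read_fixture_bundle <- function(dir) {
  native <- read_pdb_model(file.path(dir, "native.pdb"))
  L <- model_length(native)
  decoy_files <- sort(list.files(dir, "^decoy[0-9]+\\.pdb$", full.names = TRUE))
  decoys <- lapply(decoy_files, function(f) {
    m <- read_pdb_model(f)
    list(model = m, true_lddt = compute_lddt(m, native)$per_residue)
  })
  ref_files <- sort(list.files(dir, "^ref[0-9]+\\.pdb$", full.names = TRUE))
  references <- lapply(seq_along(ref_files), function(i) {
    m <- read_pdb_model(ref_files[i])
    d <- read_distogram(file.path(dir, sprintf("disto%02d.rds", i)))
    list(model = m, distogram = d, confidence = m$bfactor,
         source_id = d$source_id)
  })
  att_path <- file.path(dir, "attention.rds")
  attention <- if (file.exists(att_path)) {
    read_attention_tensor(att_path, L)
  } else NULL
  structure(list(native = native, decoys = decoys, references = references,
                 attention = attention, rng_seed = NA_integer_),
            class = "synthetic_target")
}
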