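# Node and edge feature assembly for the two operating modes:
#  - reference mode: five reference predictions (model + distogram +
#    confidence) are available -> (L,33) nodes, (L,L,71) edges
#  - single-model mode: only the input model (plus an optional language
#    model attention tensor) -> (L,24) nodes, (L,L,146) edges

#' Default 64-bin distogram bounds
#'
#' The AlphaFold2 distogram convention: 64 Cb-Cb distance bins whose 63
#' finite edges run from 2.3125 to 21.6875 A in steps of 0.3125 A. The two
#' open end bins are given finite pseudo-bounds half a bin width beyond the
#' first/last edge so every bin has a finite midpoint (needed by the
#' distance-error transform).
#'
#' @return list with numeric length-64 vectors `lower`, `upper`, `mid`.
#' @export
distogram_bins <- function() {
  edges <- seq(2.3125, 21.6875, by = 0.3125)   # 63 finite edges
  w <- 0.3125
  lower <- c(edges[1] - w, edges)
  upper <- c(edges, edges[length(edges)] + w)
  list(lower = lower, upper = upper, mid = (lower + upper) / 2)
}

# Signed distance-error bins: the unique 9-bin partition of the real line
# symmetric around the four lDDT thresholds (0.5, 1, 2, 4 A), open tails.
ERROR_BIN_EDGES <- c(-Inf, -4, -2, -1, -0.5, 0.5, 1, 2, 4, Inf)

#' Construct a distogram prediction
#'
#' An L x L x 64 tensor of per-pair probability distributions over Cb-Cb
#' distance bins. Logits are accepted and softmax-normalized per pair; the
#' tensor is symmetrized over the pair axes and renormalized.
#'
#' @param probs L x L x 64 array of probabilities, or logits when
#'   `logits = TRUE`.
#' @param lower_bounds,upper_bounds per-bin bounds (A); default AlphaFold2
#'   convention from [distogram_bins()].
#' @param source_id identifier used for deterministic ordering of reference
#'   channels.
#' @param logits whether `probs` holds unnormalized logits.
#' @return object of class `distogram_prediction`.
#' @export
distogram_prediction <- function(probs, lower_bounds = NULL,
                                 upper_bounds = NULL, source_id = "disto",
                                 logits = FALSE) {
  bins <- distogram_bins()
  if (is.null(lower_bounds)) lower_bounds <- bins$lower
  if (is.null(upper_bounds)) upper_bounds <- bins$upper
  stopifnot(length(dim(probs)) == 3L, dim(probs)[3] == length(lower_bounds),
            dim(probs)[1] == dim(probs)[2],
            length(lower_bounds) == length(upper_bounds))
  if (any(diff(lower_bounds) <= 0) || any(diff(upper_bounds) <= 0)) {
    stop("bin bounds must be strictly increasing")
  }
  if (logits) {
    mx <- apply(probs, c(1, 2), max)
    e <- exp(sweep(probs, c(1, 2), mx))
    probs <- sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
  }
  probs <- (probs + aperm(probs, c(2, 1, 3))) / 2
  s <- apply(probs, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-5)) {
    probs <- sweep(probs, c(1, 2), s, "/")
  }
  structure(list(probs = probs, lower_bounds = lower_bounds,
                 upper_bounds = upper_bounds, source_id = source_id),
            class = "distogram_prediction")
}

#' Distance-error probabilities from a distogram and a model
#'
#' Converts a 64-bin distance distribution into a 9-bin distribution over
#' the signed distance error between the predicted distance and the
#' model's Cb-Cb distance. For each pair (i,j) and distogram bin k, the
#' signed error mid_k - d_model(i,j) (mid_k the bin midpoint) is assigned
#' to one of nine signed bins with edges at +-0.5, +-1, +-2, +-4 A (open
#' tails), and the bin accumulates that distogram bin's probability. The
#' nine bins partition the real line, so per-pair mass is conserved.
#'
#' @param disto a [distogram_prediction()].
#' @param model the scored [protein_model()] (Cb distances are used).
#' @return object of class `error_bin_probabilities`: `probs` (L x L x 9)
#'   and `bin_edges`.
#' @export
error_bin_probabilities <- function(disto, model) {
  L <- model_length(model)
  if (dim(disto$probs)[1] != L) {
    stop("contract error: distogram L ", dim(disto$probs)[1],
         " != model L ", L)
  }
  mid <- (disto$lower_bounds + disto$upper_bounds) / 2
  dcb <- as.matrix(stats::dist(model$coords_cb))
  out <- array(0, dim = c(L, L, 9L))
  for (k in seq_along(mid)) {
    bin <- matrix(findInterval(mid[k] - dcb, ERROR_BIN_EDGES,
                               left.open = TRUE), L, L)
    for (n in sort(unique(as.integer(bin)))) {
      sel <- bin == n
      out[, , n][sel] <- out[, , n][sel] + disto$probs[, , k][sel]
    }
  }
  structure(list(probs = out, bin_edges = ERROR_BIN_EDGES),
            class = "error_bin_probabilities")
}

#' Contact probability map from reference distograms
#'
#' Per distogram, sums the probabilities of all bins whose midpoint is at
#' most `cutoff`, then averages the resulting maps across distograms.
#'
#' @param distos list of [distogram_prediction()]s.
#' @param cutoff contact distance (A), default 15.
#' @return L x L matrix with entries in \[0,1\].
#' @export
contact_probability_map <- function(distos, cutoff = 15) {
  if (length(distos) == 0L) stop("contract error: empty distogram list")
  maps <- lapply(distos, function(d) {
    mid <- (d$lower_bounds + d$upper_bounds) / 2
    sel <- which(mid <= cutoff)
    apply(d$probs[, , sel, drop = FALSE], c(1, 2), sum)
  })
  Reduce(`+`, maps) / length(maps)
}

#' Binary contact map of a structural model
#'
#' Entry (i,j) is 1 when the Cb-Cb distance is at most `cutoff` (virtual
#' Cb where needed), else 0. The diagonal is 1 (self-contact), so the
#' initial-score aggregation needs no special case.
#'
#' @param model a [protein_model()].
#' @param cutoff contact distance (A), default 15.
#' @return symmetric L x L 0/1 matrix.
#' @export
model_contact_map <- function(model, cutoff = 15) {
  d <- as.matrix(stats::dist(model$coords_cb))
  m <- (d <= cutoff) * 1
  diag(m) <- 1
  unname(m)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

one_hot_sequence <- function(sequence) {
  m <- matrix(0, length(sequence), 20L, dimnames = list(NULL, AA1))
  m[cbind(seq_along(sequence), match(sequence, AA1))] <- 1
  m
}

#' Assemble per-residue node features
#'
#' Reference mode (five references given): columns are the 20-way one-hot
#' sequence encoding, the three z-scored geometric descriptors, the Ca-lDDT
#' of the model against each reference (5 columns) and each reference's own
#' per-residue confidence (5 columns) — width 33. Single-model mode:
#' one-hot, three z-scored descriptors, and the model's self-reported
#' confidence — width 24. Descriptors are standardized within the model;
#' lDDT/confidence columns stay on their native \[0,1\] scale.
#'
#' @param model a [protein_model()].
#' @param descriptors a `geometric_descriptors` from [compute_descriptors()].
#' @param references optional list of exactly five `list(model =, confidence =)`
#'   reference entries (reference mode).
#' @return object of class `node_features`: `matrix` (L x 33 or L x 24) and
#'   `mode` ("reference" or "single").
#' @export
assemble_node_features <- function(model, descriptors, references = NULL) {
  L <- model_length(model)
  oh <- one_hot_sequence(model$sequence)
  desc <- cbind(zscore(descriptors$sasa),
                zscore(descriptors$voronoi_volume),
                zscore(as.numeric(descriptors$buriedness)))
  if (!is.null(references)) {
    if (length(references) != 5L) {
      stop("contract error: reference mode needs exactly 5 references, got ",
           length(references))
    }
    ids <- vapply(seq_along(references), function(i) {
      id <- references[[i]]$source_id
      if (is.null(id)) sprintf("ref%02d", i) else as.character(id)
    }, character(1))
    ord <- order(ids)
    lddt <- vapply(references[ord], function(r) {
      compute_lddt(model, r$model)$per_residue
    }, numeric(L))
    conf <- vapply(references[ord], function(r) {
      normalize_confidence(r$confidence)
    }, numeric(L))
    mat <- cbind(oh, desc, lddt, conf)
    mode <- "reference"
  } else {
    if (any(is.na(model$bfactor))) {
      stop("single-model mode requires self-reported confidence (b-factors)")
    }
    mat <- cbind(oh, desc, model$bfactor)
    mode <- "single"
  }
  dimnames(mat) <- NULL
  structure(list(matrix = mat, mode = mode), class = "node_features")
}

#' Assemble pairwise edge features
#'
#' Reference mode: the five distograms' 9-bin distance-error blocks
#' (grouped by distogram, sorted by `source_id`; 45 channels), the averaged
#' contact probability map (1) and the spherical-harmonic embedding (25) —
#' 71 channels. Single-model mode: the model's binary contact map (1), the
#' protein-language-model attention tensor (120; a zero placeholder when
#' absent) and the harmonics (25) — 146 channels.
#'
#' @param model a [protein_model()].
#' @param harmonics a `spherical_embedding` from [spherical_embedding()].
#' @param distos optional list of exactly five [distogram_prediction()]s.
#' @param attention optional L x L x 120 array.
#' @param contact_cutoff contact distance (A), default 15.
#' @return object of class `edge_features`: `tensor` (L x L x 71 or
#'   L x L x 146), `mode`, and `contact` (the L x L map used by the
#'   initial-score head).
#' @export
assemble_edge_features <- function(model, harmonics, distos = NULL,
                                   attention = NULL, contact_cutoff = 15) {
  L <- model_length(model)
  H <- harmonics$harmonics
  stopifnot(dim(H)[1] == L, dim(H)[2] == L)
  if (!is.null(distos)) {
    if (length(distos) != 5L) {
      stop("contract error: reference mode needs exactly 5 distograms, got ",
           length(distos))
    }
    ids <- vapply(distos, function(d) as.character(d$source_id), character(1))
    distos <- distos[order(ids)]
    blocks <- lapply(distos, function(d) error_bin_probabilities(d, model)$probs)
    contact <- contact_probability_map(distos, cutoff = contact_cutoff)
    tensor <- array(0, dim = c(L, L, 45L + 1L + dim(H)[3]))
    for (i in seq_len(5L)) {
      tensor[, , ((i - 1L) * 9L + 1L):(i * 9L)] <- blocks[[i]]
    }
    tensor[, , 46L] <- contact
    tensor[, , 47L:dim(tensor)[3]] <- H
    mode <- "reference"
  } else {
    contact <- model_contact_map(model, cutoff = contact_cutoff)
    if (is.null(attention)) {
      attention <- array(0, dim = c(L, L, 120L))
    }
    if (!identical(dim(attention), c(L, L, 120L))) {
      stop("contract error: attention tensor must be L x L x 120 with L = ", L)
    }
    tensor <- array(0, dim = c(L, L, 1L + 120L + dim(H)[3]))
    tensor[, , 1L] <- contact
    tensor[, , 2L:121L] <- attention
    tensor[, , 122L:dim(tensor)[3]] <- H
    mode <- "single"
  }
  structure(list(tensor = tensor, mode = mode, contact = contact),
            class = "edge_features")
}

# --- tensor archives -------------------------------------------------------

#' Write / read a distogram archive
#'
#' Array archives are R-native serialized lists; a distogram file holds
#' `probs` (or `logits`), `lower_bounds`, `upper_bounds` and `source_id`.
#'
#' @param disto a [distogram_prediction()].
#' @param path file path.
#' @return `write_distogram` returns `path` invisibly; `read_distogram` a
#'   [distogram_prediction()].
#' @export
write_distogram <- function(disto, path) {
  saveRDS(list(probs = disto$probs, lower_bounds = disto$lower_bounds,
               upper_bounds = disto$upper_bounds, source_id = disto$source_id),
          path)
  invisible(path)
}

#' @rdname write_distogram
#' @export
read_distogram <- function(path) {
  x <- readRDS(path)
  probs <- if (!is.null(x$probs)) x$probs else x$logits
  if (is.null(probs)) stop("format error: no `probs` or `logits` in ", path)
  distogram_prediction(probs, x$lower_bounds, x$upper_bounds,
                       source_id = if (is.null(x$source_id)) basename(path)
                       else x$source_id,
                       logits = is.null(x$probs))
}

#' Read a protein-language-model attention tensor
#'
#' Validates the expected L x L x 120 shape and symmetrizes the tensor over
#' the pair axes as (A + t(A)) / 2.
#'
#' @param path archive written by [write_attention_tensor()].
#' @param expected_L chain length the tensor must match.
#' @return symmetrized L x L x 120 array.
#' @export
read_attention_tensor <- function(path, expected_L) {
  x <- readRDS(path)
  att <- if (is.list(x)) x$attention else x
  if (is.null(att)) stop("format error: no `attention` array in ", path)
  d <- dim(att)
  if (length(d) != 3L || d[1] != expected_L || d[2] != expected_L ||
      d[3] != 120L) {
    stop("format error: attention shape (", paste(d, collapse = ","),
         ") but expected (", expected_L, ",", expected_L, ",120)")
  }
  (att + aperm(att, c(2, 1, 3))) / 2
}

#' @rdname read_attention_tensor
#' @param attention L x L x 120 array to store.
#' @export
write_attention_tensor <- function(attention, path) {
  saveRDS(list(attention = attention), path)
  invisible(path)
}
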