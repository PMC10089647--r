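# The learnable quality-assessment model: a residual 2D stage over pair
# features predicting a 9-bin distance-error classification, an initial
# quality score derived from it through the contact map, and a two-level
# E(n)-equivariant graph network (node-level message passing with
# coordinate updates; edge-level message passing on the line graph) ending
# in per-residue lDDT and pairwise distance-error heads.
#
# Internally, pair tensors (L x L x C) are flattened column-major into
# (L^2 x C) matrices: pair (i, j) lives in row i + (j-1) L, which matches
# as.numeric() of an L x L matrix.

# Per-signed-bin weight with which a unit of error mass counts toward the
# four-threshold lDDT-style score: the central |e|<=0.5 bin passes all four
# thresholds, the open tails none.
LDDT_BIN_WEIGHTS <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)

#' Network configuration
#'
#' @param mode `"reference"` (five reference predictions; 33/71 feature
#'   widths) or `"single"` (self-contained; 24/146).
#' @param hidden hidden width of the graph modules (default 64).
#' @param residual_blocks,residual_channels residual 2D stage size
#'   (default 5 blocks of 32 channels).
#' @param residual_kernel convolution kernel width of the residual stage:
#'   3 (default; sequence-local, as in DeepAccNet-style pair stacks) or 1
#'   (pointwise; makes the whole network permutation-equivariant under
#'   residue relabeling, useful for property testing).
#' @param pair_channels width of the pair embedding passed from the
#'   residual stage to the edge-level module (default 32).
#' @param node_layers,edge_layers number of node-level EGNN layers
#'   (default 4) and edge-level line-graph layers (default 2); edge layers
#'   are interleaved after the early node layers.
#' @param knn_k neighbors in the edge-level line graph (default 3).
#' @param graph_cutoff Ca-Ca distance (A) defining graph edges (default 15).
#' @param seed weight-initialization seed.
#' @return a `network_config` list.
#' @export
network_config <- function(mode = c("reference", "single"), hidden = 64L,
                           residual_blocks = 5L, residual_channels = 32L,
                           residual_kernel = 3L, pair_channels = 32L,
                           node_layers = 4L, edge_layers = 2L, knn_k = 3L,
                           graph_cutoff = 15, seed = 42L) {
  mode <- match.arg(mode)
  stopifnot(residual_kernel %in% c(1L, 3L))
  structure(list(mode = mode, hidden = as.integer(hidden),
                 residual_blocks = as.integer(residual_blocks),
                 residual_channels = as.integer(residual_channels),
                 residual_kernel = as.integer(residual_kernel),
                 pair_channels = as.integer(pair_channels),
                 node_layers = as.integer(node_layers),
                 edge_layers = as.integer(edge_layers),
                 knn_k = as.integer(knn_k), graph_cutoff = graph_cutoff,
                 seed = as.integer(seed)),
            class = "network_config")
}

node_feature_width <- function(mode) if (mode == "reference") 33L else 24L
edge_feature_width <- function(mode) if (mode == "reference") 71L else 146L

# layer schedule: edge layers interleaved after the first node layers
layer_schedule <- function(cfg) {
  sched <- character(0)
  ne <- cfg$edge_layers
  for (l in seq_len(cfg$node_layers)) {
    sched <- c(sched, paste0("node", l))
    if (l <= ne) sched <- c(sched, paste0("edge", l))
  }
  sched
}

#' Initialize a quality-assessment network
#'
#' Creates all parameters with uniform fan-in scaling from the
#' configuration seed. The final layer of every coordinate network is
#' initialized to zero, so an untrained network is the identity on
#' coordinates.
#'
#' @param config a [network_config()].
#' @return object of class `qa_network` with fields `config` and `params`.
#' @export
network_init <- function(config = network_config()) {
  cfg <- config
  nd <- node_feature_width(cfg$mode)
  ed <- edge_feature_width(cfg$mode)
  ch <- cfg$residual_channels
  hid <- cfg$hidden
  ea <- 9L + cfg$pair_channels       # edge attribute width in the graph
  p <- with_seed(cfg$seed, {
    p <- list()
    p <- init_linear(p, "embed", nd, ch)
    p <- init_linear(p, "res_in", 2L * ch + ed, ch)
    ktap <- if (cfg$residual_kernel == 3L) 9L else 1L
    for (b in seq_len(cfg$residual_blocks)) {
      p <- init_linear(p, paste0("block", b, "a"), ktap * ch, ch)
      p <- init_linear(p, paste0("block", b, "b"), ktap * ch, ch)
    }
    p <- init_linear(p, "head_logits", ch, 9L)
    p <- init_linear(p, "head_pair", ch, cfg$pair_channels)
    p <- init_linear(p, "node_in", ch + 1L, hid)
    for (l in seq_len(cfg$node_layers)) {
      p <- init_linear(p, paste0("n", l, "_m1"), 2L * hid + 1L + ea, hid)
      p <- init_linear(p, paste0("n", l, "_m2"), hid, hid)
      p <- init_linear(p, paste0("n", l, "_x1"), hid, hid)
      p <- init_linear(p, paste0("n", l, "_x2"), hid, 1L, zero = TRUE)
      p <- init_linear(p, paste0("n", l, "_h1"), 2L * hid, hid)
      p <- init_linear(p, paste0("n", l, "_h2"), hid, hid)
    }
    for (l in seq_len(cfg$edge_layers)) {
      p <- init_linear(p, paste0("g", l, "_m1"), 2L * ea + 2L, hid)
      p <- init_linear(p, paste0("g", l, "_m2"), hid, hid)
      p <- init_linear(p, paste0("g", l, "_h1"), ea + hid, hid)
      p <- init_linear(p, paste0("g", l, "_h2"), hid, ea)
    }
    p <- init_linear(p, "out1", hid + 2L, hid)
    p <- init_linear(p, "out2", hid, 1L)
    p[["out_skip_W"]] <- matrix(1, 1L, 1L)
    p
  })
  structure(list(config = cfg, params = p), class = "qa_network")
}

#' @export
print.qa_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<qa_network> mode=%s, %d parameters\n", x$config$mode, np))
  invisible(x)
}

# residue graph connectivity (directed edge list) from Ca coordinates
residue_graph_edges <- function(coords_ca, cutoff = 15) {
  d <- as.matrix(stats::dist(coords_ca))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  list(ei = idx[, 1], ej = idx[, 2], dist = d)
}

#' Residue graph for the equivariant network
#'
#' Nodes are residues with their (centered) Ca coordinates; edges connect
#' residue pairs with Ca-Ca distance at most `cutoff`, both directions,
#' no self edges.
#'
#' @param model a [protein_model()].
#' @param cutoff edge distance cutoff (A), default 15.
#' @return list with `ei`, `ej` (directed edge endpoints), `coords`
#'   (centered L x 3), `isolated` (logical per node).
#' @export
residue_graph <- function(model, cutoff = 15) {
  g <- residue_graph_edges(model$coords_ca, cutoff)
  L <- model_length(model)
  list(ei = g$ei, ej = g$ej,
       coords = sweep(model$coords_ca, 2, colMeans(model$coords_ca)),
       isolated = tabulate(g$ei, nbins = L) == 0L)
}

# deterministic k-nearest-neighbor line-graph connectivity over midpoints;
# ties broken by smaller edge-node index
knn_edges <- function(mid, k) {
  nu <- nrow(mid)
  if (nu < 2L) return(list(r = integer(0), s = integer(0)))
  D <- as.matrix(stats::dist(mid))
  r <- integer(0); s <- integer(0)
  for (u in seq_len(nu)) {
    others <- setdiff(seq_len(nu), u)
    o <- others[order(D[u, others], others)]
    nb <- o[seq_len(min(k, length(o)))]
    r <- c(r, rep(u, length(nb)))
    s <- c(s, nb)
  }
  list(r = r, s = s)
}

# ---- tape-level building blocks ------------------------------------------

# residual 2D stage on tape nodes; returns symmetrized logits + embedding
stage_residual_2d <- function(pl, cfg, h0, em, L) {
  i_idx <- rep(seq_len(L), L)
  j_idx <- rep(seq_len(L), each = L)
  tperm <- j_idx + (i_idx - 1L) * L
  pp <- ad_cbind(ad_gather(h0, i_idx), ad_gather(h0, j_idx), em)
  p <- nn_linear(pl, "res_in", pp, act = "relu")
  if (cfg$residual_kernel == 3L) {
    idxc <- conv3x3_indices(L)
    conv <- function(name, x, act = "none") nn_conv3x3(pl, name, x, idxc, act)
  } else {
    conv <- function(name, x, act = "none") nn_linear(pl, name, x, act)
  }
  for (b in seq_len(cfg$residual_blocks)) {
    r <- conv(paste0("block", b, "a"), p, act = "relu")
    r <- conv(paste0("block", b, "b"), r)
    p <- ad_relu(ad_add(p, r))
  }
  logits <- nn_linear(pl, "head_logits", p)
  logits <- ad_cmul(ad_add(logits, ad_gather(logits, tperm)), 0.5)
  emb <- nn_linear(pl, "head_pair", p)
  emb <- ad_cmul(ad_add(emb, ad_gather(emb, tperm)), 0.5)
  list(logits = logits, embedding = emb)
}

# one node-level EGNN layer on tape nodes
stage_node_layer <- function(pl, name, h, x, a, ei, ej, invn) {
  xi <- ad_gather(x, ei); xj <- ad_gather(x, ej)
  dx <- ad_sub(xi, xj)
  d2 <- ad_rowsums(ad_square(dx))
  m <- nn_mlp(pl, paste0(name, "_m"),
              ad_cbind(ad_gather(h, ei), ad_gather(h, ej), d2, a),
              act_out = "relu")
  # scalar coordinate weight, tanh-bounded for optimization stability
  phix <- ad_tanh(nn_linear(pl, paste0(name, "_x2"),
                            ad_relu(nn_linear(pl, paste0(name, "_x1"), m))))
  upd <- ad_scatter(ad_mul(dx, ad_colrep(phix, 3L)), ei, nrow(x$value))
  x_new <- ad_add(x, ad_rowscale(upd, invn))
  mi <- ad_scatter(m, ei, nrow(h$value))
  h_new <- nn_mlp(pl, paste0(name, "_h"), ad_cbind(h, mi))
  list(h = h_new, x = x_new)
}

# one edge-level (line-graph) layer on tape nodes: features updated,
# coordinates (midpoints) always re-derived from node coordinates
stage_edge_layer <- function(pl, name, f, x, und_i, und_j, k) {
  mid <- ad_cmul(ad_add(ad_gather(x, und_i), ad_gather(x, und_j)), 0.5)
  lg <- knn_edges(mid$value, k)
  if (length(lg$r) == 0L) return(f)
  dm <- ad_sub(ad_gather(mid, lg$r), ad_gather(mid, lg$s))
  d2 <- ad_rowsums(ad_square(dm))
  d1 <- ad_sqrt(d2)
  m <- nn_mlp(pl, paste0(name, "_m"),
              ad_cbind(ad_gather(f, lg$r), ad_gather(f, lg$s), d2, d1),
              act_out = "relu")
  magg <- ad_scatter(m, lg$r, nrow(f$value))
  nn_mlp(pl, paste0(name, "_h"), ad_cbind(f, magg))
}

# ---- full forward pass ----------------------------------------------------

#' Run the network forward
#'
#' Executes the full pipeline on assembled features: residual 2D stage,
#' initial score (appended to the node features), alternating node-level /
#' edge-level equivariant layers, and the output heads. Coordinates are
#' centered on the model centroid before entering the network, so
#' translation invariance is exact.
#'
#' @param net a [network_init()] network.
#' @param model the scored [protein_model()].
#' @param node_feats a `node_features` object matching the network mode.
#' @param edge_feats an `edge_features` object matching the network mode.
#' @param labels optional training labels from [quality_labels()]; when
#'   given, the composite loss and parameter gradients can be computed.
#' @param keep_tape keep autodiff internals (for training); off by default.
#' @param loss_weights weights of (ce, mse_lddt, mse_pair_error) in the
#'   composite loss (default `c(1, 5, 1)`).
#' @return a `network_output` list: `initial_error_logits` (L x L x 9),
#'   `initial_score` (L), `final_lddt` (L, in \[0,1\]), `updated_coords`
#'   (L x 3), `final_pair_error` (L x L, A), and `loss` components when
#'   labels were supplied.
#' @export
network_forward <- function(net, model, node_feats, edge_feats,
                            labels = NULL, keep_tape = FALSE,
                            loss_weights = c(1, 5, 1)) {
  cfg <- net$config
  L <- model_length(model)
  if (node_feats$mode != cfg$mode || edge_feats$mode != cfg$mode) {
    stop("contract error: feature mode does not match network mode")
  }
  stopifnot(nrow(node_feats$matrix) == L, dim(edge_feats$tensor)[1] == L)

  tape <- ad_tape()
  pl <- lapply(net$params, function(v) ad_leaf(tape, v))

  xn <- ad_leaf(tape, node_feats$matrix)
  em <- ad_leaf(tape, matrix(edge_feats$tensor, nrow = L * L))
  h0 <- nn_linear(pl, "embed", xn, act = "relu")

  st <- stage_residual_2d(pl, cfg, h0, em, L)
  probs <- ad_softmax_rows(st$logits)

  # initial quality score (contact-weighted lDDT-like expectation)
  cvec <- as.numeric(edge_feats$contact)
  csum <- rowSums(edge_feats$contact)
  if (any(csum <= 0)) {
    warning(sum(csum <= 0), " residue(s) with zero contact weight; ",
            "initial score set to 0 there")
  }
  i_idx <- rep(seq_len(L), L)
  inner <- ad_matmul(probs, ad_leaf(tape, matrix(LDDT_BIN_WEIGHTS, 9L, 1L)))
  ssum <- ad_scatter(ad_rowscale(inner, cvec), i_idx, L)
  score <- ad_rowscale(ssum, ifelse(csum > 0, 1 / csum, 0))

  h <- nn_linear(pl, "node_in", ad_cbind(h0, score), act = "relu")

  # residue graph over centered coordinates
  ctr <- colMeans(model$coords_ca)
  xc <- sweep(model$coords_ca, 2, ctr)
  g <- residue_graph_edges(xc, cfg$graph_cutoff)
  ei <- g$ei; ej <- g$ej
  counts <- tabulate(ei, nbins = L)
  invn <- ifelse(counts > 0, 1 / counts, 0)
  x <- ad_leaf(tape, xc)
  edge_row <- ei + (ej - 1L) * L

  a <- ad_gather(ad_cbind(probs, st$embedding), edge_row)

  sel_und <- which(ei < ej)
  und_i <- ei[sel_und]; und_j <- ej[sel_und]
  und_id <- matrix(0L, L, L)
  und_id[cbind(und_i, und_j)] <- seq_along(sel_und)
  und_id[cbind(und_j, und_i)] <- seq_along(sel_und)
  und_of_dir <- und_id[cbind(ei, ej)]

  nl <- 0L; el <- 0L
  for (step in layer_schedule(cfg)) {
    if (startsWith(step, "node")) {
      nl <- nl + 1L
      upd <- stage_node_layer(pl, paste0("n", nl), h, x, a, ei, ej, invn)
      h <- upd$h; x <- upd$x
    } else {
      el <- el + 1L
      f <- ad_gather(a, sel_und)
      f <- stage_edge_layer(pl, paste0("g", el), f, x, und_i, und_j, cfg$knn_k)
      a <- ad_gather(f, und_of_dir)
    }
  }

  # per-residue geometric evidence for the quality head: how far the
  # equivariant module moved each residue, and how much it corrected the
  # local distance map (both rigid-motion invariant)
  x0 <- ad_leaf(tape, xc)
  disp <- ad_sqrt(ad_rowsums(ad_square(ad_sub(x, x0))))
  de <- ad_sqrt(ad_rowsums(ad_square(ad_sub(ad_gather(x, ei),
                                            ad_gather(x, ej)))))
  derr <- ad_square(ad_cadd(de, -matrix(g$dist[cbind(ei, ej)], ncol = 1L)))
  dcorr <- ad_sqrt(ad_rowscale(ad_scatter(derr, ei, L), invn))
  # the initial score skips through to the quality head in log-odds space:
  # the untrained head starts at the initial estimate and the graph trunk
  # learns a refinement on top of it
  head_logit <- nn_linear(pl, "out2",
                          ad_relu(nn_linear(pl, "out1",
                                            ad_cbind(h, disp, dcorr))))
  skip <- ad_matmul(ad_logit(score), pl[["out_skip_W"]])
  lddt <- ad_sigmoid(ad_add(head_logit, skip))

  # final signed pair error: distance map of updated coords minus initial
  j_idx <- rep(seq_len(L), each = L)
  dfin <- ad_sqrt(ad_rowsums(ad_square(ad_sub(ad_gather(x, i_idx),
                                              ad_gather(x, j_idx)))))
  d0 <- as.numeric(as.matrix(stats::dist(xc)))
  perr <- ad_cadd(dfin, -matrix(d0, ncol = 1L))

  out <- list(
    initial_error_logits = array(st$logits$value, dim = c(L, L, 9L)),
    initial_score = as.numeric(score$value),
    final_lddt = as.numeric(lddt$value),
    updated_coords = sweep(x$value, 2, ctr, "+"),
    final_pair_error = matrix(perr$value, L, L)
  )

  if (!is.null(labels)) {
    ce <- ad_ce_logits(st$logits, as.integer(labels$true_error_bins))
    mse_l <- ad_mean(ad_square(ad_sub(lddt,
                                      ad_leaf(tape, matrix(labels$true_lddt,
                                                           ncol = 1L)))))
    # the distance-error regression is trained on local pairs (model
    # distance within the graph cutoff): a 15-A residue graph carries no
    # information about distant pairs, and local errors are what lDDT sees
    loc <- which(d0 <= cfg$graph_cutoff)
    mse_e <- ad_mean(ad_square(ad_sub(
      ad_gather(perr, loc),
      ad_leaf(tape, matrix(as.numeric(labels$true_pair_error)[loc],
                           ncol = 1L)))))
    total <- ad_add(ad_add(ad_cmul(ce, loss_weights[1]),
                           ad_cmul(mse_l, loss_weights[2])),
                    ad_cmul(mse_e, loss_weights[3]))
    out$loss <- list(total = total$value, ce = ce$value,
                     mse_lddt = mse_l$value, mse_pair_error = mse_e$value)
    if (keep_tape) {
      out$.tape <- tape
      out$.loss_node <- total
      out$.param_nodes <- pl
    }
  }
  class(out) <- "network_output"
  out
}

#' Initial quality score from error-bin probabilities and a contact map
#'
#' For residue n, the contact-weighted mean over partners i of the
#' four-threshold pass fraction implied by the 9-bin signed-error
#' distribution: P(|e| <= t) for t in 0.5, 1, 2, 4 A sums the signed bins
#' wholly inside \[-t, t\], and the four are averaged. The contact-weight
#' normalization keeps the score in \[0,1\]; residues with zero total
#' contact weight score 0 (with a warning).
#'
#' @param error_probs L x L x 9 array of per-pair distributions.
#' @param contact L x L nonnegative weight matrix.
#' @return numeric per-residue score in \[0,1\].
#' @export
initial_quality_score <- function(error_probs, contact) {
  L <- dim(error_probs)[1]
  stopifnot(dim(error_probs)[3] == 9L, all(dim(contact) == c(L, L)))
  inner <- matrix(matrix(error_probs, nrow = L * L) %*% LDDT_BIN_WEIGHTS, L, L)
  csum <- rowSums(contact)
  if (any(csum <= 0)) {
    warning(sum(csum <= 0), " residue(s) with zero contact weight")
  }
  ifelse(csum > 0, rowSums(contact * inner) / csum, 0)
}

#' Residual 2D stage (standalone)
#'
#' Runs only the pair-feature stage of the network: tiled node features and
#' edge features through 5 residual blocks, producing symmetrized 9-class
#' distance-error logits and the pair embedding for the edge-level module.
#'
#' @inheritParams network_forward
#' @return list with `logits` (L x L x 9) and `embedding`
#'   (L x L x pair_channels).
#' @export
residual_2d_stage <- function(net, node_feats, edge_feats) {
  L <- nrow(node_feats$matrix)
  tape <- ad_tape()
  pl <- lapply(net$params, function(v) ad_leaf(tape, v))
  h0 <- nn_linear(pl, "embed", ad_leaf(tape, node_feats$matrix), act = "relu")
  em <- ad_leaf(tape, matrix(edge_feats$tensor, nrow = L * L))
  st <- stage_residual_2d(pl, net$config, h0, em, L)
  list(logits = array(st$logits$value, dim = c(L, L, 9L)),
       embedding = array(st$embedding$value,
                         dim = c(L, L, net$config$pair_channels)))
}

#' One node-level equivariant layer (standalone)
#'
#' Applies a single EGNN layer: messages from node-feature pairs, squared
#' distance and edge attributes; coordinate updates along difference
#' vectors scaled by the coordinate network and averaged over neighbors;
#' node updates from aggregated messages. Isolated nodes keep their
#' coordinates and receive a zero message.
#'
#' @param net a [network_init()] network.
#' @param layer layer index (1-based).
#' @param h L x hidden node feature matrix.
#' @param coords L x 3 coordinates.
#' @param ei,ej directed edge endpoints.
#' @param edge_attr per-edge attribute matrix (one row per directed edge).
#' @return list with updated `h` and `coords`.
#' @export
egnn_node_layer <- function(net, layer, h, coords, ei, ej, edge_attr) {
  L <- nrow(h)
  counts <- tabulate(ei, nbins = L)
  invn <- ifelse(counts > 0, 1 / counts, 0)
  tape <- ad_tape()
  pl <- lapply(net$params, function(v) ad_leaf(tape, v))
  upd <- stage_node_layer(pl, paste0("n", layer),
                          ad_leaf(tape, h), ad_leaf(tape, coords),
                          ad_leaf(tape, edge_attr), ei, ej, invn)
  list(h = upd$h$value, coords = upd$x$value)
}

#' One edge-level line-graph layer (standalone)
#'
#' Edges of the residue graph become line-graph nodes carrying the edge
#' features; their coordinates are the edge midpoints (always derived from
#' the residue coordinates, never updated here); connectivity is k-nearest
#' midpoints with ties broken by smaller index; attributes are midpoint
#' distances. Only features are updated.
#'
#' @param net a [network_init()] network.
#' @param layer layer index (1-based).
#' @param f per-undirected-edge feature matrix.
#' @param coords L x 3 residue coordinates.
#' @param und_i,und_j undirected edge endpoints (i < j).
#' @param k neighbor count; defaults to the network's `knn_k`.
#' @return updated feature matrix, same shape as `f`.
#' @export
edge_level_module <- function(net, layer, f, coords, und_i, und_j,
                              k = net$config$knn_k) {
  tape <- ad_tape()
  pl <- lapply(net$params, function(v) ad_leaf(tape, v))
  out <- stage_edge_layer(pl, paste0("g", layer), ad_leaf(tape, f),
                          ad_leaf(tape, coords), und_i, und_j, k)
  out$value
}

#' Training labels for one decoy against its native structure
#'
#' Per-residue Ca-lDDT, the signed pairwise Ca distance error
#' (d_native - d_model), and the 9-bin class of the signed Cb distance
#' error (the classification target of the residual stage).
#'
#' @param model the decoy [protein_model()].
#' @param native the reference/native [protein_model()].
#' @return list with `true_lddt` (L), `true_pair_error` (L x L) and
#'   `true_error_bins` (L x L integer in 1..9).
#' @export
quality_labels <- function(model, native) {
  L <- model_length(model)
  stopifnot(model_length(native) == L)
  dm_ca <- as.matrix(stats::dist(model$coords_ca))
  dn_ca <- as.matrix(stats::dist(native$coords_ca))
  dm_cb <- as.matrix(stats::dist(model$coords_cb))
  dn_cb <- as.matrix(stats::dist(native$coords_cb))
  bins <- matrix(findInterval(dn_cb - dm_cb, ERROR_BIN_EDGES,
                              left.open = TRUE), L, L)
  list(true_lddt = compute_lddt(model, native)$per_residue,
       true_pair_error = dn_ca - dm_ca,
       true_error_bins = bins)
}

#' Composite training loss
#'
#' Weighted sum of the categorical cross-entropy of the initial 9-bin
#' distance-error classification (weight 1), the MSE of the predicted
#' per-residue lDDT (weight 5) and the MSE of the final pairwise distance
#' error (weight 1).
#'
#' @param output a `network_output` from [network_forward()].
#' @param true_lddt per-residue lDDT labels.
#' @param true_pair_error L x L signed distance-error labels (A).
#' @param true_error_bins L x L integer labels in 1..9.
#' @param weights length-3 weights for (ce, mse_lddt, mse_pair_error);
#'   default `c(1, 5, 1)`.
#' @return list with `total` and components `ce`, `mse_lddt`,
#'   `mse_pair_error`.
#' @export
composite_loss <- function(output, true_lddt, true_pair_error,
                           true_error_bins, weights = c(1, 5, 1)) {
  L <- length(output$final_lddt)
  logits <- matrix(output$initial_error_logits, nrow = L * L)
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  cls <- as.integer(true_error_bins)
  ce <- -mean(log(pmax(p[cbind(seq_len(L * L), cls)], 1e-300)))
  mse_l <- mean((output$final_lddt - true_lddt)^2)
  mse_e <- mean((output$final_pair_error - true_pair_error)^2)
  list(total = weights[1] * ce + weights[2] * mse_l + weights[3] * mse_e,
       ce = ce, mse_lddt = mse_l, mse_pair_error = mse_e)
}

#' Save / load network weights
#'
#' Weights are stored as a single archive containing a format version, the
#' full configuration and the parameter list.
#'
#' @param net a `qa_network`.
#' @param path file path.
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   restored `qa_network`.
#' @export
save_network <- function(net, path) {
  saveRDS(list(format = "qa_network/1", config = unclass(net$config),
               params = net$params), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "qa_network/1")) {
    stop("format error: not a qa_network archive: ", path)
  }
  structure(list(config = structure(x$config, class = "network_config"),
                 params = x$params), class = "qa_network")
}
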