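# End-to-end orchestration: run configuration, long-chain cropping with
# concatenated stitching, the prediction pipeline (read -> descriptors ->
# features -> forward -> write) and SGD training with early stopping.

#' Run configuration
#'
#' Bundles the operating mode, cropping rule, optimizer settings and loss
#' weights. The optimizer defaults are the published training regime (SGD,
#' learning rate 1e-6, momentum 0.9, weight decay 5e-5, 60 epochs, early
#' stopping after 5 non-improving validation epochs, loss weights 5/1/1 for
#' lDDT / initial-error CE / final-error MSE); desk-scale smoke training
#' overrides the learning rate.
#'
#' @param mode `"reference"` or `"single"`.
#' @param crop_threshold chains longer than this are cropped (default 850).
#' @param crop_length maximum segment length (default 800).
#' @param seed RNG / initialization seed.
#' @param learning_rate,momentum,weight_decay SGD settings.
#' @param epochs,patience training length and early-stopping patience.
#' @param loss_weights weights (ce, mse_lddt, mse_pair_error).
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("reference", "single"),
                       crop_threshold = 850L, crop_length = 800L,
                       seed = 42L, learning_rate = 1e-6, momentum = 0.9,
                       weight_decay = 5e-5, epochs = 60L, patience = 5L,
                       loss_weights = c(1, 5, 1)) {
  mode <- match.arg(mode)
  stopifnot(crop_length <= crop_threshold, all(loss_weights > 0))
  structure(list(mode = mode, crop_threshold = as.integer(crop_threshold),
                 crop_length = as.integer(crop_length),
                 seed = as.integer(seed), learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 loss_weights = loss_weights),
            class = "run_config")
}

#' Segment boundaries for long-chain cropping
#'
#' Chains of length at most `threshold` form a single segment. Longer
#' chains are split into ceiling(L / segment) near-equal contiguous
#' segments, each of length at most `segment`, with no overlap (the
#' stitched result is the plain concatenation of segment outputs).
#'
#' @param L chain length.
#' @param threshold crop threshold (default 850).
#' @param segment maximum segment length (default 800).
#' @return list of integer index vectors covering 1..L without overlap.
#' @export
crop_segments <- function(L, threshold = 850L, segment = 800L) {
  if (L <= threshold) return(list(seq_len(L)))
  k <- ceiling(L / segment)
  sizes <- rep(floor(L / k), k)
  extra <- L - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) seq.int(starts[i], ends[i]))
}

#' Predict per-residue quality with cropping and stitching
#'
#' Applies `runner` to the whole model when it fits under the threshold,
#' otherwise to each non-overlapping segment, and concatenates the
#' per-residue outputs in order. No smoothing is applied across segment
#' boundaries.
#'
#' @param model a [protein_model()].
#' @param runner function(sub_model, idx) returning per-residue scores for
#'   the sub-model (`idx` are the original residue indices).
#' @param threshold,segment cropping rule (defaults 850 / 800).
#' @return a [quality_prediction()] of length `model_length(model)`.
#' @export
crop_and_stitch <- function(model, runner, threshold = 850L, segment = 800L) {
  segs <- crop_segments(model_length(model), threshold, segment)
  parts <- lapply(segs, function(idx) {
    sub <- if (length(segs) == 1L) model else subset_model(model, idx)
    as.numeric(runner(sub, idx))
  })
  quality_prediction(unlist(parts))
}

subset_distogram <- function(disto, idx) {
  distogram_prediction(disto$probs[idx, idx, , drop = FALSE],
                       disto$lower_bounds, disto$upper_bounds,
                       source_id = disto$source_id)
}

#' Assemble features and labels for one model
#'
#' Runs descriptors, spherical embedding and the mode-appropriate feature
#' assembly; optionally computes training labels against a native.
#'
#' @param model the scored [protein_model()].
#' @param references optional list of 5 reference entries
#'   (`model`, `distogram`, `confidence`, `source_id`) for reference mode.
#' @param attention optional L x L x 120 array for single-model mode.
#' @param native optional native structure; adds `labels`.
#' @return list with `model`, `node_features`, `edge_features`, `labels`.
#' @export
prepare_sample <- function(model, references = NULL, attention = NULL,
                           native = NULL) {
  desc <- compute_descriptors(model)
  emb <- spherical_embedding(model)
  if (!is.null(references)) {
    nf <- assemble_node_features(model, desc, references = references)
    ef <- assemble_edge_features(model, emb,
                                 distos = lapply(references, `[[`, "distogram"))
  } else {
    nf <- assemble_node_features(model, desc)
    ef <- assemble_edge_features(model, emb, attention = attention)
  }
  list(model = model, node_features = nf, edge_features = ef,
       labels = if (is.null(native)) NULL else quality_labels(model, native))
}

#' Full prediction pipeline for one model
#'
#' Features are assembled per segment (after cropping when the chain
#' exceeds the threshold) and the network produces per-residue lDDT; the
#' pairwise-error matrix is attached for single-segment runs.
#'
#' @param net a trained (or freshly initialized) `qa_network`.
#' @param model the scored [protein_model()].
#' @param references,attention mode-appropriate extra inputs (see
#'   [prepare_sample()]).
#' @param config a [run_config()]; governs cropping.
#' @return a [quality_prediction()].
#' @export
predict_quality <- function(net, model, references = NULL, attention = NULL,
                            config = run_config(mode = net$config$mode)) {
  if (net$config$mode == "reference" && is.null(references)) {
    stop("usage error: reference mode requires 5 reference predictions")
  }
  L <- model_length(model)
  last_output <- NULL
  runner <- function(sub, idx) {
    refs <- references
    att <- attention
    if (length(idx) < L) {
      if (!is.null(refs)) {
        refs <- lapply(refs, function(r) {
          list(model = subset_model(r$model, idx),
               distogram = subset_distogram(r$distogram, idx),
               confidence = r$confidence[idx], source_id = r$source_id)
        })
      }
      if (!is.null(att)) att <- att[idx, idx, , drop = FALSE]
    }
    smp <- prepare_sample(sub, references = refs, attention = att)
    out <- network_forward(net, sub, smp$node_features, smp$edge_features)
    last_output <<- out
    out$final_lddt
  }
  pred <- crop_and_stitch(model, runner, config$crop_threshold,
                          config$crop_length)
  if (length(crop_segments(L, config$crop_threshold,
                           config$crop_length)) == 1L) {
    pred$pairwise_error <- last_output$final_pair_error
  }
  pred
}

# one optimization step on a prepared sample; returns loss components
train_step <- function(net, sample, opt_state, lr, momentum, weight_decay,
                       clip_norm = 10, optimizer = "sgd") {
  out <- network_forward(net, sample$model, sample$node_features,
                         sample$edge_features, labels = sample$labels,
                         keep_tape = TRUE)
  ad_backward(out$.tape, out$.loss_node)
  grads <- lapply(out$.param_nodes, function(nd) nd$grad)
  upd <- if (optimizer == "adam") {
    adam_step(net$params, grads, opt_state, lr = lr,
              weight_decay = weight_decay, clip_norm = clip_norm)
  } else {
    sgd_step(net$params, grads, opt_state, lr = lr,
             momentum = momentum, weight_decay = weight_decay,
             clip_norm = clip_norm)
  }
  net$params <- upd$params
  list(net = net, state = upd$state, loss = out$loss)
}

target_samples <- function(target, mode) {
  lapply(target$decoys, function(d) {
    if (mode == "reference") {
      prepare_sample(d$model, references = target$references,
                     native = target$native)
    } else {
      prepare_sample(d$model, attention = target$attention,
                     native = target$native)
    }
  })
}

#' Train the network on synthetic targets
#'
#' SGD (momentum, weight decay) over all decoys of all training targets,
#' batch size 1, with per-epoch validation loss and early stopping after
#' `patience` consecutive epochs without improvement. Targets are split
#' 80/20 into train/validation by target unless a validation set is given;
#' with a single target (overfit smoke setting) validation = training.
#'
#' @param net a `qa_network` (freshly initialized or loaded).
#' @param targets list of [make_target()] bundles.
#' @param config a [run_config()] (optimizer settings, seed).
#' @param epochs override for `config$epochs`.
#' @param learning_rate override for `config$learning_rate`.
#' @param optimizer `"sgd"` (default, the published regime) or `"adam"`.
#' @param validation optional list of targets used for validation.
#' @param opt_state optimizer state from a previous run (resume training);
#'   default fresh.
#' @param verbose print per-epoch losses.
#' @return list with `net` (best-validation weights), `final_net` (weights
#'   at the last epoch, for resuming), `opt_state`, `history`
#'   (data.frame: epoch, split, total, ce, mse_lddt, mse_pair_error),
#'   `best_epoch`.
#' @export
train_network <- function(net, targets, config = run_config(mode = net$config$mode),
                          epochs = config$epochs,
                          learning_rate = config$learning_rate,
                          optimizer = "sgd",
                          validation = NULL, opt_state = NULL,
                          verbose = FALSE) {
  if (length(targets) == 0L) stop("usage error: empty training set")
  if (is.null(validation)) {
    if (length(targets) >= 5L) {
      ntr <- floor(0.8 * length(targets))
      validation <- targets[(ntr + 1L):length(targets)]
      targets <- targets[seq_len(ntr)]
    } else {
      validation <- targets
    }
  }
  mode <- net$config$mode
  train_s <- unlist(lapply(targets, target_samples, mode = mode),
                    recursive = FALSE)
  val_s <- unlist(lapply(validation, target_samples, mode = mode),
                  recursive = FALSE)
  if (is.null(opt_state)) {
    opt_state <- if (optimizer == "adam") adam_state() else sgd_state()
  }
  best <- Inf; best_params <- net$params; best_epoch <- 0L
  bad <- 0L
  hist <- list()
  for (ep in seq_len(epochs)) {
    tr_losses <- matrix(0, 0, 4)
    for (s in train_s) {
      st <- train_step(net, s, opt_state, lr = learning_rate,
                       momentum = config$momentum,
                       weight_decay = config$weight_decay,
                       optimizer = optimizer)
      net <- st$net; opt_state <- st$state
      tr_losses <- rbind(tr_losses, unlist(st$loss))
    }
    vl <- vapply(val_s, function(s) {
      out <- network_forward(net, s$model, s$node_features, s$edge_features,
                             labels = s$labels)
      unlist(out$loss)
    }, numeric(4))
    trm <- colMeans(tr_losses); vlm <- rowMeans(vl)
    hist[[length(hist) + 1L]] <- data.frame(
      epoch = ep, split = c("train", "val"),
      total = c(trm[1], vlm[1]), ce = c(trm[2], vlm[2]),
      mse_lddt = c(trm[3], vlm[3]), mse_pair_error = c(trm[4], vlm[4])
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, trm[1], vlm[1]))
    }
    if (vlm[1] < best - 1e-12) {
      best <- vlm[1]; best_params <- net$params; best_epoch <- ep; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  final_net <- net
  net$params <- best_params
  list(net = net, final_net = final_net, opt_state = opt_state,
       history = do.call(rbind, hist), best_epoch = best_epoch)
}

#' Overfit smoke training on one target
#'
#' Runs a fixed number of SGD steps cycling over a single target's decoys
#' (train = validation), returning losses before/after and the Pearson
#' correlation between predicted and true per-residue lDDT pooled across
#' the decoys. A parameter-recovery-style check of the optimization path,
#' not a claim about generalization.
#'
#' @param target a [make_target()] bundle.
#' @param steps number of optimizer steps (default 200).
#' @param mode network mode (default `"single"`).
#' @param learning_rate desk-scale smoke learning rate (default 1e-3).
#' @param optimizer `"adam"` (default; per-parameter scaling copes with the
#'   heterogeneous loss-term gradient scales within a small step budget) or
#'   `"sgd"` (the full-scale training regime).
#' @param seed initialization seed.
#' @return list with `loss_first`, `loss_last`, `reduction` (fractional),
#'   `pearson`, `net`.
#' @export
overfit_smoke <- function(target, steps = 200L, mode = "single",
                          learning_rate = 1e-3, optimizer = "adam",
                          seed = 7L) {
  net <- network_init(network_config(mode = mode, seed = seed))
  cfg <- run_config(mode = mode, seed = seed)
  samples <- target_samples(target, mode)
  mean_loss <- function(n) {
    mean(vapply(samples, function(s) {
      network_forward(n, s$model, s$node_features, s$edge_features,
                      labels = s$labels)$loss$total
    }, numeric(1)))
  }
  loss_first <- mean_loss(net)
  opt_state <- if (optimizer == "adam") adam_state() else sgd_state()
  k <- 0L
  while (k < steps) {
    for (s in samples) {
      k <- k + 1L
      if (k > steps) break
      st <- train_step(net, s, opt_state, lr = learning_rate,
                       momentum = cfg$momentum,
                       weight_decay = cfg$weight_decay,
                       optimizer = optimizer)
      net <- st$net; opt_state <- st$state
    }
  }
  loss_last <- mean_loss(net)
  pred <- unlist(lapply(samples, function(s) {
    network_forward(net, s$model, s$node_features,
                    s$edge_features)$final_lddt
  }))
  truth <- unlist(lapply(target$decoys, `[[`, "true_lddt"))
  list(loss_first = loss_first, loss_last = loss_last,
       reduction = 1 - loss_last / loss_first,
       pearson = stats::cor(pred, truth), net = net)
}
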