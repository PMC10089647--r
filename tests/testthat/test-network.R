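single_sample <- function(L = 10, seed = 3, decoy = 2) {
  tgt <- make_target(L, seed = seed)
  list(tgt = tgt,
       smp = prepare_sample(tgt$decoys[[decoy]]$model,
                            attention = tgt$attention,
                            native = tgt$native))
}

test_that("residual 2D stage: 9 logit channels, symmetric, permutation-equivariant", {
  x <- single_sample(10, seed = 13)
  net <- network_init(network_config(mode = "single", seed = 5))
  st <- residual_2d_stage(net, x$smp$node_features, x$smp$edge_features)
  expect_equal(dim(st$logits), c(10L, 10L, 9L))
  expect_lt(max(abs(st$logits - aperm(st$logits, c(2, 1, 3)))), 1e-12)
  expect_lt(max(abs(st$embedding - aperm(st$embedding, c(2, 1, 3)))), 1e-12)

  # the default 3x3 stage is sequence-local by design; with a pointwise
  # kernel the stage is exactly permutation-equivariant
  net1 <- network_init(network_config(mode = "single", residual_kernel = 1L,
                                      seed = 5))
  st1 <- residual_2d_stage(net1, x$smp$node_features, x$smp$edge_features)
  set.seed(8)
  perm <- sample(10)
  nfp <- x$smp$node_features
  nfp$matrix <- nfp$matrix[perm, , drop = FALSE]
  efp <- x$smp$edge_features
  efp$tensor <- efp$tensor[perm, perm, , drop = FALSE]
  stp <- residual_2d_stage(net1, nfp, efp)
  expect_lt(max(abs(stp$logits - st1$logits[perm, perm, ])), 1e-5)
})

test_that("full forward pass is permutation-equivariant with a pointwise stage", {
  x <- single_sample(10, seed = 41)
  net <- network_init(network_config(mode = "single", residual_kernel = 1L,
                                     seed = 13))
  base <- network_forward(net, x$smp$model, x$smp$node_features,
                          x$smp$edge_features)
  set.seed(14)
  perm <- sample(10)
  mp <- subset_model(x$smp$model, perm)
  nfp <- x$smp$node_features
  nfp$matrix <- nfp$matrix[perm, , drop = FALSE]
  efp <- x$smp$edge_features
  efp$tensor <- efp$tensor[perm, perm, , drop = FALSE]
  efp$contact <- efp$contact[perm, perm]
  got <- network_forward(net, mp, nfp, efp)
  expect_lt(max(abs(got$final_lddt - base$final_lddt[perm])), 1e-5)
  expect_lt(max(abs(got$final_pair_error - base$final_pair_error[perm, perm])),
            1e-5)
})

test_that("initial score: closed-form extremes and brute-force equality", {
  L <- 5
  set.seed(2)
  contact <- matrix(runif(L * L), L, L); contact <- (contact + t(contact)) / 2
  central <- array(0, c(L, L, 9)); central[, , 5] <- 1
  tails <- array(0, c(L, L, 9)); tails[, , 1] <- 0.5; tails[, , 9] <- 0.5
  expect_equal(initial_quality_score(central, contact), rep(1, L))
  expect_equal(initial_quality_score(tails, contact), rep(0, L))

  p <- array(runif(L * L * 9), c(L, L, 9))
  p <- sweep(p, c(1, 2), apply(p, c(1, 2), sum), "/")
  expect_lt(max(abs(initial_quality_score(p, contact) -
                      initial_score_oracle(p, contact))), 1e-12)
  expect_warning(initial_quality_score(p, matrix(0, L, L)), "zero contact")
})

test_that("node-level EGNN layer: identity coordinates at zero init, equivariance, relabeling", {
  x <- single_sample(10, seed = 17)
  net <- network_init(network_config(mode = "single", seed = 6))
  L <- 10
  coords <- sweep(x$smp$model$coords_ca, 2, colMeans(x$smp$model$coords_ca))
  g <- enqar:::residue_graph_edges(coords, 15)
  set.seed(4)
  h <- matrix(rnorm(L * net$config$hidden), L)
  a <- matrix(rnorm(length(g$ei) * 41), length(g$ei))

  # freshly initialized coordinate network outputs zero -> coords unchanged
  out <- egnn_node_layer(net, 1, h, coords, g$ei, g$ej, a)
  expect_identical(out$coords, coords)

  # make the coordinate update nonzero, then check E(3) equivariance
  net$params[["n1_x2_W"]][] <- rnorm(length(net$params[["n1_x2_W"]]), sd = 0.3)
  base <- egnn_node_layer(net, 1, h, coords, g$ei, g$ej, a)
  for (k in 1:20) {
    R <- rand_rotation(); tr <- rnorm(3, sd = 8)
    rot <- sweep(coords %*% t(R), 2, tr, "+")
    got <- egnn_node_layer(net, 1, h, rot, g$ei, g$ej, a)
    expect_lt(max(abs(got$h - base$h)), 1e-4)
    expect_lt(max(abs(got$coords - sweep(base$coords %*% t(R), 2, tr, "+"))),
              1e-4)
  }

  # node relabeling: outputs permute consistently
  perm <- sample(L)
  inv <- order(perm)
  ei_p <- inv[g$ei]; ej_p <- inv[g$ej]
  got <- egnn_node_layer(net, 1, h[perm, ], coords[perm, ], ei_p, ej_p, a)
  expect_lt(max(abs(got$h - base$h[perm, ])), 1e-5)
  expect_lt(max(abs(got$coords - base$coords[perm, ])), 1e-5)
})

test_that("edge-level module: line-graph structure and kNN oracle", {
  # 3-residue path: 2 undirected edges, midpoints are endpoint means
  ca <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  mid <- rbind(c(3, 0, 0), c(9, 0, 0))
  lg <- enqar:::knn_edges(mid, 3)
  expect_equal(sort(unique(lg$r)), 1:2)
  expect_equal(lg$s[lg$r == 1], 2L)
  expect_equal(lg$s[lg$r == 2], 1L)

  # k >= available neighbors -> fully connected
  set.seed(5)
  mids <- matrix(runif(12), 4, 3)
  lg2 <- enqar:::knn_edges(mids, 10)
  expect_equal(length(lg2$r), 4 * 3)

  # brute-force kNN with the same tie rule (distance, then smaller index)
  set.seed(6)
  mids <- matrix(runif(30, 0, 5), 10, 3)
  k <- 3
  lg3 <- enqar:::knn_edges(mids, k)
  D <- as.matrix(dist(mids))
  for (u in 1:10) {
    others <- setdiff(1:10, u)
    want <- others[order(D[u, others], others)][1:k]
    expect_equal(sort(lg3$s[lg3$r == u]), sort(want))
  }

  # feature update keeps shape and runs on a real graph
  x <- single_sample(10, seed = 19)
  net <- network_init(network_config(mode = "single", seed = 2))
  coords <- sweep(x$smp$model$coords_ca, 2, colMeans(x$smp$model$coords_ca))
  g <- enqar:::residue_graph_edges(coords, 15)
  sel <- which(g$ei < g$ej)
  f <- matrix(rnorm(length(sel) * 41), length(sel))
  f2 <- edge_level_module(net, 1, f, coords, g$ei[sel], g$ej[sel])
  expect_equal(dim(f2), dim(f))
  expect_false(isTRUE(all.equal(f, f2)))
})

test_that("forward pass: bounded outputs, determinism, graph contracts", {
  x <- single_sample(10, seed = 23)
  net <- network_init(network_config(mode = "single", seed = 11))
  out <- network_forward(net, x$smp$model, x$smp$node_features,
                         x$smp$edge_features)
  L <- 10
  expect_length(out$final_lddt, L)
  expect_true(all(out$final_lddt >= 0 & out$final_lddt <= 1))
  expect_equal(dim(out$initial_error_logits), c(L, L, 9L))
  expect_equal(dim(out$final_pair_error), c(L, L))
  expect_true(all(abs(diag(out$final_pair_error)) < 1e-5))
  expect_true(all(out$initial_score >= 0 & out$initial_score <= 1))

  net2 <- network_init(network_config(mode = "single", seed = 11))
  out2 <- network_forward(net2, x$smp$model, x$smp$node_features,
                          x$smp$edge_features)
  expect_identical(out$final_lddt, out2$final_lddt)
  expect_identical(out$final_pair_error, out2$final_pair_error)

  wrong <- network_init(network_config(mode = "reference", seed = 1))
  expect_error(network_forward(wrong, x$smp$model, x$smp$node_features,
                               x$smp$edge_features), "mode")

  rg <- residue_graph(x$smp$model)
  expect_true(all(rg$ei != rg$ej))
  key <- paste(rg$ei, rg$ej); rev_key <- paste(rg$ej, rg$ei)
  expect_true(all(rev_key %in% key))
})

test_that("composite loss: zero components, uniform-logits closed form, recomposition", {
  x <- single_sample(10, seed = 29)
  net <- network_init(network_config(mode = "single", seed = 3))
  out <- network_forward(net, x$smp$model, x$smp$node_features,
                         x$smp$edge_features)
  lb <- x$smp$labels

  perfect <- out
  perfect$final_lddt <- lb$true_lddt
  perfect$final_pair_error <- lb$true_pair_error
  cl <- composite_loss(perfect, lb$true_lddt, lb$true_pair_error,
                       lb$true_error_bins)
  expect_equal(cl$mse_lddt, 0)
  expect_equal(cl$mse_pair_error, 0)

  uo <- perfect
  uo$initial_error_logits <- array(0, dim = c(10, 10, 9))
  cu <- composite_loss(uo, lb$true_lddt, lb$true_pair_error,
                       lb$true_error_bins)
  expect_equal(cu$ce, log(9), tolerance = 1e-12)

  cr <- composite_loss(out, lb$true_lddt, lb$true_pair_error,
                       lb$true_error_bins, weights = c(1, 5, 1))
  expect_lt(abs(cr$total - (cr$ce + 5 * cr$mse_lddt + cr$mse_pair_error)),
            1e-10)
})

test_that("network weights archive round-trips", {
  net <- network_init(network_config(mode = "single", seed = 31))
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  expect_identical(net2$params, net$params)
  expect_equal(net2$config$mode, "single")
  x <- single_sample(10, seed = 37)
  o1 <- network_forward(net, x$smp$model, x$smp$node_features,
                        x$smp$edge_features)
  o2 <- network_forward(net2, x$smp$model, x$smp$node_features,
                        x$smp$edge_features)
  expect_identical(o1$final_lddt, o2$final_lddt)
  saveRDS(list(format = "other"), f)
  expect_error(load_network(f), "format")
})
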