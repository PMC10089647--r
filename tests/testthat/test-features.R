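make_uniform_disto <- function(L) {
  distogram_prediction(array(1 / 64, dim = c(L, L, 64)), source_id = "u")
}

point_mass_disto <- function(L, bin) {
  p <- array(0, dim = c(L, L, 64))
  p[, , bin] <- 1
  distogram_prediction(p, source_id = sprintf("pm%02d", bin))
}

test_that("distogram container normalizes, symmetrizes and accepts logits", {
  set.seed(3)
  lg <- array(rnorm(5 * 5 * 64), dim = c(5, 5, 64))
  d <- distogram_prediction(lg, logits = TRUE, source_id = "lg")
  s <- apply(d$probs, c(1, 2), sum)
  expect_lt(max(abs(s - 1)), 1e-9)
  expect_lt(max(abs(d$probs - aperm(d$probs, c(2, 1, 3)))), 1e-12)
  expect_error(distogram_prediction(array(1, c(3, 3, 2)),
                                    lower_bounds = c(2, 1),
                                    upper_bounds = c(3, 4)), "increasing")
  b <- distogram_bins()
  expect_length(b$mid, 64L)
  expect_true(all(diff(b$lower) > 0) && all(diff(b$upper) > 0))
})

test_that("error-bin probabilities conserve mass and match the oracle", {
  nat <- make_native(6, seed = 21)
  u <- make_uniform_disto(6)
  eb <- error_bin_probabilities(u, nat)
  expect_lt(max(abs(apply(eb$probs, c(1, 2), sum) - 1)), 1e-6)

  # point mass on the bin nearest a pair's distance -> central bin
  dcb <- as.matrix(dist(nat$coords_cb))
  mid <- distogram_bins()$mid
  k <- which.min(abs(mid - dcb[1, 2]))
  eb2 <- error_bin_probabilities(point_mass_disto(6, k), nat)
  expect_equal(eb2$probs[1, 2, 5], 1)

  set.seed(9)
  dr <- distogram_prediction(array(runif(6 * 6 * 64), dim = c(6, 6, 64)),
                             logits = FALSE, source_id = "r")
  expect_lt(max(abs(error_bin_probabilities(dr, nat)$probs -
                      error_bin_oracle(dr, nat))), 1e-12)
  expect_error(error_bin_probabilities(make_uniform_disto(5), nat), "contract")
})

test_that("contact probability map sums sub-cutoff mass and averages", {
  mid <- distogram_bins()$mid
  k3 <- which.min(abs(mid - 3)); k20 <- which.min(abs(mid - 20))
  expect_true(mid[k3] <= 15 && mid[k20] > 15)
  c3 <- contact_probability_map(list(point_mass_disto(4, k3)))
  c20 <- contact_probability_map(list(point_mass_disto(4, k20)))
  expect_true(all(c3 == 1))
  expect_true(all(c20 == 0))

  set.seed(4)
  distos <- lapply(1:5, function(i) {
    distogram_prediction(array(runif(4 * 4 * 64), dim = c(4, 4, 64)),
                         source_id = paste0("d", i))
  })
  avg <- contact_probability_map(distos)
  ind <- lapply(distos, function(d) contact_probability_map(list(d)))
  expect_lt(max(abs(avg - Reduce(`+`, ind) / 5)), 1e-12)
  expect_error(contact_probability_map(list()), "contract")
})

test_that("model contact map straddles the cutoff and is symmetric", {
  near <- model_from_ca(rbind(c(0, 0, 0), c(14.9, 0, 0)))
  far <- model_from_ca(rbind(c(0, 0, 0), c(15.1, 0, 0)))
  # contact uses Cb distances; shift Cb to the stated separations
  near$coords_cb <- rbind(c(0, 0, 0), c(14.9, 0, 0))
  far$coords_cb <- rbind(c(0, 0, 0), c(15.1, 0, 0))
  expect_equal(model_contact_map(near)[1, 2], 1)
  expect_equal(model_contact_map(far)[1, 2], 0)

  dec <- make_decoy(make_native(12, seed = 2), 2, seed = 8)$model
  cm <- model_contact_map(dec)
  expect_identical(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  d <- as.matrix(dist(dec$coords_cb))
  naive <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) naive[i, j] <- as.numeric(d[i, j] <= 15)
  diag(naive) <- 1
  expect_identical(cm, naive)
})

test_that("node features have the documented widths and content", {
  tgt <- make_target(12, seed = 5)
  dec <- tgt$decoys[[2]]$model
  desc <- compute_descriptors(dec)

  nf_ref <- assemble_node_features(dec, desc, references = tgt$references)
  expect_equal(dim(nf_ref$matrix), c(12L, 33L))
  expect_equal(nf_ref$mode, "reference")
  expect_true(all(rowSums(nf_ref$matrix[, 1:20]) == 1))

  nf_one <- assemble_node_features(dec, desc)
  expect_equal(dim(nf_one$matrix), c(12L, 24L))
  expect_equal(nf_one$mode, "single")

  # model identical to every reference -> all five lDDT columns are 1
  self_refs <- lapply(1:5, function(i) {
    list(model = dec, confidence = rep(1, 12), source_id = paste0("s", i))
  })
  nf_self <- assemble_node_features(dec, desc, references = self_refs)
  expect_true(all(abs(nf_self$matrix[, 24:28] - 1) < 1e-12))

  expect_error(assemble_node_features(dec, desc,
                                      references = tgt$references[1:4]),
               "contract")
})

test_that("edge features have the documented channel structure", {
  tgt <- make_target(10, seed = 6)
  dec <- tgt$decoys[[1]]$model
  emb <- spherical_embedding(dec)

  ef <- assemble_edge_features(dec, emb,
                               distos = lapply(tgt$references, `[[`,
                                               "distogram"))
  expect_equal(dim(ef$tensor)[3], 71L)
  # each distogram's 9-channel group is a distribution per pair
  for (g in 0:4) {
    s <- apply(ef$tensor[, , (g * 9 + 1):(g * 9 + 9)], c(1, 2), sum)
    expect_lt(max(abs(s - 1)), 1e-6)
  }
  expect_true(all(ef$tensor[, , 46] >= 0 & ef$tensor[, , 46] <= 1))
  expect_lt(max(abs(ef$tensor[, , 47:71] - emb$harmonics)), 1e-12)

  ef1 <- assemble_edge_features(dec, emb, attention = tgt$attention)
  expect_equal(dim(ef1$tensor)[3], 146L)
  ef0 <- assemble_edge_features(dec, emb)   # zero attention placeholder
  expect_equal(dim(ef0$tensor)[3], 146L)
  expect_true(all(ef0$tensor[, , 2:121] == 0))
  expect_lt(max(abs(ef0$tensor[, , 122:146] - emb$harmonics)), 1e-12)

  expect_error(assemble_edge_features(dec, emb,
                                      distos = list(tgt$references[[1]]$distogram)),
               "contract")
})

test_that("tensor archives round-trip, validate shape and symmetrize", {
  att <- make_attention(7, seed = 3)
  f <- tempfile(fileext = ".rds")
  write_attention_tensor(att, f)
  expect_identical(read_attention_tensor(f, 7L), att)  # already symmetric
  expect_error(read_attention_tensor(f, 9L), "format")

  asym <- array(runif(7 * 7 * 120), dim = c(7, 7, 120))
  write_attention_tensor(asym, f)
  got <- read_attention_tensor(f, 7L)
  expect_lt(max(abs(got - aperm(got, c(2, 1, 3)))), 1e-15)

  d <- make_distogram(make_native(6, seed = 2), concentration = 2, seed = 1)
  fd <- tempfile(fileext = ".rds")
  write_distogram(d, fd)
  d2 <- read_distogram(fd)
  expect_equal(d2$probs, d$probs, tolerance = 1e-12)
  expect_identical(d2$source_id, d$source_id)
})
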