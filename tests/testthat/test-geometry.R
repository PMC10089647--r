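test_that("local frames follow the stated axis construction", {
  m <- protein_model(
    sequence = c("A", "A"),
    coords_n = rbind(c(1, 0, 0), c(11, 0, 0)),
    coords_ca = rbind(c(0, 0, 0), c(10, 0, 0)),
    coords_c = rbind(c(0, 1, 0), c(10, 1, 0))
  )
  fr <- build_local_frames(m)[[1]]
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-12)
})

test_that("frames are orthonormal, right-handed and rotation-equivariant", {
  dec <- make_decoy(make_native(15, seed = 2), 1.5, seed = 9)$model
  frames <- build_local_frames(dec)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    M <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-6)
    expect_equal(det(M), 1, tolerance = 1e-6)
    # y-axis oriented toward the Ca->C direction
    expect_gt(sum(fr$y_axis * (dec$coords_c[i, ] - dec$coords_ca[i, ])), 0)
  }
  set.seed(17)
  for (k in 1:20) {
    R <- rand_rotation(); tr <- rnorm(3, sd = 10)
    f2 <- build_local_frames(transform_model(dec, R, tr))
    for (i in seq_along(frames)) {
      for (ax in c("x_axis", "y_axis", "z_axis")) {
        expect_lt(max(abs(f2[[i]][[ax]] - as.numeric(R %*% frames[[i]][[ax]]))),
                  1e-6)
      }
    }
  }
})

test_that("spherical angles use the polar-from-z, azimuth-from-x convention", {
  # residue 1's frame is axis-aligned by construction
  mk <- function(nbr) protein_model(
    sequence = c("A", "A"),
    coords_n = rbind(c(1, 0, 0), nbr + c(1, 0, 0)),
    coords_ca = rbind(c(0, 0, 0), nbr),
    coords_c = rbind(c(0, 1, 0), nbr + c(0, 1, 0))
  )
  m <- mk(c(0, 0, 5))
  ang <- spherical_angles(build_local_frames(m), m)
  expect_equal(ang$theta[1, 2], 0, tolerance = 1e-12)
  expect_equal(ang$radius[1, 2], 5, tolerance = 1e-12)
  m <- mk(c(5, 0, 0))
  ang <- spherical_angles(build_local_frames(m), m)
  expect_equal(ang$theta[1, 2], pi / 2, tolerance = 1e-12)
  expect_equal(ang$phi[1, 2], 0, tolerance = 1e-12)
  expect_equal(ang$theta[1, 1], 0)  # diagonal convention
})

test_that("angles, radius and harmonics are invariant under rigid motions", {
  dec <- make_decoy(make_native(12, seed = 4), 2, seed = 3)$model
  e1 <- spherical_embedding(dec)
  set.seed(23)
  for (k in 1:5) {
    e2 <- spherical_embedding(transform_model(dec, rand_rotation(),
                                              rnorm(3, sd = 30)))
    expect_lt(max(abs(e1$theta - e2$theta)), 1e-6)
    expect_lt(max(abs(e1$phi - e2$phi)), 1e-6)
    expect_lt(max(abs(e1$radius - e2$radius)), 1e-6)
    expect_lt(max(abs(e1$harmonics - e2$harmonics)), 1e-6)
  }
  expect_lt(max(abs(e1$radius - t(e1$radius))), 1e-12)
  expect_equal(dim(e1$harmonics)[3], 25L)
})

test_that("real spherical harmonics match the explicit table oracle", {
  set.seed(5)
  th <- runif(500, 0, pi); ph <- runif(500, -pi, pi)
  H <- matrix(real_spherical_harmonics(matrix(th), matrix(ph)), 500, 25)
  O <- t(vapply(seq_len(500), function(i) sh_table_oracle(th[i], ph[i]),
                numeric(25)))
  expect_lt(max(abs(H - O)), 1e-8)
  expect_true(all(abs(H[, 1] - 1 / (2 * sqrt(pi))) < 1e-12))
  expect_error(real_spherical_harmonics(matrix(th), matrix(ph), -1),
               "contract")
})

test_that("harmonics satisfy the addition theorem for every degree", {
  set.seed(6)
  th <- runif(1000, 0, pi); ph <- runif(1000, -pi, pi)
  H <- matrix(real_spherical_harmonics(matrix(th), matrix(ph)), 1000, 25)
  for (l in 0:4) {
    idx <- (l^2 + 1):((l + 1)^2)
    expect_lt(max(abs(rowSums(H[, idx, drop = FALSE]^2) -
                        (2 * l + 1) / (4 * pi))), 1e-8)
  }
})

test_that("lDDT: identity scores 1, bounded, and asymmetric in its arguments", {
  nat <- make_native(10, seed = 7)
  expect_equal(compute_lddt(nat, nat)$per_residue, rep(1, 10))
  dec <- make_decoy(nat, 2, seed = 1)$model
  r <- compute_lddt(dec, nat)
  expect_true(all(r$per_residue >= 0 & r$per_residue <= 1))
  expect_equal(r$global, mean(r$per_residue))
  # inclusion set follows the reference: swapping arguments changes it
  ca_ref <- rbind(c(0, 0, 0), c(4, 0, 0), c(20, 0, 0))
  ca_mod <- rbind(c(0, 0, 0), c(4, 0, 0), c(12, 0, 0))
  a <- compute_lddt(model_from_ca(ca_mod), model_from_ca(ca_ref))
  b <- compute_lddt(model_from_ca(ca_ref), model_from_ca(ca_mod))
  expect_false(isTRUE(all.equal(a$per_residue, b$per_residue)))
  expect_error(compute_lddt(nat, make_native(11, seed = 7)), "contract")
})

test_that("a 0.7 A error on the only included pair scores 3/4", {
  ref <- model_from_ca(rbind(c(0, 0, 0), c(4, 0, 0), c(20, 0, 0)))
  mod <- model_from_ca(rbind(c(0, 0, 0), c(4.7, 0, 0), c(20, 0, 0)))
  r <- compute_lddt(mod, ref)
  # residues 1 and 2 see only the perturbed pair: passes 1/2/4, fails 0.5
  expect_equal(r$per_residue[1], 3 / 4)
  expect_equal(r$per_residue[2], 3 / 4)
  expect_equal(r$per_residue[3], 1)  # empty inclusion set
})

test_that("lDDT equals the brute-force double-loop oracle", {
  set.seed(12)
  for (k in 1:5) {
    nat <- make_native(10, seed = 100 + k)
    dec <- make_decoy(nat, runif(1, 0.5, 3), seed = 200 + k)$model
    expect_lt(max(abs(compute_lddt(dec, nat)$per_residue -
                        lddt_oracle(dec, nat))), 1e-12)
  }
})
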