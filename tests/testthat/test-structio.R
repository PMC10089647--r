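test_that("PDB write-then-read round trip preserves geometry and scores", {
  nat <- make_native(12, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(nat, f)
  m <- read_pdb_model(f)
  expect_equal(model_length(m), 12L)
  expect_identical(m$sequence, nat$sequence)
  expect_lt(max(abs(m$coords_ca - nat$coords_ca)), 1e-3)
  expect_lt(max(abs(m$coords_n - nat$coords_n)), 1e-3)
  expect_lt(max(abs(m$coords_c - nat$coords_c)), 1e-3)
  # b-factor column written on the 0-100 scale, read back to [0,1]
  expect_lt(max(abs(m$bfactor - nat$bfactor)), 0.005)
})

test_that("residues missing backbone atoms are dropped and reported", {
  nat <- make_native(6, seed = 1)
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(nat, f)
  lines <- readLines(f)
  ca_lines <- grep("^ATOM.* CA ", lines)
  writeLines(lines[-ca_lines[3]], f)
  expect_warning(m <- read_pdb_model(f), "3")
  expect_equal(model_length(m), 5L)

  # dropping down to fewer than 2 usable residues is a hard error
  writeLines(lines[-ca_lines[-1]], f)
  expect_error(suppressWarnings(read_pdb_model(f)), "degenerate|fewer")
})

test_that("multi-chain files require an explicit chain selector", {
  nat <- make_native(6, seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(nat, f)
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  second <- lines
  substr(second, 22, 22) <- "B"
  writeLines(c(lines, second, "END"), f)
  # (bio3d warns about duplicated atom numbers in the stitched file)
  expect_error(suppressWarnings(read_pdb_model(f)), "chain")
  m <- suppressWarnings(read_pdb_model(f, chain = "B"))
  expect_equal(m$chain_id, "B")
  expect_equal(model_length(m), 6L)
})

test_that("glycine always gets a virtual Cb; deposited Cb kept otherwise", {
  nat <- make_native(10, seed = 8)
  gly <- which(nat$sequence == "G")
  if (length(gly) == 0L) {
    nat$sequence[4] <- "G"
    gly <- 4L
  }
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(nat, f)
  m <- read_pdb_model(f)
  expect_true(all(m$cb_virtual[gly]))
  expect_true(all(is.finite(m$coords_cb)))
  i <- gly[1]
  expect_equal(as.numeric(m$coords_cb[i, ]),
               as.numeric(virtual_cb(m$coords_n[i, ], m$coords_ca[i, ],
                                     m$coords_c[i, ])),
               tolerance = 1e-8)
  # virtual reconstruction lands close to a deposited ideal-geometry Cb
  j <- setdiff(seq_len(10), gly)[1]
  d <- sqrt(sum((virtual_cb(m$coords_n[j, ], m$coords_ca[j, ], m$coords_c[j, ]) -
                   m$coords_cb[j, ])^2))
  expect_lt(d, 0.6)
})

test_that("virtual_cb matches the hand-computed axis-aligned closed form", {
  cb <- virtual_cb(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  # frozen from the tetrahedral construction evaluated by hand:
  # bisector -(1,1,0)/sqrt(2), out-of-plane -z, alpha = cos(109.5deg)/(-1/sqrt2)
  expect_equal(as.numeric(cb), c(-0.50806, -0.50806, -1.34174),
               tolerance = 1e-4)
  expect_error(virtual_cb(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("virtual_cb is exactly equivariant under rigid transforms", {
  set.seed(31)
  n <- c(1.3, 0.2, -0.5); ca <- c(0.1, -0.2, 0.4); cc <- c(-0.9, 1.1, 0.3)
  base <- virtual_cb(n, ca, cc)
  for (k in 1:100) {
    R <- rand_rotation(); tr <- rnorm(3, sd = 50)
    got <- virtual_cb(R %*% n + tr, R %*% ca + tr, R %*% cc + tr)
    expect_lt(max(abs(got - (R %*% base + tr))), 1e-6)
  }
})

test_that("write_prediction emits the score table and rescored PDB", {
  nat <- make_native(8, seed = 5)
  pred <- quality_prediction(rep(1, 8))
  prefix <- tempfile()
  write_prediction(pred, nat, prefix)
  tab <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(names(tab), c("index", "aa", "plddt"))
  expect_equal(nrow(tab), 8L)
  m <- read_pdb_model(paste0(prefix, ".pdb"))
  expect_true(all(abs(m$bfactor - 1) < 1e-6))  # 100.00 in the file

  set.seed(2)
  p2 <- quality_prediction(runif(8))
  write_prediction(p2, nat, prefix)
  m2 <- read_pdb_model(paste0(prefix, ".pdb"))
  expect_lt(max(abs(m2$bfactor - p2$per_residue_lddt)), 0.005)

  expect_error(write_prediction(quality_prediction(rep(0.5, 5)), nat, prefix),
               "contract")
})

test_that("model containers enforce their invariants", {
  expect_error(protein_model("A", matrix(0, 1, 3), matrix(0, 1, 3),
                             matrix(0, 1, 3)), "2 residues")
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  expect_error(model_from_ca(ca, sequence = c("A", "Z")), "non-standard")
  expect_error(quality_prediction(c(0.5, 1.2)), "within")
  p <- quality_prediction(c(0.25, 0.75))
  expect_equal(p$global_score, 0.5)
})
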