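AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a single-chain protein model
#'
#' Container for a parsed single-chain structural model: sequence, backbone
#' coordinates (N, Ca, C), beta-carbon coordinates (virtual for glycine or
#' when the deposited atom is absent), and a per-residue confidence taken
#' from the b-factor column. Coordinates are in Angstrom.
#'
#' @param sequence character vector of one-letter amino-acid codes, or a
#'   single string; only the 20 standard letters are accepted.
#' @param coords_n,coords_ca,coords_c L x 3 numeric matrices of backbone
#'   atom positions.
#' @param coords_cb optional L x 3 matrix of beta-carbon positions; rows
#'   that are `NA` (and all rows when `NULL`) are filled with an idealized
#'   Cb built from the local N/Ca/C frame (see [virtual_cb()]).
#' @param bfactor optional per-residue confidence; values greater than 1 are
#'   interpreted as a 0-100 scale and divided by 100.
#' @param chain_id chain identifier (single string).
#' @return An object of class `protein_model` with fields `sequence`
#'   (character vector), `coords_n`, `coords_ca`, `coords_c`, `coords_cb`,
#'   `bfactor`, `chain_id` and `cb_virtual` (logical: which Cb rows were
#'   constructed rather than deposited).
#' @export
protein_model <- function(sequence, coords_n, coords_ca, coords_c,
                          coords_cb = NULL, bfactor = NULL, chain_id = "A") {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  L <- length(sequence)
  if (L < 2L) stop("degenerate input: a model needs at least 2 residues")
  bad <- setdiff(unique(sequence), AA1)
  if (length(bad) > 0L) {
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  }
  coords_n <- as_coord_matrix(coords_n, L, "coords_n")
  coords_ca <- as_coord_matrix(coords_ca, L, "coords_ca")
  coords_c <- as_coord_matrix(coords_c, L, "coords_c")
  if (is.null(bfactor)) bfactor <- rep(NA_real_, L)
  stopifnot(length(bfactor) == L)
  bfactor <- normalize_confidence(bfactor)

  cb_virtual <- rep(TRUE, L)
  vb <- t(vapply(seq_len(L), function(i) {
    virtual_cb(coords_n[i, ], coords_ca[i, ], coords_c[i, ])
  }, numeric(3)))
  if (is.null(coords_cb)) {
    coords_cb <- vb
  } else {
    coords_cb <- as_coord_matrix(coords_cb, L, "coords_cb", allow_na = TRUE)
    miss <- !stats::complete.cases(coords_cb) | sequence == "G"
    coords_cb[miss, ] <- vb[miss, ]
    cb_virtual <- miss
  }
  m <- structure(list(
    sequence = sequence,
    coords_n = coords_n, coords_ca = coords_ca, coords_c = coords_c,
    coords_cb = coords_cb, bfactor = bfactor,
    chain_id = chain_id, cb_virtual = cb_virtual
  ), class = "protein_model")
  validate_protein_model(m)
  m
}

as_coord_matrix <- function(x, L, name, allow_na = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != L || ncol(x) != 3L) {
    stop(name, " must be an L x 3 matrix (L = ", L, ")")
  }
  if (!allow_na && any(!is.finite(x))) stop(name, " contains non-finite values")
  dimnames(x) <- NULL
  x
}

normalize_confidence <- function(b) {
  b <- as.numeric(b)
  # pLDDT is conventionally written on a 0-100 scale; the network uses [0,1]
  if (any(b > 1, na.rm = TRUE)) b <- b / 100
  pmin(pmax(b, 0), 1)
}

validate_protein_model <- function(m) {
  L <- length(m$sequence)
  stopifnot(
    L >= 2L,
    nrow(m$coords_n) == L, nrow(m$coords_ca) == L,
    nrow(m$coords_c) == L, nrow(m$coords_cb) == L
  )
  for (f in c("coords_n", "coords_ca", "coords_c", "coords_cb")) {
    if (any(!is.finite(m[[f]]))) stop("non-finite coordinates in ", f)
  }
  dca <- sqrt(rowSums((m$coords_ca[-1, , drop = FALSE] -
                         m$coords_ca[-L, , drop = FALSE])^2))
  if (any(dca <= 0)) stop("coincident consecutive Ca atoms")
  invisible(m)
}

#' Number of residues in a protein model
#' @param model a `protein_model`.
#' @return integer chain length L.
#' @export
model_length <- function(model) length(model$sequence)

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> chain %s, %d residues\n", x$chain_id,
              model_length(x)))
  cat("  ", paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Idealized beta-carbon position from backbone atoms
#'
#' Places a Cb atom from the N/Ca/C positions of one residue using fixed
#' tetrahedral geometry: the Cb direction makes equal 109.5 degree angles
#' with the Ca-N and Ca-C bonds and points out of the backbone plane on the
#' side conventional for L-amino acids; the Ca-Cb bond length is 1.522 A.
#' The construction is a pure function of the local frame, hence exactly
#' equivariant under rigid motions.
#'
#' @param n,ca,c numeric 3-vectors: backbone N, Ca and C positions (A).
#' @return numeric 3-vector: the idealized Cb position.
#' @export
virtual_cb <- function(n, ca, c) {
  vn <- n - ca
  vc <- c - ca
  nvn <- sqrt(sum(vn^2)); nvc <- sqrt(sum(vc^2))
  if (nvn == 0 || nvc == 0) stop("geometry error: zero-length backbone bond")
  vn <- vn / nvn
  vc <- vc / nvc
  perp <- c(vn[2] * vc[3] - vn[3] * vc[2],
            vn[3] * vc[1] - vn[1] * vc[3],
            vn[1] * vc[2] - vn[2] * vc[1])
  np <- sqrt(sum(perp^2))
  if (np < 1e-8) stop("geometry error: collinear N, Ca, C")
  perp <- perp / np
  bis <- -(vn + vc)
  bis <- bis / sqrt(sum(bis^2))
  cos_t <- cos(109.5 * pi / 180)
  # vn . bis = -sqrt((1 + vn.vc)/2); solve for the in-plane weight
  alpha <- cos_t / sum(vn * bis)
  alpha <- min(alpha, 1)
  beta <- sqrt(max(0, 1 - alpha^2))
  ca + 1.522 * (alpha * bis - beta * perp)
}

#' Read a single-chain structural model from a PDB file
#'
#' Parses ATOM records with [bio3d::read.pdb()], keeps one chain, and
#' extracts per-residue backbone geometry and the Ca b-factor as
#' self-reported confidence. Residues missing any of N/Ca/C are dropped
#' with a warning naming their indices; positions are renumbered
#' contiguously. Deposited Cb atoms are kept where present; glycines (and
#' residues without a Cb) receive an idealized Cb.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; required when the file has several chains.
#' @param force_virtual_cb if `TRUE`, ignore deposited Cb atoms and build
#'   every Cb from ideal geometry.
#' @return a [protein_model()].
#' @export
read_pdb_model <- function(path, chain = NULL, force_virtual_cb = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("PDB parse error: no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("ambiguous input: multiple chains (", paste(chains, collapse = ","),
           "); pass `chain`")
    }
    chain <- chains[1]
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain ", chain, " not found in ", path)

  ins <- at$insert
  ins[is.na(ins)] <- ""
  rid <- paste(at$resno, ins, sep = "_")
  rids <- unique(rid)

  grab <- function(rows, elety) {
    k <- which(at$elety[rows] == elety)
    if (length(k) == 0L) return(NULL)
    r <- rows[k[1]]
    c(at$x[r], at$y[r], at$z[r])
  }

  n_list <- ca_list <- c_list <- cb_list <- list()
  seq1 <- character(0)
  bf <- numeric(0)
  dropped <- integer(0)
  for (i in seq_along(rids)) {
    rows <- which(rid == rids[i])
    xyz_n <- grab(rows, "N"); xyz_ca <- grab(rows, "CA"); xyz_c <- grab(rows, "C")
    if (is.null(xyz_n) || is.null(xyz_ca) || is.null(xyz_c)) {
      dropped <- c(dropped, i)
      next
    }
    aa <- bio3d::aa321(at$resid[rows[1]])
    if (!aa %in% AA1) {
      dropped <- c(dropped, i)
      next
    }
    j <- length(seq1) + 1L
    seq1[j] <- aa
    n_list[[j]] <- xyz_n; ca_list[[j]] <- xyz_ca; c_list[[j]] <- xyz_c
    cb <- if (force_virtual_cb) NULL else grab(rows, "CB")
    cb_list[[j]] <- if (is.null(cb)) rep(NA_real_, 3) else cb
    bfi <- at$b[rows[at$elety[rows] == "CA"][1]]
    bf[j] <- if (is.na(bfi)) NA_real_ else bfi
  }
  if (length(dropped) > 0L) {
    warning("dropped ", length(dropped),
            " residue(s) with missing backbone atoms or non-standard type ",
            "at file position(s): ", paste(dropped, collapse = ", "))
  }
  if (length(seq1) < 2L) {
    stop("degenerate input: fewer than 2 usable residues in ", path,
         if (length(dropped)) paste0(" (dropped: ",
                                     paste(dropped, collapse = ", "), ")"))
  }
  protein_model(
    sequence = seq1,
    coords_n = do.call(rbind, n_list),
    coords_ca = do.call(rbind, ca_list),
    coords_c = do.call(rbind, c_list),
    coords_cb = do.call(rbind, cb_list),
    bfactor = bf, chain_id = chain
  )
}

#' Construct a quality prediction object
#'
#' @param per_residue predicted per-residue lDDT values in \[0,1\].
#' @param pairwise_error optional L x L signed distance-error matrix (A).
#' @return An object of class `quality_prediction` with fields
#'   `per_residue_lddt`, `global_score` (their mean) and `pairwise_error`.
#' @export
quality_prediction <- function(per_residue, pairwise_error = NULL) {
  per_residue <- as.numeric(per_residue)
  if (any(!is.finite(per_residue)) || any(per_residue < 0 | per_residue > 1)) {
    stop("per-residue lDDT must be finite and within [0,1]")
  }
  if (!is.null(pairwise_error)) {
    pairwise_error <- as.matrix(pairwise_error)
    stopifnot(nrow(pairwise_error) == length(per_residue),
              ncol(pairwise_error) == length(per_residue))
  }
  structure(list(
    per_residue_lddt = per_residue,
    global_score = mean(per_residue),
    pairwise_error = pairwise_error
  ), class = "quality_prediction")
}

#' @export
print.quality_prediction <- function(x, ...) {
  cat(sprintf("<quality_prediction> L = %d, global lDDT = %.4f\n",
              length(x$per_residue_lddt), x$global_score))
  invisible(x)
}

#' Write prediction outputs
#'
#' Writes (a) a per-residue TSV table with columns `index`, `aa`, `plddt`
#' and (b) a PDB copy of the input model whose temperature-factor column
#' carries the predicted lDDT scaled to 0-100.
#'
#' @param pred a [quality_prediction()].
#' @param model the scored [protein_model()].
#' @param prefix output path prefix; `<prefix>.tsv` and `<prefix>.pdb` are
#'   written.
#' @return invisibly, the two paths written.
#' @export
write_prediction <- function(pred, model, prefix) {
  L <- model_length(model)
  if (length(pred$per_residue_lddt) != L) {
    stop("contract error: prediction length ", length(pred$per_residue_lddt),
         " != model length ", L)
  }
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(
    data.frame(index = seq_len(L), aa = model$sequence,
               plddt = sprintf("%.4f", pred$per_residue_lddt)),
    file = tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  pdbf <- paste0(prefix, ".pdb")
  write_model_pdb(model, pdbf, bfactor = pred$per_residue_lddt * 100)
  invisible(c(tsv, pdbf))
}

#' Write a protein model as a PDB file
#'
#' Emits N/CA/C/CB ATOM records (CB omitted for glycine) through
#' [bio3d::write.pdb()]. Fixed-width PDB columns quantize coordinates to
#' 1e-3 A and b-factors to 1e-2.
#'
#' @param model a [protein_model()].
#' @param path output file.
#' @param bfactor per-residue value for the temperature-factor column;
#'   defaults to the model's confidence on a 0-100 scale.
#' @return invisibly, `path`.
#' @export
write_model_pdb <- function(model, path, bfactor = NULL) {
  L <- model_length(model)
  if (is.null(bfactor)) {
    bfactor <- ifelse(is.na(model$bfactor), 0, model$bfactor * 100)
  }
  stopifnot(length(bfactor) == L)
  xyz <- c(); elety <- c(); resno <- c(); resid <- c(); b <- c()
  for (i in seq_len(L)) {
    atoms <- list(N = model$coords_n[i, ], CA = model$coords_ca[i, ],
                  C = model$coords_c[i, ])
    if (model$sequence[i] != "G") atoms$CB <- model$coords_cb[i, ]
    for (a in names(atoms)) {
      xyz <- c(xyz, atoms[[a]])
      elety <- c(elety, a)
      resno <- c(resno, i)
      resid <- c(resid, bio3d::aa123(model$sequence[i]))
      b <- c(b, bfactor[i])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(model$chain_id, length(elety)),
                   b = b)
  invisible(path)
}

#' Extract a contiguous sub-model
#' @param model a `protein_model`.
#' @param idx increasing integer vector of residue indices to keep.
#' @return a `protein_model` over the selected residues.
#' @export
subset_model <- function(model, idx) {
  protein_model(
    sequence = model$sequence[idx],
    coords_n = model$coords_n[idx, , drop = FALSE],
    coords_ca = model$coords_ca[idx, , drop = FALSE],
    coords_c = model$coords_c[idx, , drop = FALSE],
    coords_cb = model$coords_cb[idx, , drop = FALSE],
    bfactor = model$bfactor[idx],
    chain_id = model$chain_id
  )
}

#' Apply a rigid transform to a model
#'
#' Utility used throughout the test-suite to verify invariance and
#' equivariance properties.
#'
#' @param model a `protein_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return the transformed `protein_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(x) sweep(x %*% t(rotation), 2, translation, "+")
  protein_model(
    sequence = model$sequence,
    coords_n = tr(model$coords_n),
    coords_ca = tr(model$coords_ca),
    coords_c = tr(model$coords_c),
    coords_cb = tr(model$coords_cb),
    bfactor = model$bfactor,
    chain_id = model$chain_id
  )
}
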