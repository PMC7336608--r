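# The protein_model container: one chain, ordered residues, atoms in a flat
# data frame, optional per-residue secondary structure and relative solvent
# accessibility.

#' Construct a protein model
#'
#' A `protein_model` holds one protein chain as an ordered residue list:
#' a flat atom table (0-based residue index, residue type, atom name,
#' coordinates), the derived one-letter sequence, and optional per-residue
#' 3-state secondary structure (`H`/`E`/`C`) and relative solvent
#' accessibility in `[0, 1]`.
#'
#' @param id model identifier string.
#' @param atoms data.frame with columns `res_index` (0-based integer),
#'   `aa` (one-letter residue code), `atom` (PDB atom name), `x`, `y`, `z`
#'   (Angstrom) and optionally `resno_pdb`.
#' @param ss3 optional character vector, one of `H`,`E`,`C` per residue.
#' @param rsa optional numeric vector in `[0,1]` per residue.
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(id, atoms, ss3 = NULL, rsa = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("res_index", "aa", "atom", "x", "y", "z") %in% names(atoms)))
  if (anyNA(atoms$aa)) stop("unknown residue type in atom table")
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  idx <- sort(unique(atoms$res_index))
  if (!identical(idx, seq_along(idx) - 1L)) {
    ## renumber to contiguous 0-based indices, preserving order
    atoms$res_index <- match(atoms$res_index, idx) - 1L
    idx <- seq_along(idx) - 1L
  }
  n <- length(idx)
  seq1 <- atoms$aa[match(idx, atoms$res_index)]
  dup <- duplicated(atoms[, c("res_index", "atom")])
  if (any(dup)) atoms <- atoms[!dup, , drop = FALSE]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (is.null(ss3)) ss3 <- rep(NA_character_, n)
  if (is.null(rsa)) rsa <- rep(NA_real_, n)
  stopifnot(length(ss3) == n, length(rsa) == n)
  if (any(!is.na(rsa) & (rsa < 0 | rsa > 1))) stop("rsa outside [0,1]")
  structure(list(id = id, atoms = atoms, seq = seq1, ss3 = ss3, rsa = rsa),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d residues, %d atoms, ss3 %s, rsa %s\n",
              x$id, n_residues(x), nrow(x$atoms),
              if (anyNA(x$ss3)) "unassigned" else "assigned",
              if (anyNA(x$rsa)) "unassigned" else "assigned"))
  invisible(x)
}

#' Number of residues in a model
#' @param model a `protein_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) length(model$seq)

#' Per-residue coordinates of one named atom
#'
#' Returns an `L x 3` matrix with one row per residue (`NA` rows where the
#' atom is missing). For `"CB"` with `gly_ca = TRUE` the Ca coordinate is
#' substituted for glycine, the standard completion for Cb-based potentials.
#'
#' @param model a `protein_model`.
#' @param name atom name, e.g. `"CA"`.
#' @param gly_ca substitute Ca for glycine when `name == "CB"`.
#' @return numeric matrix `L x 3`.
#' @export
atom_coords <- function(model, name, gly_ca = TRUE) {
  L <- n_residues(model)
  out <- matrix(NA_real_, L, 3)
  a <- model$atoms[model$atoms$atom == name, ]
  out[a$res_index + 1L, ] <- as.matrix(a[, c("x", "y", "z")])
  if (name == "CB" && gly_ca) {
    gly <- which(model$seq == "G")
    if (length(gly)) {
      ca <- atom_coords(model, "CA", gly_ca = FALSE)
      out[gly, ] <- ca[gly, , drop = FALSE]
    }
  }
  out
}

## all heavy atoms (no hydrogens) as a data.frame
heavy_atoms <- function(model) {
  a <- model$atoms
  elem <- substr(gsub("^[0-9]", "", a$atom), 1, 1)
  a[elem != "H", , drop = FALSE]
}

## apply rigid-body (or any affine) transform to all coordinates
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Write a model to a PDB file
#'
#' @param model a `protein_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$res_index + 1L,
                   resid = aa1_to_3(a$aa),
                   elety = a$atom,
                   chain = rep("A", nrow(a)))
  invisible(path)
}
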