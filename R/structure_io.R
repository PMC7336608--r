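# Structure and annotation input: PDB models, STRIDE assignments, predicted
# secondary-structure / burial strings, and the internal geometric
# secondary-structure + accessibility assigner used when no STRIDE file is
# available.

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records of the first (or a named) chain into a
#' [protein_model]. Alternate locations are resolved to the highest
#' occupancy (ties: first record); insertion-code residues are kept in file
#' order; HETATM records are ignored; of multi-MODEL files only the first
#' model is read. Residues with non-standard types are skipped with a
#' warning.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default first chain in the file.
#' @param id model id; defaults to the file name without extension.
#' @return A [protein_model].
#' @export
read_pdb <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain | (is.na(at$chain) & is.na(chain)), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain ", chain, " in ", path)

  ## residue identity = (resno, insert); keep file order
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rid <- paste(at$resno, ins)
  uid <- unique(rid)
  res_index <- match(rid, uid) - 1L

  ## altloc: keep, per (residue, atom name), the highest-occupancy record
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(res_index, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  at <- at[keep, , drop = FALSE]
  res_index <- res_index[keep]

  aa <- aa3_to_1(at$resid)
  if (anyNA(aa)) {
    bad <- unique(at$resid[is.na(aa)])
    warning("skipping residues of unknown type: ", paste(bad, collapse = ", "))
    ok <- !is.na(aa)
    at <- at[ok, , drop = FALSE]
    res_index <- res_index[ok]
    aa <- aa[ok]
    if (nrow(at) == 0) stop("no standard-residue ATOM records in ", path)
    res_index <- match(res_index, sort(unique(res_index))) - 1L
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  protein_model(id, data.frame(res_index = res_index, aa = aa,
                               atom = at$elety, x = at$x, y = at$y, z = at$z,
                               resno_pdb = at$resno,
                               stringsAsFactors = FALSE))
}

## STRIDE 7-state -> 3-state mapping; total over the STRIDE alphabet.
stride_ss3 <- function(code) {
  up <- toupper(code)
  out <- rep("C", length(code))
  out[up %in% c("H", "G", "I")] <- "H"
  out[up %in% c("E", "B")] <- "E"
  out
}

#' Read per-residue secondary structure and accessibility from STRIDE output
#'
#' Parses `ASG` records. The 7-state STRIDE code is mapped to 3 states
#' (H,G,I to H; E,B to E; everything else to C) and the solvent-accessible
#' area is converted to relative accessibility by dividing by the residue's
#' theoretical maximum area (Tien et al. 2013), clamped to `[0, 1]`.
#'
#' @param path STRIDE output file.
#' @return data.frame with columns `aa` (one-letter), `ss3`, `rsa`, in
#'   record order.
#' @export
read_stride <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  asg <- grep("^ASG", lines)
  if (!length(asg)) stop("no ASG records in ", path)
  res <- lapply(asg, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 10)
      stop("malformed ASG record at line ", i, " of ", path)
    aa <- aa3_to_1(f[2])
    area <- suppressWarnings(as.numeric(f[10]))
    if (is.na(area)) stop("malformed ASG record at line ", i, " of ", path)
    rsa <- if (is.na(aa)) NA_real_ else min(1, max(0, area / MAX_ASA[[aa]]))
    data.frame(aa = aa, ss3 = stride_ss3(f[6]), rsa = rsa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## Backbone dihedrals per residue; NA at termini, missing atoms and chain
## breaks (peptide C-N bond longer than 2.5 A).
backbone_dihedrals <- function(model) {
  L <- n_residues(model)
  N <- atom_coords(model, "N")
  CA <- atom_coords(model, "CA")
  C <- atom_coords(model, "C")
  phi <- psi <- rep(NA_real_, L)
  bond_ok <- function(i, j) {          # C(i) - N(j) peptide bond intact
    all(is.finite(C[i, ])) && all(is.finite(N[j, ])) &&
      vnorm(C[i, ] - N[j, ]) < 2.5
  }
  for (i in seq_len(L)) {
    if (i > 1 &&
        all(is.finite(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))) &&
        bond_ok(i - 1, i))
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < L &&
        all(is.finite(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))) &&
        bond_ok(i, i + 1))
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  list(phi = phi, psi = psi)
}

## runs of TRUE of length >= k
runs_at_least <- function(x, k) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Assign secondary structure and relative accessibility geometrically
#'
#' Deterministic fallback used when no STRIDE file is supplied. Helix:
#' residues whose (phi, psi) fall in (-100..-30, -80..-5) degrees over runs
#' of at least 4; strand: (-180..-40, 90..180 or -180..-170) over runs of at
#' least 2; otherwise coil. Relative accessibility comes from a heavy-atom
#' neighbour-count proxy (atoms within 10 A of the residue's Ca, own residue
#' excluded) mapped through a fixed monotone decreasing ramp onto `[0, 1]`.
#' When a STRIDE assignment is available it should always be preferred.
#'
#' @param model a [protein_model] with backbone N, Ca, C atoms.
#' @return The model with `ss3` and `rsa` filled.
#' @export
assign_ss_rsa <- function(model) {
  L <- n_residues(model)
  if (L < 5) {
    warning("chain shorter than 5 residues: all coil, rsa 0.5")
    model$ss3 <- rep("C", L)
    model$rsa <- rep(0.5, L)
    return(model)
  }
  di <- backbone_dihedrals(model)
  phi <- di$phi
  psi <- di$psi
  helix_ok <- !is.na(phi) & !is.na(psi) &
    phi > -100 & phi < -30 & psi > -80 & psi < -5
  strand_ok <- !is.na(phi) & !is.na(psi) &
    phi > -180 & phi < -40 & (psi > 90 | psi < -170)
  ss <- rep("C", L)
  ss[runs_at_least(strand_ok, 2)] <- "E"
  ss[runs_at_least(helix_ok, 4)] <- "H"

  ha <- heavy_atoms(model)
  CA <- atom_coords(model, "CA")
  hx <- as.matrix(ha[, c("x", "y", "z")])
  rsa <- rep(0.5, L)
  ok <- which(apply(is.finite(CA), 1, all))
  if (length(ok)) {
    d <- cross_dist(CA[ok, , drop = FALSE], hx)
    cnt <- vapply(seq_along(ok), function(k) {
      sum(d[k, ] <= 10 & ha$res_index != (ok[k] - 1L))
    }, 0L)
    ## monotone ramp: <= 10 neighbours fully exposed, >= 80 fully buried
    rsa[ok] <- pmin(1, pmax(0, (80 - cnt) / 70))
  }
  model$ss3 <- ss
  model$rsa <- rsa
  model
}

#' Apply a STRIDE assignment to a model
#'
#' @param model a [protein_model].
#' @param stride data.frame from [read_stride()].
#' @return The model with `ss3`/`rsa` taken from the STRIDE records.
#' @export
apply_stride <- function(model, stride) {
  if (nrow(stride) != n_residues(model))
    stop("STRIDE record count (", nrow(stride), ") does not match model length (",
         n_residues(model), ")")
  model$ss3 <- stride$ss3
  model$rsa <- stride$rsa
  model
}

#' Read predicted secondary-structure and burial strings
#'
#' Plain-text one-letter-per-residue strings: secondary structure over
#' `{H, E, C}` and two-state burial over `{e, -}` or `{E, B}` (exposed /
#' buried). Whitespace and lines starting with `>` are ignored.
#'
#' @param path text file path.
#' @param kind `"ss"` or `"burial"`.
#' @return A single validated string; burial strings are normalised to
#'   `e` (exposed) / `-` (buried).
#' @export
read_prediction_string <- function(path, kind = c("ss", "burial")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines)]
  s <- gsub("\\s", "", paste(lines, collapse = ""))
  if (nchar(s) == 0) stop("empty prediction string in ", path)
  ch <- strsplit(s, "")[[1]]
  if (kind == "ss") {
    bad <- which(!ch %in% c("H", "E", "C"))
    if (length(bad))
      stop("illegal secondary-structure letter '", ch[bad[1]],
           "' at position ", bad[1])
    return(s)
  }
  bad <- which(!ch %in% c("e", "-", "E", "B"))
  if (length(bad))
    stop("illegal burial letter '", ch[bad[1]], "' at position ", bad[1])
  ch[ch == "E"] <- "e"
  ch[ch == "B"] <- "-"
  paste(ch, collapse = "")
}
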