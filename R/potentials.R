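# The ten statistical potentials: per-residue / per-atom state emitters and
# model scoring against a reference. Five potentials are computed for both
# Ca and Cb representatives, giving 15 potential scores per model.

#' Potential and pipeline configuration
#'
#' Bin ranges, class counts and cutoffs for every potential, plus the
#' energy-formula constants. Defaults are the method's published settings.
#'
#' @param sigma energy-formula weight (default 1/50).
#' @param RT energy-formula temperature factor, kcal/mole (default 0.582).
#' @param pap_n pseudo-bond angle classes over `[0, 180]` degrees.
#' @param tap_n dihedral classes over `(-180, 180]` degrees.
#' @param csp_n centrosymmetric distance classes over `[0, 3*Rg]`.
#' @param aspr_radius,aspr_lo,aspr_hi,aspr_n residue-level accessible-surface
#'   sphere radius (A) and neighbour-count binning.
#' @param aspa_radius,aspa_lo,aspa_hi,aspa_n atomic-level accessible-surface
#'   sphere radius (A) and neighbour-count binning.
#' @param ddp_lo,ddp_hi,ddp_n,ddp_min_sep distance-potential range (A),
#'   classes, and minimum sequence separation.
#' @param ssdp_max_dist,ssdp_lo,ssdp_hi,ssdp_n separation-potential distance
#'   cutoff (A) and separation binning.
#' @param cdp_min_sep,cdp_max_dist contact-potential separation and distance
#'   (A) cutoffs.
#' @param rsap_n relative-accessibility classes over `[0, 1]`.
#' @param vdp_lo,vdp_hi,vdp_n,vdp_ball,vdp_grid volume-potential binning
#'   (A^3), bounding-ball radius (A) and sampling grid spacing (A).
#' @return A named list of class `mass_config`.
#' @export
mass_config <- function(sigma = 1 / 50, RT = 0.582,
                        pap_n = 6L, tap_n = 9L, csp_n = 30L,
                        aspr_radius = 11, aspr_lo = 0, aspr_hi = 50, aspr_n = 25L,
                        aspa_radius = 8, aspa_lo = 50, aspa_hi = 200, aspa_n = 30L,
                        ddp_lo = 5, ddp_hi = 25, ddp_n = 40L, ddp_min_sep = 3L,
                        ssdp_max_dist = 8, ssdp_lo = 0, ssdp_hi = 300, ssdp_n = 60L,
                        cdp_min_sep = 6L, cdp_max_dist = 9,
                        rsap_n = 10L, vdp_lo = 10, vdp_hi = 30, vdp_n = 10L,
                        vdp_ball = 8, vdp_grid = 0.8) {
  cfg <- list(sigma = sigma, RT = RT, pap_n = as.integer(pap_n),
              tap_n = as.integer(tap_n), csp_n = as.integer(csp_n),
              aspr_radius = aspr_radius, aspr_lo = aspr_lo,
              aspr_hi = aspr_hi, aspr_n = as.integer(aspr_n),
              aspa_radius = aspa_radius, aspa_lo = aspa_lo,
              aspa_hi = aspa_hi, aspa_n = as.integer(aspa_n),
              ddp_lo = ddp_lo, ddp_hi = ddp_hi, ddp_n = as.integer(ddp_n),
              ddp_min_sep = as.integer(ddp_min_sep),
              ssdp_max_dist = ssdp_max_dist, ssdp_lo = ssdp_lo,
              ssdp_hi = ssdp_hi, ssdp_n = as.integer(ssdp_n),
              cdp_min_sep = as.integer(cdp_min_sep),
              cdp_max_dist = cdp_max_dist, rsap_n = as.integer(rsap_n),
              vdp_lo = vdp_lo, vdp_hi = vdp_hi, vdp_n = as.integer(vdp_n),
              vdp_ball = vdp_ball, vdp_grid = vdp_grid)
  class(cfg) <- c("mass_config", "list")
  cfg
}

#' Names of the 15 potential scores
#'
#' Ten potentials, five of which are evaluated with both Ca and Cb residue
#' representatives.
#'
#' @return Character vector of length 15.
#' @export
potential_names <- function() {
  c("pap", "tap", "aspa", "rsap", "vdp",
    "aspr_ca", "aspr_cb", "cdp_ca", "cdp_cb", "csp_ca", "csp_cb",
    "ddp_ca", "ddp_cb", "ssdp_ca", "ssdp_cb")
}

## helper: event frame
ev_frame <- function(type, state) {
  data.frame(type = as.character(type), state = as.character(state),
             stringsAsFactors = FALSE)
}

## representative-atom coordinate matrix for a kind ("ca" / "cb")
rep_coords <- function(model, kind) {
  atom_coords(model, if (kind == "ca") "CA" else "CB", gly_ca = TRUE)
}

#' Pseudo-bond angle states
#'
#' For residue `i` (not terminal), the angles at `X_i` formed by
#' `X_{i-1}, X_i, X_{i+1}` for X in N, Ca, C, each binned evenly over
#' `[0, 180]` degrees into `pap_n` classes. Residues missing any of the nine
#' atoms involved are skipped.
#'
#' @param model annotated [protein_model].
#' @param config a [mass_config()].
#' @return data.frame of events: `type` = residue type, `state` =
#'   `ss:cN:cCa:cC`.
#' @export
pseudo_bond_angle_states <- function(model, config = mass_config()) {
  L <- n_residues(model)
  if (L < 3) return(ev_frame(character(0), character(0)))
  Xs <- list(N = atom_coords(model, "N"), CA = atom_coords(model, "CA"),
             C = atom_coords(model, "C"))
  ang <- lapply(Xs, function(X) {
    th <- rep(NA_real_, L)
    for (i in 2:(L - 1)) {
      if (all(is.finite(c(X[i - 1, ], X[i, ], X[i + 1, ]))))
        th[i] <- point_angle(X[i - 1, ], X[i, ], X[i + 1, ])
    }
    th
  })
  ok <- which(!is.na(ang$N) & !is.na(ang$CA) & !is.na(ang$C) &
                !is.na(model$ss3))
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  cN <- bin_index(ang$N[ok], 0, 180, config$pap_n)
  cCA <- bin_index(ang$CA[ok], 0, 180, config$pap_n)
  cC <- bin_index(ang$C[ok], 0, 180, config$pap_n)
  ev_frame(model$seq[ok], paste(model$ss3[ok], cN, cCA, cC, sep = ":"))
}

## 5-way pattern class of a class triple (a1, a2, a3)
pattern5 <- function(a1, a2, a3) {
  ifelse(a1 == a2 & a1 == a3, 1L,
    ifelse(a1 != a2 & a2 != a3 & a1 != a3, 2L,
      ifelse(a1 == a2, 3L,
        ifelse(a1 == a3, 4L, 5L))))
}

## 4-way pattern class centred on a2
pattern4 <- function(a1, a2, a3) {
  ifelse(a2 == a1 & a2 == a3, 1L,
    ifelse(a2 != a1 & a2 != a3, 2L,
      ifelse(a2 == a1, 3L, 4L)))
}

#' Torsion-angle pattern states
#'
#' Each backbone dihedral is binned into `tap_n` classes over
#' `(-180, 180]` degrees (-180 is mapped to +180). For residue `i`, the
#' class triples of (phi_{i-1}, phi_i, phi_{i+1}) and of the psi
#' counterparts are reduced to a 5-way equality pattern (all equal; all
#' distinct; first pair equal; outer pair equal; last pair equal) and a
#' 4-way pattern centred on the middle class. Residues with any of the six
#' dihedrals undefined (termini, chain breaks) are skipped.
#'
#' @inheritParams pseudo_bond_angle_states
#' @return data.frame of events: `type` = residue type, `state` =
#'   `ss:phi_c5:psi_c5:phi_c4:psi_c4`.
#' @export
torsion_states <- function(model, config = mass_config()) {
  L <- n_residues(model)
  if (L < 3) return(ev_frame(character(0), character(0)))
  di <- backbone_dihedrals(model)
  tor_bin <- function(v) {
    v[!is.na(v) & v == -180] <- 180
    bin_index(v, -180, 180, config$tap_n)  # NA propagates
  }
  cphi <- tor_bin(di$phi)
  cpsi <- tor_bin(di$psi)
  idx <- 2:(L - 1)
  ok <- idx[!is.na(cphi[idx - 1]) & !is.na(cphi[idx]) & !is.na(cphi[idx + 1]) &
              !is.na(cpsi[idx - 1]) & !is.na(cpsi[idx]) & !is.na(cpsi[idx + 1]) &
              !is.na(model$ss3[idx])]
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  p5 <- pattern5(cphi[ok - 1], cphi[ok], cphi[ok + 1])
  s5 <- pattern5(cpsi[ok - 1], cpsi[ok], cpsi[ok + 1])
  p4 <- pattern4(cphi[ok - 1], cphi[ok], cphi[ok + 1])
  s4 <- pattern4(cpsi[ok - 1], cpsi[ok], cpsi[ok + 1])
  ev_frame(model$seq[ok], paste(model$ss3[ok], p5, s5, p4, s4, sep = ":"))
}

#' Static radius of gyration from chain length
#'
#' Regression estimate for globular proteins: `0.395 * N^0.6 + 7.257` (A).
#'
#' @param n_residues chain length.
#' @return Radius of gyration estimate in Angstrom.
#' @export
static_rg <- function(n_residues) 0.395 * n_residues^0.6 + 7.257

#' Centrosymmetric burial states
#'
#' Distance of each representative atom to the centroid of all
#' representative atoms, binned evenly over `[0, 3*Rg]` (static `Rg` from
#' chain length) into `csp_n` classes, clamped at the edges.
#'
#' @inheritParams pseudo_bond_angle_states
#' @param atom_kind `"ca"` or `"cb"` residue representative.
#' @return data.frame of events: `type` = residue type, `state` = `ss:c30`.
#' @export
csp_states <- function(model, atom_kind = c("ca", "cb"),
                       config = mass_config()) {
  atom_kind <- match.arg(atom_kind)
  X <- rep_coords(model, atom_kind)
  ok <- which(apply(is.finite(X), 1, all) & !is.na(model$ss3))
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  ctr <- colMeans(X[ok, , drop = FALSE])
  d <- sqrt(rowSums(sweep(X[ok, , drop = FALSE], 2, ctr)^2))
  cls <- bin_index(d, 0, 3 * static_rg(n_residues(model)), config$csp_n)
  ev_frame(model$seq[ok], paste(model$ss3[ok], cls, sep = ":"))
}

#' Residue-level accessible-surface states
#'
#' Burial proxy: the number of other residues whose representative atom lies
#' within `aspr_radius` (11 A) of the residue's representative atom, binned
#' evenly over `[aspr_lo, aspr_hi]` into `aspr_n` classes (clamped).
#'
#' @inheritParams csp_states
#' @return data.frame of events: `type` = residue type, `state` = `ss:c25`.
#' @export
aspr_states <- function(model, atom_kind = c("ca", "cb"),
                        config = mass_config()) {
  atom_kind <- match.arg(atom_kind)
  X <- rep_coords(model, atom_kind)
  ok <- which(apply(is.finite(X), 1, all) & !is.na(model$ss3))
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  D <- cross_dist(X[ok, , drop = FALSE], X[ok, , drop = FALSE])
  cnt <- rowSums(D <= config$aspr_radius) - 1L
  cls <- bin_index(cnt, config$aspr_lo, config$aspr_hi, config$aspr_n)
  ev_frame(model$seq[ok], paste(model$ss3[ok], cls, sep = ":"))
}

#' Atomic-level accessible-surface states
#'
#' For every typed heavy atom, the number of other heavy atoms within
#' `aspa_radius` (8 A), binned evenly over `[aspa_lo, aspa_hi]` into
#' `aspa_n` classes (clamped). Atom types come from [atom_type_40()]; atoms
#' outside the typing table are skipped with a warning.
#'
#' @inheritParams pseudo_bond_angle_states
#' @return data.frame of events: `type` = 40-class atom type, `state` = c30.
#' @export
aspa_states <- function(model, config = mass_config()) {
  ha <- heavy_atoms(model)
  if (nrow(ha) == 0) return(ev_frame(character(0), character(0)))
  ty <- atom_type_40(aa1_to_3(ha$aa), ha$atom)
  if (anyNA(ty)) {
    warning("skipping ", sum(is.na(ty)), " heavy atoms outside the 40-type table")
    ha <- ha[!is.na(ty), , drop = FALSE]
    ty <- ty[!is.na(ty)]
    if (nrow(ha) == 0) return(ev_frame(character(0), character(0)))
  }
  X <- as.matrix(ha[, c("x", "y", "z")])
  D <- cross_dist(X, X)
  cnt <- rowSums(D <= config$aspa_radius) - 1L
  cls <- bin_index(cnt, config$aspa_lo, config$aspa_hi, config$aspa_n)
  ev_frame(ty, as.character(cls))
}

## all unordered residue pairs (i < j) with defined representative coords
pair_index <- function(X) {
  ok <- which(apply(is.finite(X), 1, all))
  if (length(ok) < 2) return(NULL)
  cmb <- utils::combn(ok, 2)
  list(i = cmb[1, ], j = cmb[2, ])
}

## unordered residue-type pair key, e.g. "A:V"
pair_type <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Distance-dependent pair events
#'
#' Unordered residue pairs at least `ddp_min_sep` (3) apart in sequence with
#' representative-atom distance inside `[ddp_lo, ddp_hi]` ([5, 25] A; pairs
#' outside the range are ignored), binned evenly into `ddp_n` classes.
#'
#' @inheritParams csp_states
#' @return data.frame of events: `type` = unordered residue-type pair,
#'   `state` = distance class.
#' @export
ddp_pairs <- function(model, atom_kind = c("ca", "cb"),
                      config = mass_config()) {
  atom_kind <- match.arg(atom_kind)
  X <- rep_coords(model, atom_kind)
  px <- pair_index(X)
  if (is.null(px)) return(ev_frame(character(0), character(0)))
  i <- px$i; j <- px$j
  sep <- abs(i - j)
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  keep <- sep >= config$ddp_min_sep & d >= config$ddp_lo & d <= config$ddp_hi
  if (!any(keep)) return(ev_frame(character(0), character(0)))
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  cls <- bin_index(d, config$ddp_lo, config$ddp_hi, config$ddp_n,
                   policy = "reject")
  ev_frame(pair_type(model$seq[i], model$seq[j]), as.character(cls))
}

#' Sequence-separation pair events
#'
#' Unordered residue pairs in contact (representative-atom distance at most
#' `ssdp_max_dist`, 8 A) emit their sequence separation, binned evenly over
#' `[ssdp_lo, ssdp_hi]` ([0, 300]) into `ssdp_n` classes; separations beyond
#' the range are ignored.
#'
#' @inheritParams csp_states
#' @return data.frame of events: `type` = unordered residue-type pair,
#'   `state` = separation class.
#' @export
ssdp_pairs <- function(model, atom_kind = c("ca", "cb"),
                       config = mass_config()) {
  atom_kind <- match.arg(atom_kind)
  X <- rep_coords(model, atom_kind)
  px <- pair_index(X)
  if (is.null(px)) return(ev_frame(character(0), character(0)))
  i <- px$i; j <- px$j
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  keep <- d <= config$ssdp_max_dist
  if (!any(keep)) return(ev_frame(character(0), character(0)))
  i <- i[keep]; j <- j[keep]
  cls <- bin_index(abs(i - j), config$ssdp_lo, config$ssdp_hi, config$ssdp_n,
                   policy = "reject")
  ok <- !is.na(cls)
  ev_frame(pair_type(model$seq[i[ok]], model$seq[j[ok]]),
           as.character(cls[ok]))
}

#' Contact-dependent events
#'
#' For every ordered residue pair (focal `i`, partner `j`) with sequence
#' separation at least `cdp_min_sep` (6) and representative-atom distance
#' below `cdp_max_dist` (9 A), one event per direction: the focal residue's
#' type and secondary structure with the partner's type as the contact
#' class.
#'
#' @inheritParams csp_states
#' @return data.frame of events: `type` = focal residue type, `state` =
#'   `ss_i:type_j`.
#' @export
cdp_pairs <- function(model, atom_kind = c("ca", "cb"),
                      config = mass_config()) {
  atom_kind <- match.arg(atom_kind)
  X <- rep_coords(model, atom_kind)
  px <- pair_index(X)
  if (is.null(px)) return(ev_frame(character(0), character(0)))
  i <- px$i; j <- px$j
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  keep <- abs(i - j) >= config$cdp_min_sep & d < config$cdp_max_dist
  if (!any(keep)) return(ev_frame(character(0), character(0)))
  i <- i[keep]; j <- j[keep]
  foc <- c(i, j)                     # both directions: each residue focal once
  par <- c(j, i)
  ok <- !is.na(model$ss3[foc])
  ev_frame(model$seq[foc[ok]],
           paste(model$ss3[foc[ok]], model$seq[par[ok]], sep = ":"))
}

#' Relative solvent accessibility states
#'
#' Assigned relative accessibility binned evenly over `[0, 1]` into
#' `rsap_n` classes (`rsa == 1` in the top class). Residues with no
#' assignment are skipped.
#'
#' @inheritParams pseudo_bond_angle_states
#' @return data.frame of events: `type` = residue type, `state` = `ss:c10`.
#' @export
rsap_states <- function(model, config = mass_config()) {
  ok <- which(!is.na(model$rsa) & !is.na(model$ss3))
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  cls <- bin_index(model$rsa[ok], 0, 1, config$rsap_n)
  ev_frame(model$seq[ok], paste(model$ss3[ok], cls, sep = ":"))
}

#' Per-Ca bounded Voronoi volumes
#'
#' Volume of each Ca atom's Voronoi cell among all Ca atoms, intersected
#' with a ball of radius `vdp_ball` (8 A), estimated by deterministic grid
#' sampling at `vdp_grid` (0.8 A) spacing. The grid is evaluated in the
#' principal-axes frame of the Ca cloud so the volumes are invariant under
#' rigid-body transforms of the model.
#'
#' @inheritParams pseudo_bond_angle_states
#' @return Numeric vector of volumes (A^3), `NA` where Ca is missing.
#' @export
ca_volumes <- function(model, config = mass_config()) {
  X <- atom_coords(model, "CA")
  L <- n_residues(model)
  ok <- which(apply(is.finite(X), 1, all))
  vol <- rep(NA_real_, L)
  if (!length(ok)) return(vol)
  Xc <- canonical_frame(X[ok, , drop = FALSE])
  h <- config$vdp_grid
  r <- config$vdp_ball
  g <- seq(-r, r, by = h)
  tmpl <- as.matrix(expand.grid(x = g, y = g, z = g))
  tmpl <- tmpl[rowSums(tmpl^2) <= r^2, , drop = FALSE]
  cell <- h^3
  for (k in seq_along(ok)) {
    pts <- sweep(tmpl, 2, Xc[k, ], "+")
    ## nearest-site test against sites within reach of the ball
    cand <- which(sqrt(rowSums(sweep(Xc, 2, Xc[k, ])^2)) <= 2 * r)
    D2 <- cross_dist(pts, Xc[cand, , drop = FALSE])^2
    own <- rowSums(tmpl^2)
    inside <- own <= apply(D2, 1, min) + 1e-9
    vol[ok[k]] <- sum(inside) * cell
  }
  vol
}

#' Volume-dependent states
#'
#' Bounded Voronoi volume of each Ca (see [ca_volumes()]) binned evenly over
#' `[vdp_lo, vdp_hi]` ([10, 30] A^3) into `vdp_n` classes, clamped.
#'
#' @inheritParams pseudo_bond_angle_states
#' @return data.frame of events: `type` = residue type, `state` = `ss:c10`.
#' @export
vdp_states <- function(model, config = mass_config()) {
  vol <- ca_volumes(model, config)
  ok <- which(!is.na(vol) & !is.na(model$ss3))
  if (!length(ok)) return(ev_frame(character(0), character(0)))
  cls <- bin_index(vol[ok], config$vdp_lo, config$vdp_hi, config$vdp_n)
  ev_frame(model$seq[ok], paste(model$ss3[ok], cls, sep = ":"))
}

## dispatcher: potential id -> event frame
emit_states <- function(model, potential_id, config = mass_config()) {
  switch(potential_id,
    pap = pseudo_bond_angle_states(model, config),
    tap = torsion_states(model, config),
    aspa = aspa_states(model, config),
    rsap = rsap_states(model, config),
    vdp = vdp_states(model, config),
    aspr_ca = aspr_states(model, "ca", config),
    aspr_cb = aspr_states(model, "cb", config),
    cdp_ca = cdp_pairs(model, "ca", config),
    cdp_cb = cdp_pairs(model, "cb", config),
    csp_ca = csp_states(model, "ca", config),
    csp_cb = csp_states(model, "cb", config),
    ddp_ca = ddp_pairs(model, "ca", config),
    ddp_cb = ddp_pairs(model, "cb", config),
    ssdp_ca = ssdp_pairs(model, "ca", config),
    ssdp_cb = ssdp_pairs(model, "cb", config),
    stop("unknown potential: ", potential_id))
}

#' Score a model against a reference
#'
#' Each of the 15 potential scores is the sum, over the model's emitted
#' state events, of the reference energy of that `(type, state)`; states
#' unseen in the reference contribute 0.
#'
#' @param model annotated [protein_model] (`ss3`/`rsa` assigned with
#'   [assign_ss_rsa()] if missing).
#' @param reference a `mass_reference` from [build_reference()] /
#'   [load_reference()].
#' @param config optional [mass_config()]; must match the reference's.
#' @return Named numeric vector of 15 energies (kcal/mole), in
#'   [potential_names()] order.
#' @export
score_model <- function(model, reference, config = NULL) {
  if (!inherits(reference, "mass_reference"))
    stop("reference must be a mass_reference")
  if (!is.null(config) && !isTRUE(all.equal(config, reference$config)))
    stop("config conflicts with the reference's configuration")
  cfg <- reference$config
  if (anyNA(model$ss3) || anyNA(model$rsa)) model <- assign_ss_rsa(model)
  out <- vapply(potential_names(), function(p) {
    ev <- emit_states(model, p, cfg)
    if (nrow(ev) == 0) return(0)
    sum(energy_lookup(reference$tables[[p]]$energy, ev$type, ev$state))
  }, 0)
  out
}
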