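# Synthetic structures: ideal backbone chains built from internal
# coordinates, Gaussian-perturbation decoys, a Kabsch-based GDT-TS labeler,
# and complete labeled per-target datasets.

## ideal backbone internal coordinates (Engh-Huber-like averages)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ca_cb = 1.530,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5, ang_c_ca_cb = 110.1,
                tor_n_c_ca_cb = 123.0)

## Build a backbone-complete chain (N, CA, C, O, CB; no CB for glycine)
## from per-residue (phi, psi) with trans peptide bonds.
build_chain <- function(phi, psi, sequence, id) {
  n <- length(phi)
  stopifnot(length(psi) == n, nchar(sequence) == n)
  seq1 <- strsplit(sequence, "")[[1]]
  if (!all(seq1 %in% AA1)) stop("non-standard residue in sequence")
  g <- BB_GEOM
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$ca_c *
    c(cos(pi - g$ang_n_ca_c * pi / 180), sin(pi - g$ang_n_ca_c * pi / 180), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, 180)   # omega = trans
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    psi_i <- if (i < n) psi[i] else 0
    O <- nerf_place(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, psi_i + 180)
    res <- data.frame(res_index = i - 1L,
                      aa = seq1[i],
                      atom = c("N", "CA", "C", "O"),
                      x = c(N[i, 1], CA[i, 1], C[i, 1], O[1]),
                      y = c(N[i, 2], CA[i, 2], C[i, 2], O[2]),
                      z = c(N[i, 3], CA[i, 3], C[i, 3], O[3]),
                      stringsAsFactors = FALSE)
    if (seq1[i] != "G") {
      CB <- nerf_place(N[i, ], C[i, ], CA[i, ],
                       g$ca_cb, g$ang_c_ca_cb, g$tor_n_c_ca_cb)
      res <- rbind(res, data.frame(res_index = i - 1L, aa = seq1[i],
                                   atom = "CB", x = CB[1], y = CB[2],
                                   z = CB[3], stringsAsFactors = FALSE))
    }
    rows[[i]] <- res
  }
  protein_model(id, do.call(rbind, rows))
}

#' Build an ideal alpha-helix
#'
#' Backbone-complete poly-alanine (or given sequence) helix built from the
#' canonical helical dihedrals (phi, psi) = (-57, -47) degrees, which give
#' the standard 1.5 A rise and ~100 degrees twist per residue.
#'
#' @param n number of residues (at least 3).
#' @param sequence optional one-letter sequence of length `n`.
#' @param id model id.
#' @return A [protein_model].
#' @export
build_helix <- function(n, sequence = NULL, id = "helix") {
  if (n < 3) stop("need at least 3 residues")
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  build_chain(rep(-57, n), rep(-47, n), sequence, id)
}

#' Build a fully extended chain
#'
#' Backbone-complete chain with phi = psi = 180 degrees.
#'
#' @inheritParams build_helix
#' @return A [protein_model].
#' @export
build_extended <- function(n, sequence = NULL, id = "extended") {
  if (n < 3) stop("need at least 3 residues")
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  build_chain(rep(180, n), rep(180, n), sequence, id)
}

## helix first half, extended second half
build_mixed <- function(n, sequence = NULL, id = "mixed") {
  if (n < 6) stop("need at least 6 residues")
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  h <- floor(n / 2)
  build_chain(c(rep(-57, h), rep(180, n - h)),
              c(rep(-47, h), rep(180, n - h)), sequence, id)
}

#' Perturb a model into a decoy
#'
#' Adds independent zero-mean Gaussian displacement (standard deviation
#' `amplitude`, per coordinate of every atom).
#'
#' @param model a [protein_model].
#' @param amplitude displacement scale in Angstrom (`>= 0`).
#' @param seed integer seed.
#' @param id decoy id.
#' @return The perturbed [protein_model] (annotations cleared).
#' @export
perturb_model <- function(model, amplitude, seed,
                          id = paste0(model$id, "_decoy")) {
  stopifnot(amplitude >= 0)
  set.seed(seed)
  n <- nrow(model$atoms)
  model$atoms$x <- model$atoms$x + stats::rnorm(n, 0, amplitude)
  model$atoms$y <- model$atoms$y + stats::rnorm(n, 0, amplitude)
  model$atoms$z <- model$atoms$z + stats::rnorm(n, 0, amplitude)
  model$id <- id
  model$ss3 <- rep(NA_character_, n_residues(model))
  model$rsa <- rep(NA_real_, n_residues(model))
  model
}

#' GDT-TS of a model against a native structure
#'
#' Single global Kabsch least-squares superposition of the shared Ca atoms
#' followed by the standard score: the mean over thresholds 1, 2, 4 and 8 A
#' of the percentage of Ca atoms within the threshold. Deliberately simpler
#' than LGA's segment search, and deterministic.
#'
#' @param model,native [protein_model]s with equal residue counts.
#' @return Score in `[0, 100]`.
#' @export
gdt_ts <- function(model, native) {
  if (n_residues(model) != n_residues(native))
    stop("residue count mismatch: ", n_residues(model), " vs ",
         n_residues(native))
  A <- atom_coords(model, "CA")
  B <- atom_coords(native, "CA")
  ok <- apply(is.finite(A), 1, all) & apply(is.finite(B), 1, all)
  if (!any(ok)) stop("no shared Ca atoms")
  Af <- kabsch_superpose(A[ok, , drop = FALSE], B[ok, , drop = FALSE])
  d <- sqrt(rowSums((Af - B[ok, , drop = FALSE])^2))
  mean(vapply(c(1, 2, 4, 8), function(th) 100 * mean(d <= th), 0))
}

#' Default decoy perturbation ladder
#'
#' Amplitudes (A) cycled across a target's decoys to guarantee a wide
#' spread of GDT-TS labels.
#'
#' @return Numeric vector of amplitudes.
#' @export
amplitude_ladder <- function() c(0.25, 0.5, 1, 2, 4, 8)

#' Generate a labeled synthetic decoy dataset
#'
#' Per target: a random chain length in 20..60, a random fold (helix,
#' extended, or helix+extended), a random sequence, and `models_per_target`
#' decoys perturbed along the amplitude ladder; every decoy is labeled with
#' its GDT-TS against the native by [gdt_ts()]. Fully seeded.
#'
#' @param n_targets number of targets (`>= 1`).
#' @param models_per_target decoys per target.
#' @param seed integer seed.
#' @return List of `synthetic_target`s: `target_id`, `native`, `decoys`
#'   (list of models) and `labels` (GDT-TS in `[0, 100]`).
#' @export
make_dataset <- function(n_targets, models_per_target, seed = 1) {
  stopifnot(n_targets >= 1, models_per_target >= 1)
  set.seed(seed)
  lens <- sample(20:60, n_targets, replace = TRUE)
  folds <- sample(c("helix", "extended", "mixed"), n_targets, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA1, L, replace = TRUE), collapse = ""), "")
  decoy_seeds <- matrix(sample.int(1e6, n_targets * models_per_target),
                        n_targets, models_per_target)
  lapply(seq_len(n_targets), function(t) {
    tid <- sprintf("T%03d", t)
    native <- switch(folds[t],
                     helix = build_helix(lens[t], seqs[t], id = tid),
                     extended = build_extended(lens[t], seqs[t], id = tid),
                     mixed = build_mixed(lens[t], seqs[t], id = tid))
    amps <- rep(amplitude_ladder(), length.out = models_per_target)
    decoys <- lapply(seq_len(models_per_target), function(m) {
      perturb_model(native, amps[m], seed = decoy_seeds[t, m],
                    id = sprintf("%s_M%03d", tid, m))
    })
    labels <- vapply(decoys, gdt_ts, 0, native = native)
    structure(list(target_id = tid, native = native, decoys = decoys,
                   labels = labels), class = "synthetic_target")
  })
}
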