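# Shared fixtures: in-code PDB text, random annotated models, and slow
# brute-force re-implementations of the potential state emitters used as
# independent oracles.

aa_letters <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

## one PDB ATOM line (fixed-width format)
pdb_line <- function(serial, name, resn, resno, x, y, z,
                     chain = "A", altloc = " ", occ = 1, rec = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resn, chain, resno, x, y, z, occ, 0,
          substr(name, 1, 1))
}

## hand-written 5-residue backbone-only PDB text
tiny_pdb_text <- function() {
  lines <- character()
  s <- 0
  for (i in 1:5) {
    for (at in c("N", "CA", "C", "O")) {
      s <- s + 1
      lines <- c(lines, pdb_line(s, at, "ALA", i,
                                 i * 3.8 + s * 0.01, s * 0.1, 0))
    }
  }
  c(lines, "END")
}

write_tiny_pdb <- function(lines = tiny_pdb_text()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

## a random annotated model: perturbed helix/extended with random sequence
random_model <- function(L = 25, seed = 1, fold = c("helix", "extended"),
                         amp = 0.8) {
  fold <- match.arg(fold)
  set.seed(seed)
  sq <- paste(sample(aa_letters, L, replace = TRUE), collapse = "")
  m <- if (fold == "helix") build_helix(L, sq, id = paste0("rm", seed))
       else build_extended(L, sq, id = paste0("rm", seed))
  m <- perturb_model(m, amp, seed = seed + 1000, id = m$id)
  suppressWarnings(assign_ss_rsa(m))
}

rigid_copy <- function(model, seed = 99) {
  set.seed(seed)
  R <- massqa:::random_rotation()
  massqa:::transform_model(model, R, stats::runif(3, -20, 20))
}

## ---- brute-force emitters (independent O(L^2) oracles, plain loops) ------

bf_events <- function(types, states) {
  if (!length(types)) return(character(0))
  sort(paste(types, states, sep = " | "))
}

emitter_events <- function(ev) bf_events(ev$type, ev$state)

bf_rep <- function(model, kind) {
  atom_coords(model, if (kind == "ca") "CA" else "CB", gly_ca = TRUE)
}

bf_bin <- function(v, lo, hi, n) {
  k <- floor(n * (v - lo) / (hi - lo))
  if (v >= hi) k <- n - 1
  if (v < lo) k <- 0
  k
}

bf_pap <- function(model) {
  L <- n_residues(model)
  Xs <- list(N = atom_coords(model, "N"), CA = atom_coords(model, "CA"),
             C = atom_coords(model, "C"))
  ty <- st <- character(0)
  for (i in 2:(L - 1)) {
    cls <- integer(0)
    ok <- TRUE
    for (X in Xs) {
      if (any(!is.finite(c(X[i - 1, ], X[i, ], X[i + 1, ])))) { ok <- FALSE; break }
      cls <- c(cls, bf_bin(point_angle(X[i - 1, ], X[i, ], X[i + 1, ]), 0, 180, 6))
    }
    if (!ok || is.na(model$ss3[i])) next
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], cls[1], cls[2], cls[3], sep = ":"))
  }
  bf_events(ty, st)
}

bf_tap <- function(model) {
  L <- n_residues(model)
  di <- massqa:::backbone_dihedrals(model)
  cl <- function(v) {
    if (is.na(v)) return(NA_integer_)
    if (v == -180) v <- 180
    as.integer(bf_bin(v, -180, 180, 9))
  }
  cphi <- vapply(di$phi, cl, 0L)
  cpsi <- vapply(di$psi, cl, 0L)
  p5 <- function(a) {
    if (a[1] == a[2] && a[1] == a[3]) 1
    else if (a[1] != a[2] && a[2] != a[3] && a[1] != a[3]) 2
    else if (a[1] == a[2]) 3 else if (a[1] == a[3]) 4 else 5
  }
  p4 <- function(a) {
    if (a[2] == a[1] && a[2] == a[3]) 1
    else if (a[2] != a[1] && a[2] != a[3]) 2
    else if (a[2] == a[1]) 3 else 4
  }
  ty <- st <- character(0)
  for (i in 2:(L - 1)) {
    f <- cphi[(i - 1):(i + 1)]
    s <- cpsi[(i - 1):(i + 1)]
    if (anyNA(c(f, s)) || is.na(model$ss3[i])) next
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], p5(f), p5(s), p4(f), p4(s), sep = ":"))
  }
  bf_events(ty, st)
}

bf_csp <- function(model, kind) {
  X <- bf_rep(model, kind)
  ok <- which(apply(is.finite(X), 1, all) & !is.na(model$ss3))
  ctr <- colMeans(X[ok, , drop = FALSE])
  rg <- 0.395 * n_residues(model)^0.6 + 7.257
  ty <- st <- character(0)
  for (i in ok) {
    d <- sqrt(sum((X[i, ] - ctr)^2))
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], bf_bin(d, 0, 3 * rg, 30), sep = ":"))
  }
  bf_events(ty, st)
}

bf_aspr <- function(model, kind) {
  X <- bf_rep(model, kind)
  ok <- which(apply(is.finite(X), 1, all) & !is.na(model$ss3))
  ty <- st <- character(0)
  for (i in ok) {
    cnt <- 0
    for (j in ok) {
      if (j != i && sqrt(sum((X[i, ] - X[j, ])^2)) <= 11) cnt <- cnt + 1
    }
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], bf_bin(cnt, 0, 50, 25), sep = ":"))
  }
  bf_events(ty, st)
}

bf_aspa <- function(model) {
  ha <- massqa:::heavy_atoms(model)
  tps <- atom_type_40(massqa:::aa1_to_3(ha$aa), ha$atom)
  keep <- which(!is.na(tps))
  X <- as.matrix(ha[, c("x", "y", "z")])
  ty <- st <- character(0)
  for (i in keep) {
    cnt <- 0
    for (j in keep) {
      if (j != i && sqrt(sum((X[i, ] - X[j, ])^2)) <= 8) cnt <- cnt + 1
    }
    ty <- c(ty, tps[i])
    st <- c(st, as.character(bf_bin(cnt, 50, 200, 30)))
  }
  bf_events(ty, st)
}

bf_ddp <- function(model, kind) {
  X <- bf_rep(model, kind)
  L <- n_residues(model)
  ty <- st <- character(0)
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    if (j - i < 3) next
    if (any(!is.finite(c(X[i, ], X[j, ])))) next
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (d < 5 || d > 25) next
    ty <- c(ty, paste(sort(c(model$seq[i], model$seq[j])), collapse = ":"))
    st <- c(st, as.character(bf_bin(d, 5, 25, 40)))
  }
  bf_events(ty, st)
}

bf_ssdp <- function(model, kind) {
  X <- bf_rep(model, kind)
  L <- n_residues(model)
  ty <- st <- character(0)
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    if (any(!is.finite(c(X[i, ], X[j, ])))) next
    if (sqrt(sum((X[i, ] - X[j, ])^2)) > 8) next
    if (j - i > 300) next
    ty <- c(ty, paste(sort(c(model$seq[i], model$seq[j])), collapse = ":"))
    st <- c(st, as.character(bf_bin(j - i, 0, 300, 60)))
  }
  bf_events(ty, st)
}

bf_cdp <- function(model, kind) {
  X <- bf_rep(model, kind)
  L <- n_residues(model)
  ty <- st <- character(0)
  for (i in 1:L) for (j in 1:L) {
    if (i == j || abs(i - j) < 6) next
    if (any(!is.finite(c(X[i, ], X[j, ])))) next
    if (sqrt(sum((X[i, ] - X[j, ])^2)) >= 9) next
    if (is.na(model$ss3[i])) next
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], model$seq[j], sep = ":"))
  }
  bf_events(ty, st)
}

bf_rsap <- function(model) {
  ok <- which(!is.na(model$rsa) & !is.na(model$ss3))
  ty <- st <- character(0)
  for (i in ok) {
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], bf_bin(model$rsa[i], 0, 1, 10), sep = ":"))
  }
  bf_events(ty, st)
}

bf_vdp <- function(model) {
  X <- atom_coords(model, "CA")
  ok <- which(apply(is.finite(X), 1, all))
  Xc <- massqa:::canonical_frame(X[ok, , drop = FALSE])
  g <- seq(-8, 8, by = 0.8)
  tmpl <- as.matrix(expand.grid(g, g, g))
  tmpl <- tmpl[rowSums(tmpl^2) <= 64, , drop = FALSE]
  ty <- st <- character(0)
  for (k in seq_along(ok)) {
    inside <- 0
    for (p in seq_len(nrow(tmpl))) {
      pt <- tmpl[p, ] + Xc[k, ]
      own <- sum(tmpl[p, ]^2)
      d2 <- rowSums(sweep(Xc, 2, pt)^2)
      if (!any(d2 < own - 1e-9)) inside <- inside + 1
    }
    vol <- inside * 0.8^3
    i <- ok[k]
    if (is.na(model$ss3[i])) next
    ty <- c(ty, model$seq[i])
    st <- c(st, paste(model$ss3[i], bf_bin(vol, 10, 30, 10), sep = ":"))
  }
  bf_events(ty, st)
}

## planted-signal feature matrix for regressor tests: noise everywhere,
## signal (label + noise) in three named MASS features
planted_features <- function(dataset, seed = 7,
                             planted = c("pot_ddp_ca", "pot_rsap",
                                         "pot_csp_ca")) {
  y <- unlist(lapply(dataset, `[[`, "labels"))
  groups <- unlist(lapply(dataset, function(t)
    rep(t$target_id, length(t$labels))))
  set.seed(seed)
  X <- matrix(stats::rnorm(length(y) * 70), length(y), 70,
              dimnames = list(NULL, feature_names()))
  for (p in planted) X[, p] <- y + stats::rnorm(length(y), 0, 5)
  list(X = X, y = y, groups = groups, planted = planted)
}
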