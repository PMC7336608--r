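cfg <- mass_config()

test_that("pseudo-bond angle states bin collinear and right-angle triples", {
  ## fabricate a 3-residue chain with collinear N and CA traces
  at <- do.call(rbind, lapply(0:2, function(i) {
    data.frame(res_index = i, aa = "A",
               atom = c("N", "CA", "C"),
               x = c(0, 1.5, 2.5) + i * 4,
               y = c(0, 0, if (i == 1) 2.5 else 0),  # right angle at C_1
               z = 0, stringsAsFactors = FALSE)
  }))
  m <- protein_model("toy", at, ss3 = rep("C", 3), rsa = rep(0.5, 3))
  ev <- pseudo_bond_angle_states(m, cfg)
  expect_equal(nrow(ev), 1)                    # only the middle residue
  parts <- strsplit(ev$state, ":")[[1]]
  expect_equal(parts[2], "5")                  # theta_N = 180 -> top class
  ## theta_C at C_1: formed by C_0=(2.5,0), C_1=(6.5,2.5), C_2=(10.5,0):
  ## symmetric, not right angle; recompute directly for the assertion
  th <- point_angle(c(2.5, 0, 0), c(6.5, 2.5, 0), c(10.5, 0, 0))
  expect_equal(parts[4], as.character(bin_index(th, 0, 180, 6)))
})

test_that("ideal helix pseudo-bond angles are tightly clustered", {
  h <- suppressWarnings(assign_ss_rsa(build_helix(20)))
  ev <- pseudo_bond_angle_states(h, cfg)
  ca_cls <- as.integer(vapply(strsplit(ev$state, ":"), `[`, "", 3))
  expect_lte(diff(range(ca_cls)), 1)
})

test_that("torsion pattern classes follow the equality rules", {
  expect_equal(massqa:::pattern5(2, 2, 2), 1L)
  expect_equal(massqa:::pattern5(1, 5, 9), 2L)
  expect_equal(massqa:::pattern5(2, 2, 7), 3L)
  expect_equal(massqa:::pattern5(2, 5, 2), 4L)
  expect_equal(massqa:::pattern5(5, 2, 2), 5L)
  expect_equal(massqa:::pattern4(2, 2, 2), 1L)
  expect_equal(massqa:::pattern4(2, 5, 2), 2L)
  expect_equal(massqa:::pattern4(4, 4, 7), 3L)
  expect_equal(massqa:::pattern4(7, 4, 4), 4L)
})

test_that("helix torsion states are the all-equal pattern", {
  h <- suppressWarnings(assign_ss_rsa(build_helix(12)))
  ev <- torsion_states(h, cfg)
  expect_gt(nrow(ev), 0)
  for (s in ev$state) {
    parts <- strsplit(s, ":")[[1]]
    expect_equal(parts[2:5], c("1", "1", "1", "1"))
  }
})

test_that("static radius of gyration matches the regression formula", {
  expect_equal(static_rg(100), 0.395 * 100^0.6 + 7.257)
  expect_lt(abs(static_rg(100) - 13.517), 1e-2)
})

test_that("centrosymmetric states clamp at the centroid and far field", {
  at <- data.frame(res_index = 0:6, aa = "A", atom = "CA",
                   x = c(0, 0, 0, 0, 0, 0, 1000), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  m <- protein_model("toy", at, ss3 = rep("C", 7), rsa = rep(0.5, 7))
  ev <- csp_states(m, "ca", cfg)
  cls <- as.integer(vapply(strsplit(ev$state, ":"), `[`, "", 2))
  expect_equal(cls[7], 29L)                    # beyond 3*Rg clamps to top
  expect_equal(cls[1], bin_index(1000 / 7, 0, 3 * static_rg(7), 30))
})

test_that("residue-level surface counts match brute-force neighbours", {
  ## 3 residues all within 11 A pairwise -> every count 2 -> class 1
  at <- data.frame(res_index = 0:2, aa = c("A", "V", "W"), atom = "CA",
                   x = c(0, 5, 9), y = 0, z = 0, stringsAsFactors = FALSE)
  m <- protein_model("toy", at, ss3 = rep("C", 3), rsa = rep(0.5, 3))
  ev <- aspr_states(m, "ca", cfg)
  expect_equal(vapply(strsplit(ev$state, ":"), `[`, "", 2), rep("1", 3))
  ## isolated single residue -> count 0 -> class 0
  m1 <- protein_model("one", at[1, ], ss3 = "C", rsa = 0.5)
  expect_equal(aspr_states(m1, "ca", cfg)$state, "C:0")
})

test_that("atomic surface typing covers the full standard heavy-atom set", {
  expect_equal(length(massqa:::ATOM40_GROUPS), 40L)
  dict <- list(
    ALA = "CB", ARG = c("CB","CG","CD","NE","CZ","NH1","NH2"),
    ASN = c("CB","CG","OD1","ND2"), ASP = c("CB","CG","OD1","OD2"),
    CYS = c("CB","SG"), GLN = c("CB","CG","CD","OE1","NE2"),
    GLU = c("CB","CG","CD","OE1","OE2"), GLY = character(0),
    HIS = c("CB","CG","ND1","CD2","CE1","NE2"),
    ILE = c("CB","CG1","CG2","CD1"), LEU = c("CB","CG","CD1","CD2"),
    LYS = c("CB","CG","CD","CE","NZ"), MET = c("CB","CG","SD","CE"),
    PHE = c("CB","CG","CD1","CD2","CE1","CE2","CZ"), PRO = c("CB","CG","CD"),
    SER = c("CB","OG"), THR = c("CB","OG1","CG2"),
    TRP = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
    TYR = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
    VAL = c("CB","CG1","CG2"))
  for (res in names(dict)) {
    atoms <- c("N", "CA", "C", "O", "OXT", dict[[res]])
    expect_false(anyNA(atom_type_40(rep(res, length(atoms)), atoms)),
                 info = res)
  }
  ## backbone O shared across residues; glycine CA kept apart
  expect_equal(atom_type_40("GLY", "O"), atom_type_40("ALA", "O"))
  expect_false(atom_type_40("GLY", "CA") == atom_type_40("ALA", "CA"))
  expect_true(is.na(atom_type_40("ALA", "H")))
})

test_that("atomic surface counts clamp sparse and bin dense packings", {
  m <- random_model(20, seed = 4)
  ev <- aspa_states(m, cfg)
  ## synthetic backbone-only models are far below 50 neighbours: class 0
  expect_true(all(ev$state == "0"))
  expect_equal(bin_index(125, 50, 200, 30), 15L)
  expect_equal(bin_index(49, 50, 200, 30), 0L)
})

test_that("distance-pair events respect separation and range rules", {
  mkpair <- function(d, sep) {
    ## pair (first, last) at separation `sep` and distance `d`; middle
    ## residues parked far away so they emit nothing
    n <- sep + 1
    x <- c(0, rep(0, n - 2), d)
    y <- c(0, 1e5 * seq_len(n - 2), 0)
    at <- data.frame(res_index = 0:sep, aa = "A", atom = "CA",
                     x = x, y = y, z = 0, stringsAsFactors = FALSE)
    protein_model("p", at, ss3 = rep("C", n), rsa = rep(0.5, n))
  }
  ## |i-j| == 2 -> no event even at valid distance
  m <- mkpair(10, 2)
  expect_equal(nrow(ddp_pairs(m, "ca", cfg)), 0)
  ## d = 5.0 -> class 0; d = 25.0 -> class 39
  m5 <- mkpair(5, 3)
  ev5 <- ddp_pairs(m5, "ca", cfg)
  expect_equal(ev5$state, "0")
  ev25 <- ddp_pairs(mkpair(25, 3), "ca", cfg)
  expect_equal(ev25$state, "39")
  ## out-of-range distances are rejected, not clamped
  expect_equal(nrow(ddp_pairs(mkpair(4.2, 3), "ca", cfg)), 0)
  expect_equal(nrow(ddp_pairs(mkpair(26, 3), "ca", cfg)), 0)
})

test_that("separation-pair events bin |i-j| and cut at 8 A", {
  mk <- function(d, sep) {
    n <- sep + 1
    x <- c(0, rep(0, n - 2), d)
    y <- c(0, 1e5 * seq_len(n - 2), 0)
    at <- data.frame(res_index = 0:sep, aa = "A", atom = "CA",
                     x = x, y = y, z = 0, stringsAsFactors = FALSE)
    protein_model("p", at, ss3 = rep("C", n), rsa = rep(0.5, n))
  }
  ev <- ssdp_pairs(mk(6, 4), "ca", cfg)
  expect_equal(ev$state, "0")                  # separation 4 -> class 0
  expect_equal(nrow(ssdp_pairs(mk(8.5, 4), "ca", cfg)), 0)
  expect_equal(bin_index(300, 0, 300, 60), 59L)
})

test_that("contact-dependent events are ordered and gated by separation", {
  base_x <- c(0, 100, 200, 300, 400, 500, 600)
  at <- data.frame(res_index = 0:6, aa = c("A", "V", "L", "I", "F", "Y", "W"),
                   atom = "CA", x = base_x, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  at$x[7] <- 8.9                               # residue 6 near residue 0
  m <- protein_model("p", at, ss3 = rep("H", 7), rsa = rep(0.5, 7))
  ev <- cdp_pairs(m, "ca", cfg)
  expect_equal(nrow(ev), 2)                    # one event per direction
  expect_setequal(paste(ev$type, ev$state), c("A H:W", "W H:A"))
  ## separation 5 at close distance emits nothing
  at$x <- base_x
  at$x[6] <- 5                                 # residue 5 near residue 0, sep 5
  m2 <- protein_model("p", at, ss3 = rep("H", 7), rsa = rep(0.5, 7))
  expect_equal(nrow(cdp_pairs(m2, "ca", cfg)), 0)
  ## an ideal helix has no contacts at separation >= 6 under 9 A
  h <- suppressWarnings(assign_ss_rsa(build_helix(30)))
  X <- atom_coords(h, "CA")
  seps <- abs(outer(1:30, 1:30, "-"))
  D <- massqa:::cross_dist(X, X)
  expect_equal(sum(seps >= 6 & D < 9) > 0, nrow(cdp_pairs(h, "ca", cfg)) > 0)
})

test_that("rsa states bin the unit interval with the top edge closed", {
  at <- data.frame(res_index = 0:2, aa = "A", atom = "CA",
                   x = (0:2) * 3.8, y = 0, z = 0, stringsAsFactors = FALSE)
  m <- protein_model("p", at, ss3 = rep("C", 3), rsa = c(0, 0.55, 1))
  ev <- rsap_states(m, cfg)
  expect_equal(vapply(strsplit(ev$state, ":"), `[`, "", 2), c("0", "5", "9"))
})

test_that("Voronoi-ball volumes shrink under crowding and are deterministic", {
  iso <- data.frame(res_index = 0L, aa = "A", atom = "CA", x = 0, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  m_iso <- protein_model("iso", iso, ss3 = "C", rsa = 0.5)
  v_iso <- ca_volumes(m_iso, cfg)
  expect_gt(v_iso, 30)                          # full ball >> bin range top
  ev <- vdp_states(m_iso, cfg)
  expect_equal(vapply(strsplit(ev$state, ":"), `[`, "", 2), "9")

  m <- random_model(15, seed = 9)
  v1 <- ca_volumes(m, cfg)
  v2 <- ca_volumes(m, cfg)
  expect_identical(v1, v2)
  ## crowding: add close neighbours around residue 1 -> smaller cell
  ca1 <- atom_coords(m, "CA")[1, ]
  crowd <- rbind(m$atoms[, c("res_index", "aa", "atom", "x", "y", "z")],
                 data.frame(res_index = 15:17, aa = "A", atom = "CA",
                            x = ca1[1] + c(2, -2, 0),
                            y = ca1[2] + c(0, 0, 2),
                            z = ca1[3], stringsAsFactors = FALSE))
  mc <- protein_model("crowd", crowd, ss3 = c(m$ss3, rep("C", 3)),
                      rsa = c(m$rsa, rep(0.5, 3)))
  expect_lt(ca_volumes(mc, cfg)[1], v1[1])
})

test_that("scoring a single-type chain against itself zeroes the potentials", {
  h <- suppressWarnings(assign_ss_rsa(build_helix(20)))     # poly-ALA
  ref <- suppressWarnings(build_reference(list(h)))
  s <- score_model(h, ref)
  ## one residue type: f_obs == f_ref for every state of every
  ## residue-typed potential
  expect_equal(unname(s["pap"]), 0, tolerance = 1e-12)
  expect_equal(unname(s["rsap"]), 0, tolerance = 1e-12)
  expect_equal(unname(s["csp_ca"]), 0, tolerance = 1e-12)
})

test_that("chain duplication doubles all local potential scores", {
  m <- random_model(20, seed = 13)
  ref <- suppressWarnings(build_reference(list(random_model(25, seed = 14))))
  a2 <- m$atoms
  a2$res_index <- a2$res_index + 20L
  a2$x <- a2$x + 1000                           # far away: a chain break
  dup <- protein_model("dup", rbind(m$atoms, a2),
                       ss3 = c(m$ss3, m$ss3), rsa = c(m$rsa, m$rsa))
  s1 <- score_model(m, ref)
  s2 <- score_model(dup, ref)
  local_pots <- setdiff(potential_names(), c("csp_ca", "csp_cb"))
  expect_equal(unname(s2[local_pots]), unname(2 * s1[local_pots]),
               tolerance = 1e-9)
})

test_that("all 15 scores are invariant under rigid-body transforms", {
  m <- random_model(28, seed = 21)
  ref <- suppressWarnings(build_reference(list(random_model(30, seed = 22),
                                               m)))
  s1 <- score_model(m, ref)
  for (sd in c(101, 202)) {
    s2 <- score_model(rigid_copy(m, seed = sd), ref)
    expect_lt(max(abs(s1 - s2)), 1e-9)
  }
})

test_that("emitters reproduce brute-force event multisets exactly", {
  for (seed in c(31, 32)) {
    m <- random_model(22, seed = seed, fold = if (seed %% 2) "helix" else
      "extended", amp = 2)
    expect_identical(emitter_events(pseudo_bond_angle_states(m, cfg)), bf_pap(m))
    expect_identical(emitter_events(torsion_states(m, cfg)), bf_tap(m))
    expect_identical(emitter_events(rsap_states(m, cfg)), bf_rsap(m))
    for (k in c("ca", "cb")) {
      expect_identical(emitter_events(csp_states(m, k, cfg)), bf_csp(m, k))
      expect_identical(emitter_events(aspr_states(m, k, cfg)), bf_aspr(m, k))
      expect_identical(emitter_events(ddp_pairs(m, k, cfg)), bf_ddp(m, k))
      expect_identical(emitter_events(ssdp_pairs(m, k, cfg)), bf_ssdp(m, k))
      expect_identical(emitter_events(cdp_pairs(m, k, cfg)), bf_cdp(m, k))
    }
    expect_identical(emitter_events(aspa_states(m, cfg)), bf_aspa(m))
  }
  m8 <- random_model(8, seed = 33, amp = 1.5)
  expect_identical(emitter_events(vdp_states(m8, cfg)), bf_vdp(m8))
})

test_that("pair emitters are symmetric under residue-order reversal", {
  m <- random_model(20, seed = 41, amp = 3)
  rev_atoms <- m$atoms
  rev_atoms$res_index <- max(m$atoms$res_index) - rev_atoms$res_index
  mr <- protein_model("rev", rev_atoms, ss3 = rev(m$ss3), rsa = rev(m$rsa))
  for (f in list(ddp_pairs, ssdp_pairs)) {
    expect_identical(emitter_events(f(m, "ca", cfg)),
                     emitter_events(f(mr, "ca", cfg)))
  }
})

test_that("emitted class indices respect declared arities", {
  for (seed in 51:53) {
    m <- random_model(26, seed = seed, amp = 2.5)
    checks <- list(
      list(pseudo_bond_angle_states(m, cfg), 2:4, cfg$pap_n),
      list(csp_states(m, "cb", cfg), 2, cfg$csp_n),
      list(aspr_states(m, "ca", cfg), 2, cfg$aspr_n),
      list(rsap_states(m, cfg), 2, cfg$rsap_n),
      list(vdp_states(m, cfg), 2, cfg$vdp_n))
    for (ch in checks) {
      parts <- strsplit(ch[[1]]$state, ":")
      for (pos in ch[[2]]) {
        cls <- as.integer(vapply(parts, `[`, "", pos))
        expect_true(all(cls >= 0 & cls < ch[[3]]))
      }
    }
    dd <- as.integer(ddp_pairs(m, "ca", cfg)$state)
    expect_true(all(dd >= 0 & dd < cfg$ddp_n))
    ss <- as.integer(ssdp_pairs(m, "ca", cfg)$state)
    expect_true(all(ss >= 0 & ss < cfg$ssdp_n))
  }
})
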