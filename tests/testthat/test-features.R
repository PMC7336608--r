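test_that("q3 counts identical positions", {
  expect_equal(q3("HHH", "HHH"), 1)
  expect_equal(q3("HHH", "HHC"), 2 / 3)
  expect_equal(q3("HEC", "CEH"), 1 / 3)
  expect_error(q3("HH", "HHH"), "length")
  expect_error(q3("HHX", "HHH"), "illegal")
})

test_that("segment overlap scores handle identity, disjointness and shifts", {
  expect_equal(sov99("HHHECC", "HHHECC"), 1)
  expect_equal(sov99("CCCCC", "HHHHH"), 0)
  expect_equal(sov_refine("HHHECC", "HHHECC"), 1)
  expect_equal(sov_refine("CCCCC", "HHHHH"), 0)

  ## one-residue segment shift, hand-enumerated:
  ## assigned CHHHHC vs predicted HHHHCC ->
  ##   H: minov 3, maxov 5, delta 2 -> 4 * 5/5 = 4 over den 4
  ##   C: seg(1) no overlap (den 1); seg(6) vs pred C(5..6): 0.5 over den 1
  ##   total (4 + 0.5) / 6 = 0.75
  pred <- "HHHHCC"
  asg <- "CHHHHC"
  expect_equal(sov99(pred, asg), 0.75)
  expect_gt(sov99(pred, asg), q3(pred, asg))
  expect_lt(sov99(pred, asg), 1)

  ## allowance scales monotonically with lambda
  s0 <- sov_refine(pred, asg, lambda = 0)
  s1 <- sov_refine(pred, asg, lambda = 1)
  expect_lt(s0, s1)
  ## lambda 0 removes the allowance entirely: H pair scores minov/maxov
  expect_equal(s0, (4 * 3 / 5 + 0.5) / 6)
})

test_that("burial agreement splits by predicted category", {
  expect_equal(unname(rsa_agreement("e-e-", c(0.5, 0.1, 0.9, 0.2))),
               c(1, 1, 1))
  expect_equal(unname(rsa_agreement("----", c(0.9, 0.8, 0.7, 0.6))),
               c(0, 0, 0))
  ## half right in each category
  r <- rsa_agreement("ee--", c(0.5, 0.1, 0.1, 0.9))
  expect_equal(unname(r), c(0.5, 0.5, 0.5))
  expect_error(rsa_agreement("ee", c(0.5)), "length")
})

test_that("pseudo amino acid composition is normalised and order-aware", {
  p <- pseaa("ACDEFGHIKLMNPQRSTVWY")
  expect_length(p, 23)
  expect_equal(sum(p), 1)
  ## homopolymer: no property differences, composition concentrates on A
  ph <- pseaa("AAAAAAAA")
  expect_equal(unname(ph["pseaa_A"]), 1)
  expect_equal(unname(ph[21:23]), c(0, 0, 0))
  ## permutation changes only the order terms
  p1 <- pseaa("ACDEFGHIKL")
  p2 <- pseaa("LKIHGFEDCA")
  expect_equal(p1[1:20] * sum(p2[1:20]) / sum(p1[1:20]), p2[1:20],
               tolerance = 1e-12)
  expect_error(pseaa("AC"), "lam")
})

test_that("radius of gyration uses backbone atoms with equal masses", {
  at <- data.frame(res_index = 0:1, aa = "A", atom = "CA",
                   x = c(0, 2), y = 0, z = 0, stringsAsFactors = FALSE)
  m <- protein_model("two", at)
  expect_equal(radius_of_gyration(m), 1)
  mm <- random_model(20, seed = 61)
  expect_equal(radius_of_gyration(rigid_copy(mm)), radius_of_gyration(mm),
               tolerance = 1e-9)
})

test_that("contact features match brute-force enumeration", {
  e <- build_extended(20)
  expect_equal(unname(contact_features(e)), c(0, 0))
  ## single engineered contact: sep 7 at 6.5 A
  x <- c(0, rep(0, 6), 6.5)
  y <- c(0, 1e4 * 1:6, 0)
  at <- data.frame(res_index = 0:7, aa = "A", atom = "CA",
                   x = x, y = y, z = 0, stringsAsFactors = FALSE)
  m <- protein_model("c1", at)
  expect_equal(unname(contact_features(m)), c(7, 6.5))
  ## dense random model vs all-pairs loop
  mm <- random_model(30, seed = 62, amp = 3)
  X <- atom_coords(mm, "CA")
  seps <- dists <- c()
  for (i in 1:29) for (j in (i + 1):30) {
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (j - i >= 6 && d < 8) { seps <- c(seps, j - i); dists <- c(dists, d) }
  }
  got <- contact_features(mm)
  if (length(seps)) {
    expect_equal(unname(got),
                 c(mean(seps), sum(dists * seps) / sum(seps)),
                 tolerance = 1e-12)
  } else {
    expect_equal(unname(got), c(0, 0))
  }
})

test_that("feature vector order is frozen and zero-fill policy applies", {
  nm <- feature_names()
  expect_length(nm, 70)
  expect_identical(nm[1:6], c("q3", "sov99", "sov_refine", "rsa_agree_buried",
                              "rsa_agree_exposed", "rsa_agree_all"))
  expect_identical(nm[7:9], c("rwplus", "goap", "dfire"))
  expect_identical(nm[33:35], c("rg", "contact_mean_sep", "contact_wmean_dist"))
  expect_identical(nm[36:50], paste0("pot_", potential_names()))
  expect_identical(nm[70], "rosetta_total")

  m <- random_model(20, seed = 63)
  ref <- suppressWarnings(build_reference(list(random_model(22, seed = 64))))
  v <- assemble_features(m, ref)
  expect_length(v, 70)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v[7:9]), c(0, 0, 0))            # no external energies
  expect_equal(unname(v[51:70]), rep(0, 20))          # no Rosetta record
  expect_equal(sum(v[10:32]), 1, tolerance = 1e-12)   # PseAA block
  expect_gte(v[["rg"]], 0)
  ## determinism
  expect_identical(assemble_features(m, ref), v)
  ## with predictions, agreement features land in [0,1]
  v2 <- assemble_features(m, ref, pred_ss = paste(m$ss3, collapse = ""),
                          pred_burial = paste(ifelse(m$rsa >= 0.25, "e", "-"),
                                              collapse = ""))
  expect_true(all(v2[1:6] >= 0 & v2[1:6] <= 1))
  expect_equal(unname(v2[1:3]), c(1, 1, 1))           # self-agreement
})

test_that("external energy records pass through into their slots", {
  m <- random_model(15, seed = 65)
  ref <- suppressWarnings(build_reference(list(m)))
  v <- assemble_features(m, ref,
                         external = list(rwplus = -1234.5, goap = -8.25,
                                         dfire = 3.5, rosetta = 1:20))
  expect_equal(unname(v[7:9]), c(-1234.5, -8.25, 3.5))
  expect_equal(unname(v[51:70]), as.numeric(1:20))
  expect_error(assemble_features(m, ref, external = list(rosetta = 1:5)),
               "20 values")
})

test_that("occlusion zeroes exactly the named group and is idempotent", {
  set.seed(1)
  X <- matrix(rnorm(3 * 70), 3, 70, dimnames = list(NULL, feature_names()))
  Xo <- occlude_features(X, "external3")
  expect_true(all(Xo[, 7:9] == 0))
  expect_identical(Xo[, -(7:9)], X[, -(7:9)])
  expect_identical(occlude_features(Xo, "external3"), Xo)
  Xm <- occlude_features(X, "MASS")
  expect_true(all(Xm[, 36:50] == 0))
  expect_error(occlude_features(X, "bogus"), "unknown feature group")
  v <- occlude_features(X[1, ], "Rosetta")
  expect_equal(unname(v[51:70]), rep(0, 20))
})
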