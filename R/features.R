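# The 70-feature global model descriptor: agreement scores, external
# energies, pseudo amino acid composition, compactness and contact
# statistics, the 15 potential scores, and Rosetta term pass-through.

#' Canonical names of the 70 features, in frozen order
#'
#' Order: positions 1-6 secondary-structure / accessibility agreement (Q3,
#' SOV'99, SOV with scalable allowance, burial agreement among predicted
#' buried / predicted exposed / all); 7-9 external potentials (RWplus, GOAP,
#' DFIRE); 10-32 pseudo amino acid composition (20 composition + 3
#' sequence-order terms); 33 radius of gyration; 34-35 contact statistics;
#' 36-50 the 15 potential scores; 51-70 Rosetta terms (19 + total).
#'
#' @return Character vector of length 70.
#' @export
feature_names <- function() {
  c("q3", "sov99", "sov_refine",
    "rsa_agree_buried", "rsa_agree_exposed", "rsa_agree_all",
    "rwplus", "goap", "dfire",
    paste0("pseaa_", AA1), paste0("pseaa_order", 1:3),
    "rg", "contact_mean_sep", "contact_wmean_dist",
    paste0("pot_", potential_names()),
    paste0("rosetta_", sprintf("%02d", 1:19)), "rosetta_total")
}

## named index ranges of the occludable feature groups
feature_groups <- function() {
  list(ss_sa = 1:6, external3 = 7:9, pseaa = 10:32, rg = 33L,
       contact = 34:35, MASS = 36:50, Rosetta = 51:70)
}

#' Burial agreement between a predicted two-state string and assigned RSA
#'
#' The assigned state is exposed when `rsa >= threshold`. Returns the
#' agreement fraction among residues predicted buried, among residues
#' predicted exposed, and over all residues; an empty category scores 0.
#'
#' @param pred_burial string over `e` (exposed) / `-` (buried); `E`/`B`
#'   also accepted.
#' @param assigned_rsa numeric vector of assigned relative accessibilities.
#' @param threshold exposure threshold (default 0.25).
#' @return Named numeric vector `(buried, exposed, all)` in `[0, 1]`.
#' @export
rsa_agreement <- function(pred_burial, assigned_rsa, threshold = 0.25) {
  p <- strsplit(pred_burial, "")[[1]]
  p[p == "E"] <- "e"
  p[p == "B"] <- "-"
  if (!all(p %in% c("e", "-"))) stop("illegal burial letter")
  if (length(p) != length(assigned_rsa))
    stop("length mismatch: ", length(p), " vs ", length(assigned_rsa))
  pred_exposed <- p == "e"
  asg_exposed <- assigned_rsa >= threshold
  agree <- pred_exposed == asg_exposed
  frac <- function(mask) if (any(mask)) mean(agree[mask]) else 0
  c(buried = frac(!pred_exposed), exposed = frac(pred_exposed),
    all = mean(agree))
}

#' Pseudo amino acid composition (type I)
#'
#' Twenty normalised composition terms plus `lam` sequence-order
#' correlation factors computed from standardised hydrophobicity,
#' hydrophilicity and side-chain mass; all `20 + lam` values sum to 1.
#'
#' @param sequence one-letter amino-acid string (standard residues).
#' @param lam number of correlation tiers (default 3, giving 23 features).
#' @param weight sequence-order weight `w` (default 0.05).
#' @return Named numeric vector of length `20 + lam`.
#' @export
pseaa <- function(sequence, lam = 3, weight = 0.05) {
  s <- strsplit(sequence, "")[[1]]
  if (!all(s %in% AA1)) stop("non-standard residue in sequence")
  L <- length(s)
  if (L <= lam) stop("sequence length (", L, ") must exceed lam (", lam, ")")
  props <- rbind(PSEAA_HYDROPHOBICITY, PSEAA_HYDROPHILICITY,
                 PSEAA_SIDE_CHAIN_MASS)
  props <- t(apply(props, 1, function(v) (v - mean(v)) / stats::sd(v)))
  corr <- function(a, b) mean((props[, a] - props[, b])^2)
  theta <- vapply(seq_len(lam), function(k) {
    mean(vapply(seq_len(L - k), function(i) corr(s[i], s[i + k]), 0))
  }, 0)
  comp <- table(factor(s, levels = AA1)) / L
  denom <- sum(comp) + weight * sum(theta)
  out <- c(as.numeric(comp), weight * theta) / denom
  names(out) <- c(paste0("pseaa_", AA1), paste0("pseaa_order", seq_len(lam)))
  out
}

#' Radius of gyration of a model
#'
#' Root-mean-square distance of the backbone N, Ca and C atoms to their
#' unweighted centroid (all atoms of interest treated as equal masses).
#'
#' @param model a [protein_model].
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(model) {
  a <- model$atoms[model$atoms$atom %in% c("N", "CA", "C"), ]
  if (nrow(a) == 0) stop("no backbone N/CA/C atoms")
  X <- as.matrix(a[, c("x", "y", "z")])
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(mean(rowSums(Xc^2)))
}

#' Residue-contact summary features
#'
#' Over all unordered Ca pairs with sequence separation at least 6 and
#' distance below 8 A: the mean sequence separation, and the mean contact
#' distance weighted by sequence separation. No contacts gives `(0, 0)`.
#'
#' @param model a [protein_model].
#' @return Named numeric vector `(mean_sep, wmean_dist)`.
#' @export
contact_features <- function(model) {
  X <- atom_coords(model, "CA")
  px <- pair_index(X)
  empty <- c(mean_sep = 0, wmean_dist = 0)
  if (is.null(px)) return(empty)
  sep <- abs(px$i - px$j)
  d <- sqrt(rowSums((X[px$i, , drop = FALSE] - X[px$j, , drop = FALSE])^2))
  keep <- sep >= 6 & d < 8
  if (!any(keep)) return(empty)
  sep <- sep[keep]
  d <- d[keep]
  c(mean_sep = mean(sep), wmean_dist = sum(d * sep) / sum(sep))
}

#' Read external energy records
#'
#' Simple adapters for externally computed scores: two-column TSV
#' (`model_id`, `score`) for RWplus / GOAP / DFIRE, and 21-column TSV
#' (`model_id` + 20 values: 19 terms and their total) for Rosetta.
#'
#' @param path TSV file with a header.
#' @param source one of `"rwplus"`, `"goap"`, `"dfire"`, `"rosetta"`.
#' @return data.frame keyed by `model_id`.
#' @export
read_external_energies <- function(path,
                                   source = c("rwplus", "goap", "dfire",
                                              "rosetta")) {
  source <- match.arg(source)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  want <- if (source == "rosetta") 21L else 2L
  if (ncol(df) != want)
    stop(source, " energy file must have ", want, " columns, found ", ncol(df))
  names(df)[1] <- "model_id"
  df
}

#' Assemble the 70-feature descriptor of one model
#'
#' Computes every feature the model itself supports and fills the rest
#' according to `policy`. Under the default zero-fill policy, missing
#' external energies (positions 7-9, 51-70) and missing prediction strings
#' (positions 1-6) are set to 0 -- the same masking the group-occlusion
#' analysis applies deliberately.
#'
#' @param model a [protein_model]; `ss3`/`rsa` assigned with
#'   [assign_ss_rsa()] if missing.
#' @param reference a `mass_reference` for the 15 potential scores.
#' @param pred_ss optional predicted 3-state string (length = model).
#' @param pred_burial optional predicted 2-state burial string.
#' @param external optional named list with any of `rwplus`, `goap`,
#'   `dfire` (scalars) and `rosetta` (20 values).
#' @param policy how to fill unavailable features; only `"zero"` is defined.
#' @return Named numeric vector of length 70 (see [feature_names()]).
#' @export
assemble_features <- function(model, reference, pred_ss = NULL,
                              pred_burial = NULL, external = NULL,
                              policy = "zero") {
  stopifnot(identical(policy, "zero"))
  if (anyNA(model$ss3) || anyNA(model$rsa)) model <- assign_ss_rsa(model)
  v <- stats::setNames(numeric(70), feature_names())

  if (!is.null(pred_ss)) {
    assigned <- paste(model$ss3, collapse = "")
    v["q3"] <- q3(pred_ss, assigned)
    v["sov99"] <- sov99(pred_ss, assigned)
    v["sov_refine"] <- sov_refine(pred_ss, assigned)
  }
  if (!is.null(pred_burial)) {
    v[c("rsa_agree_buried", "rsa_agree_exposed", "rsa_agree_all")] <-
      rsa_agreement(pred_burial, model$rsa)
  }
  for (nm in c("rwplus", "goap", "dfire"))
    if (!is.null(external[[nm]])) v[nm] <- external[[nm]]
  v[10:32] <- pseaa(paste(model$seq, collapse = ""))
  v["rg"] <- radius_of_gyration(model)
  v[c("contact_mean_sep", "contact_wmean_dist")] <- contact_features(model)
  v[36:50] <- score_model(model, reference)
  if (!is.null(external$rosetta)) {
    if (length(external$rosetta) != 20)
      stop("rosetta record must carry 20 values")
    v[51:70] <- external$rosetta
  }
  bad <- which(!is.finite(v))
  if (length(bad))
    stop("non-finite feature: ", paste(names(v)[bad], collapse = ", "))
  v
}

#' Zero out a feature group
#'
#' Sets the named group's columns to zero in a feature vector or a feature
#' matrix with canonical column order, leaving everything else untouched.
#' Groups: `ss_sa` (1-6), `external3` (7-9), `pseaa` (10-32), `rg` (33),
#' `contact` (34-35), `MASS` (36-50), `Rosetta` (51-70).
#'
#' @param X numeric vector of length 70 or matrix/data.frame with 70
#'   columns in [feature_names()] order.
#' @param group group name.
#' @return `X` with the group zeroed.
#' @export
occlude_features <- function(X, group) {
  gs <- feature_groups()
  if (!group %in% names(gs)) {
    stop("unknown feature group '", group, "'; expected one of: ",
         paste(names(gs), collapse = ", "))
  }
  idx <- gs[[group]]
  if (is.null(dim(X))) {
    stopifnot(length(X) == 70)
    X[idx] <- 0
  } else {
    stopifnot(ncol(X) == 70)
    X[, idx] <- 0
  }
  X
}
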