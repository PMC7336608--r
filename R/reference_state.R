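# Reference-state extraction: occurrence counting over a structure set and
# conversion of counts into energy lookup tables via the log-ratio potential
# formula E = RT*ln(1 + M*sigma) - RT*ln(1 + M*sigma*f_obs/f_ref).

REFERENCE_ARCHIVE_VERSION <- 1L

#' Even binning of a value into classes
#'
#' Splits `[lo, hi]` into `n` equal classes and returns the 0-based class of
#' `value`; `value == hi` maps to class `n - 1`. Values outside the range
#' follow `policy`: `"clamp"` snaps into the edge bins, `"reject"` returns
#' `NA` ("no state").
#'
#' @param value numeric vector.
#' @param lo,hi range bounds, `hi > lo`.
#' @param n number of classes.
#' @param policy `"clamp"` or `"reject"`.
#' @return Integer vector of classes in `0 .. n-1`, `NA` where rejected.
#' @export
bin_index <- function(value, lo, hi, n, policy = c("clamp", "reject")) {
  policy <- match.arg(policy)
  stopifnot(hi > lo, n >= 1)
  out <- floor(n * (value - lo) / (hi - lo))
  out[value == hi] <- n - 1
  low <- value < lo
  high <- value > hi
  if (policy == "clamp") {
    out[low] <- 0
    out[high] <- n - 1
  } else {
    out[low | high] <- NA
  }
  as.integer(out)
}

#' Potential energy of one observed state
#'
#' The log-ratio form used by all the potentials:
#' `E = RT*ln(1 + M*sigma) - RT*ln(1 + M*sigma*f_obs/f_ref)`, where `M` is
#' the number of observations for the type, `f_obs` the type-specific state
#' frequency and `f_ref` the pooled state frequency. States never observed
#' in the reference (`f_ref == 0`, hence `f_obs == 0`) score 0, the formula's
#' natural limit.
#'
#' @param M observation count for the type (vectorised).
#' @param f_obs,f_ref observed and reference frequencies, `>= 0`.
#' @param sigma dimensionless weight (default 1/50).
#' @param RT kcal/mole (default 0.582).
#' @return Energy in kcal/mole.
#' @export
potential_energy <- function(M, f_obs, f_ref, sigma = 1 / 50, RT = 0.582) {
  if (any(M < 0) || any(f_obs < 0) || any(f_ref < 0) || sigma < 0 || RT < 0)
    stop("negative inputs to potential_energy")
  ratio <- ifelse(f_ref > 0, f_obs / f_ref, 0)
  E <- RT * log(1 + M * sigma) - RT * log(1 + M * sigma * ratio)
  E[f_ref == 0] <- 0
  E
}

#' Build a count table from state events
#'
#' @param events data.frame with character columns `type` and `state`; one
#'   row per emitted state event.
#' @param potential_id identifier stored with the table.
#' @return A `count_table`: aggregated counts, per-type totals `M` and the
#'   grand total.
#' @export
count_table <- function(events, potential_id) {
  if (is.null(events) || nrow(events) == 0) {
    warning("no state events for ", potential_id, ": all-zero table")
    counts <- data.frame(type = character(), state = character(),
                         count = integer(), stringsAsFactors = FALSE)
    return(structure(list(potential_id = potential_id, counts = counts,
                          M = numeric(0), total = 0),
                     class = "count_table"))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(events))),
                          by = list(type = events$type, state = events$state),
                          FUN = sum)
  M <- tapply(agg$count, agg$type, sum)
  structure(list(potential_id = potential_id,
                 counts = agg[order(agg$type, agg$state), , drop = FALSE],
                 M = stats::setNames(as.numeric(M), names(M)),
                 total = sum(agg$count)),
            class = "count_table")
}

## merge two count tables of the same potential
merge_count_tables <- function(a, b) {
  stopifnot(a$potential_id == b$potential_id)
  both <- rbind(a$counts, b$counts)
  if (nrow(both) == 0) return(a)
  agg <- stats::aggregate(count ~ type + state, data = both, FUN = sum)
  M <- tapply(agg$count, agg$type, sum)
  structure(list(potential_id = a$potential_id,
                 counts = agg[order(agg$type, agg$state), , drop = FALSE],
                 M = stats::setNames(as.numeric(M), names(M)),
                 total = sum(agg$count)),
            class = "count_table")
}

#' Accumulate reference counts over a structure set
#'
#' Runs one potential's state emitter over every structure and sums the
#' occurrence counts.
#'
#' @param structures list of [protein_model]s with `ss3`/`rsa` assigned.
#' @param potential_id one of the 15 potential names (see
#'   [potential_names()]).
#' @param config a [mass_config()].
#' @return A `count_table`.
#' @export
accumulate_counts <- function(structures, potential_id, config = mass_config()) {
  stopifnot(length(structures) >= 1)
  ev <- lapply(structures, emit_states, potential_id = potential_id,
               config = config)
  ev <- do.call(rbind, ev)
  suppressWarnings(ct <- count_table(ev, potential_id))
  if (ct$total == 0) warning("no state events for ", potential_id)
  ct
}

#' Turn a count table into an energy lookup table
#'
#' For every `(type, state)` over the full grid of observed types and
#' states: `f_obs = counts/M[type]`, `f_ref = pooled state count / total`,
#' energy from [potential_energy()] with `M = M[type]`.
#'
#' @param counts a `count_table`.
#' @param sigma,RT potential constants.
#' @return An `energy_table` with a fast `(type, state) -> E` lookup.
#' @export
build_energy_table <- function(counts, sigma = 1 / 50, RT = 0.582) {
  ct <- counts
  types <- names(ct$M)
  states <- sort(unique(ct$counts$state))
  if (length(types) == 0 || length(states) == 0) {
    E <- stats::setNames(numeric(0), character(0))
  } else {
    grid <- expand.grid(type = types, state = states,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(grid$type, grid$state, sep = "\r")
    obs_key <- paste(ct$counts$type, ct$counts$state, sep = "\r")
    cnt <- ct$counts$count[match(key, obs_key)]
    cnt[is.na(cnt)] <- 0
    Mv <- ct$M[grid$type]
    f_obs <- ifelse(Mv > 0, cnt / Mv, 0)
    pooled <- tapply(ct$counts$count, ct$counts$state, sum)
    f_ref <- as.numeric(pooled[grid$state]) / ct$total
    E <- stats::setNames(potential_energy(Mv, f_obs, f_ref, sigma, RT), key)
  }
  structure(list(potential_id = ct$potential_id, sigma = sigma, RT = RT,
                 E = E), class = "energy_table")
}

## energy lookup; unseen (type, state) -> 0
energy_lookup <- function(etab, type, state) {
  if (length(type) == 0) return(numeric(0))
  v <- etab$E[paste(type, state, sep = "\r")]
  v[is.na(v)] <- 0
  unname(v)
}

#' Build the full reference (all 15 potentials) from a structure set
#'
#' @param structures list of [protein_model]s; `ss3`/`rsa` are assigned with
#'   [assign_ss_rsa()] where missing.
#' @param config a [mass_config()].
#' @return A `mass_reference`: count + energy tables per potential, the
#'   configuration, and a fingerprint of the structure ids.
#' @export
build_reference <- function(structures, config = mass_config()) {
  structures <- lapply(structures, function(m) {
    if (anyNA(m$ss3) || anyNA(m$rsa)) assign_ss_rsa(m) else m
  })
  ids <- sort(vapply(structures, function(m) m$id, ""))
  tabs <- lapply(potential_names(), function(p) {
    ct <- suppressWarnings(accumulate_counts(structures, p, config))
    list(counts = ct, energy = build_energy_table(ct, config$sigma, config$RT))
  })
  names(tabs) <- potential_names()
  structure(list(version = REFERENCE_ARCHIVE_VERSION, config = config,
                 fingerprint = ids, tables = tabs),
            class = "mass_reference")
}

#' Save a reference archive to JSON
#'
#' Lossless round-trip of counts, constants, bin configuration and the
#' structure-set fingerprint; energies are rebuilt on load.
#'
#' @param reference a `mass_reference`.
#' @param path output file (JSON).
#' @return `path`, invisibly.
#' @export
save_reference <- function(reference, path) {
  payload <- list(
    format = "massqa-reference",
    version = reference$version,
    config = reference$config,
    fingerprint = reference$fingerprint,
    counts = lapply(reference$tables, function(t) t$counts$counts)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a reference archive
#'
#' @param path JSON file written by [save_reference()].
#' @param config optional runtime [mass_config()]; if supplied it must equal
#'   the archived configuration.
#' @return A `mass_reference`.
#' @export
load_reference <- function(path, config = NULL) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot read reference archive ",
                                               path, ": ", conditionMessage(e)))
  if (!identical(payload$format, "massqa-reference"))
    stop("not a massqa reference archive: ", path)
  if (!identical(as.integer(payload$version), REFERENCE_ARCHIVE_VERSION))
    stop("reference archive version mismatch: file has ", payload$version,
         ", package expects ", REFERENCE_ARCHIVE_VERSION)
  arch_cfg <- do.call(mass_config, payload$config)
  if (!is.null(config) && !isTRUE(all.equal(arch_cfg, config)))
    stop("runtime configuration conflicts with the archived configuration")
  tabs <- lapply(names(payload$counts), function(p) {
    df <- payload$counts[[p]]
    if (length(df) == 0 || is.null(nrow(df)))
      df <- data.frame(type = character(), state = character(),
                       count = integer(), stringsAsFactors = FALSE)
    df$count <- as.integer(df$count)
    M <- tapply(df$count, df$type, sum)
    ct <- structure(list(potential_id = p, counts = df,
                         M = stats::setNames(as.numeric(M), names(M)),
                         total = sum(df$count)),
                    class = "count_table")
    list(counts = ct,
         energy = build_energy_table(ct, arch_cfg$sigma, arch_cfg$RT))
  })
  names(tabs) <- names(payload$counts)
  if (!setequal(names(tabs), potential_names()))
    stop("reference archive is missing potentials: ",
         paste(setdiff(potential_names(), names(tabs)), collapse = ", "))
  structure(list(version = REFERENCE_ARCHIVE_VERSION, config = arch_cfg,
                 fingerprint = payload$fingerprint, tables = tabs),
            class = "mass_reference")
}
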