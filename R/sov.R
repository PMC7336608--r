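# Secondary-structure agreement scores: Q3 and the segment-overlap family.

ss_check <- function(pred, assigned) {
  if (nchar(pred) != nchar(assigned))
    stop("length mismatch: ", nchar(pred), " vs ", nchar(assigned))
  p <- strsplit(pred, "")[[1]]
  a <- strsplit(assigned, "")[[1]]
  bad <- which(!(p %in% c("H", "E", "C")) | !(a %in% c("H", "E", "C")))
  if (length(bad)) stop("illegal letter at position ", bad[1])
  list(p = p, a = a)
}

#' Three-state secondary-structure accuracy (Q3)
#'
#' @param pred,assigned equal-length strings over `{H, E, C}`.
#' @return Fraction of identical positions, in `[0, 1]`.
#' @export
q3 <- function(pred, assigned) {
  s <- ss_check(pred, assigned)
  mean(s$p == s$a)
}

## maximal runs of one state: data.frame(start, end, len)
ss_segments <- function(x, state) {
  r <- rle(x == state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

## Segment-overlap score core. `allowance(minov, maxov, l1, l2)` returns the
## boundary-shift allowance delta for one overlapping segment pair.
sov_core <- function(pred, assigned, allowance) {
  s <- ss_check(pred, assigned)
  total_num <- 0
  total_den <- 0
  for (state in c("H", "E", "C")) {
    s1 <- ss_segments(s$a, state)          # reference segments
    s2 <- ss_segments(s$p, state)
    if (nrow(s1) == 0) next
    for (k in seq_len(nrow(s1))) {
      ov <- which(s2$start <= s1$end[k] & s2$end >= s1$start[k])
      if (length(ov) == 0) {
        total_den <- total_den + s1$len[k]
        next
      }
      for (m in ov) {
        minov <- min(s1$end[k], s2$end[m]) - max(s1$start[k], s2$start[m]) + 1
        maxov <- max(s1$end[k], s2$end[m]) - min(s1$start[k], s2$start[m]) + 1
        delta <- allowance(minov, maxov, s1$len[k], s2$len[m])
        delta <- min(delta, maxov - minov)
        total_num <- total_num + s1$len[k] * (minov + delta) / maxov
        total_den <- total_den + s1$len[k]
      }
    }
  }
  if (total_den == 0) return(0)
  min(1, total_num / total_den)
}

#' Segment-overlap score, 1999 definition
#'
#' Per-state segment overlap between predicted and assigned secondary
#' structure with the standard boundary allowance
#' `min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)`, aggregated over the
#' three states weighted by reference segment length, normalised to
#' `[0, 1]`.
#'
#' @param pred,assigned equal-length strings over `{H, E, C}`; `assigned`
#'   is the reference.
#' @return Score in `[0, 1]`.
#' @export
sov99 <- function(pred, assigned) {
  sov_core(pred, assigned, function(minov, maxov, l1, l2) {
    min(maxov - minov, minov, l1 %/% 2, l2 %/% 2)
  })
}

#' Segment-overlap score with scalable allowance
#'
#' Same aggregation as [sov99()] but the allowance is scaled by `lambda`:
#' `lambda * min(maxov - minov, minov, len1/2, len2/2)` (halves not
#' floored). `lambda = 0` gives the plain unassisted overlap ratio;
#' identical strings score 1 for every `lambda`.
#'
#' @inheritParams sov99
#' @param lambda non-negative allowance scale (default 1).
#' @return Score in `[0, 1]`.
#' @export
sov_refine <- function(pred, assigned, lambda = 1) {
  stopifnot(lambda >= 0)
  sov_core(pred, assigned, function(minov, maxov, l1, l2) {
    lambda * min(maxov - minov, minov, l1 / 2, l2 / 2)
  })
}
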