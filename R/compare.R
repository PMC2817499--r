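#' Match spots between two patterns
#'
#' Greedy nearest-neighbour matching: candidate pairs must agree within
#' `tol` relative length difference in both dimensions (length-relative so
#' the result is gel-parameter independent); ties are broken by smaller
#' Euclidean distance in `(x1, x2)`, then smaller `len_1d`, then input
#' order. Each spot participates in at most one match; unmatched spots are
#' reported as `a_only` / `b_only`. Deterministic.
#'
#' @param a,b Two [spot_pattern()]s produced under the same gel model.
#' @param tol Relative length tolerance.
#' @return Data frame with one row per match or orphan: `status`
#'   (`both`/`a_only`/`b_only`), `locus` (loci key of the a-side spot, else
#'   b-side), per-side lengths and intensities, and `intensity_ratio`
#'   (`b / a` where both present).
#' @export
match_spots <- function(a, b, tol = 0.01) {
  stopifnot(inherits(a, "rlgs_pattern"), inherits(b, "rlgs_pattern"))
  if (!same_gel(a$gel, b$gel))
    stop("patterns were produced under different gel models")
  A <- a$spots
  B <- b$spots

  pairs <- NULL
  if (nrow(A) && nrow(B)) {
    grid <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
    ok <- rel_diff(A$len_1d[grid$i], B$len_1d[grid$j]) <= tol &
      rel_diff(A$len_2d[grid$i], B$len_2d[grid$j]) <= tol
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid)) {
      d <- sqrt((A$x1[grid$i] - B$x1[grid$j])^2 +
                (A$x2[grid$i] - B$x2[grid$j])^2)
      grid <- grid[order(d, A$len_1d[grid$i], grid$i, grid$j), , drop = FALSE]
      used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
      keep <- logical(nrow(grid))
      for (r in seq_len(nrow(grid))) {
        if (!used_a[grid$i[r]] && !used_b[grid$j[r]]) {
          keep[r] <- TRUE
          used_a[grid$i[r]] <- TRUE
          used_b[grid$j[r]] <- TRUE
        }
      }
      pairs <- grid[keep, , drop = FALSE]
    }
  }

  row_of <- function(i, j) {
    has_a <- !is.na(i); has_b <- !is.na(j)
    data.frame(
      status = if (has_a && has_b) "both" else if (has_a) "a_only" else "b_only",
      locus = if (has_a) A$loci[i] else B$loci[j],
      len_1d_a = if (has_a) A$len_1d[i] else NA_integer_,
      len_2d_a = if (has_a) A$len_2d[i] else NA_integer_,
      intensity_a = if (has_a) A$intensity[i] else NA_real_,
      len_1d_b = if (has_b) B$len_1d[j] else NA_integer_,
      len_2d_b = if (has_b) B$len_2d[j] else NA_integer_,
      intensity_b = if (has_b) B$intensity[j] else NA_real_,
      intensity_ratio = if (has_a && has_b) B$intensity[j] / A$intensity[i]
                        else NA_real_,
      stringsAsFactors = FALSE
    )
  }

  out <- list()
  matched_a <- if (is.null(pairs)) integer() else pairs$i
  matched_b <- if (is.null(pairs)) integer() else pairs$j
  for (i in seq_len(nrow(A))) {
    j <- if (i %in% matched_a) matched_b[match(i, matched_a)] else NA_integer_
    out[[length(out) + 1L]] <- row_of(i, j)
  }
  for (j in setdiff(seq_len(nrow(B)), matched_b))
    out[[length(out) + 1L]] <- row_of(NA_integer_, j)
  if (!length(out))
    return(data.frame(status = character(), locus = character(),
                      len_1d_a = integer(), len_2d_a = integer(),
                      intensity_a = numeric(), len_1d_b = integer(),
                      len_2d_b = integer(), intensity_b = numeric(),
                      intensity_ratio = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Modal spot intensity of a pattern
#'
#' Default baseline for intensity classification: the most frequent spot
#' intensity (the "surrounding spots" of a pattern), ties broken towards
#' the larger value.
#'
#' @param pattern An `rlgs_pattern`.
#' @return Numeric scalar (NA for an empty pattern).
#' @export
modal_intensity <- function(pattern) {
  ints <- pattern$spots$intensity
  if (!length(ints)) return(NA_real_)
  tab <- table(ints)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  max(cand)
}

#' Classify a spot intensity relative to a baseline
#'
#' `full` when the ratio is within `tol` (relative) of 1, `half` within
#' `tol` of 0.5, `absent` when the intensity is 0, else `other`.
#'
#' @param intensity Observed spot intensity (vectorised).
#' @param baseline Full-intensity reference (> 0); see [modal_intensity()].
#' @param tol Relative tolerance of the class bands.
#' @return Character vector over `{absent, half, full, other}`.
#' @export
classify_intensity <- function(intensity, baseline, tol = 0.1) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L, baseline > 0)
  r <- intensity / baseline
  ifelse(intensity == 0, "absent",
         ifelse(abs(r - 1) <= tol, "full",
                ifelse(abs(r - 0.5) <= 0.5 * tol, "half", "other")))
}

#' Intensity of the spot at given fragment lengths
#'
#' Finds the spot whose lengths agree with `(len_1d, len_2d)` within `tol`
#' in both dimensions (closest first); returns its intensity, or 0 when no
#' such spot exists.
#'
#' @param pattern An `rlgs_pattern`.
#' @param len_1d,len_2d Reference fragment lengths in bp.
#' @param tol Relative length tolerance.
#' @return Numeric scalar.
#' @export
spot_intensity_at <- function(pattern, len_1d, len_2d, tol = 0.01) {
  sp <- pattern$spots
  ok <- rel_diff(sp$len_1d, len_1d) <= tol & rel_diff(sp$len_2d, len_2d) <= tol
  if (!any(ok)) return(0)
  d <- rel_diff(sp$len_1d, len_1d) + rel_diff(sp$len_2d, len_2d)
  sp$intensity[ok][which.min(d[ok])]
}

#' Call CpG methylation from [MspI] vs [HpaII] pattern differences
#'
#' A spot present in the [MspI] pattern but absent from [HpaII] indicates
#' internal-cytosine methylation (C-meC-G-G) at the MspI/HpaII site; full
#' [MspI] intensity with halved [HpaII] intensity indicates the
#' heterozygous case. Spots of equal intensity in both are unmethylated
#' (omitted unless `include_unmethylated`). Absence from both patterns is
#' not callable from the patterns alone; when a `reference` pattern from a
#' methylation-ignorant digest of the same sample is supplied, loci present
#' there but absent from both combos are reported as `blocked_or_absent`
#' (blocking methylation or sequence polymorphism -- indistinguishable
#' without site-level confirmation).
#'
#' @param pattern_mspI,pattern_hpaII Patterns of the same sample under the
#'   two enzyme combinations.
#' @param tol Relative length tolerance for spot matching.
#' @param intensity_tol Relative tolerance for intensity classes.
#' @param reference Optional methylation-ignorant `rlgs_pattern` of the
#'   same sample.
#' @param include_unmethylated Also report equal-intensity (unmethylated)
#'   loci?
#' @return Data frame of calls: `locus`, `len_1d`, `len_2d`,
#'   `mspI_intensity`, `hpaII_intensity`, `call` (one of
#'   `internal_C_methylated`, `unmethylated`, `blocked_or_absent`,
#'   `other`), `zygosity` (`homozygous`/`heterozygous`/NA).
#' @export
msp_hpa_diff <- function(pattern_mspI, pattern_hpaII, tol = 0.01,
                         intensity_tol = 0.1, reference = NULL,
                         include_unmethylated = FALSE) {
  m <- match_spots(pattern_mspI, pattern_hpaII, tol)
  baseline <- modal_intensity(pattern_mspI)
  if (is.na(baseline)) baseline <- 1

  call <- character(nrow(m))
  zyg <- rep(NA_character_, nrow(m))
  for (r in seq_len(nrow(m))) {
    if (m$status[r] == "a_only") {
      call[r] <- "internal_C_methylated"
      cls <- classify_intensity(m$intensity_a[r], baseline, intensity_tol)
      zyg[r] <- switch(cls, full = "homozygous", half = "heterozygous",
                       NA_character_)
    } else if (m$status[r] == "both") {
      ratio <- m$intensity_ratio[r]
      if (abs(ratio - 1) <= intensity_tol) {
        call[r] <- "unmethylated"
      } else if (abs(ratio - 0.5) <= 0.5 * intensity_tol) {
        call[r] <- "internal_C_methylated"
        zyg[r] <- "heterozygous"
      } else {
        call[r] <- "other"
      }
    } else {
      call[r] <- "other"     # HpaII-only: anomalous, flagged for inspection
    }
  }
  res <- data.frame(
    locus = m$locus,
    len_1d = ifelse(is.na(m$len_1d_a), m$len_1d_b, m$len_1d_a),
    len_2d = ifelse(is.na(m$len_2d_a), m$len_2d_b, m$len_2d_a),
    mspI_intensity = ifelse(is.na(m$intensity_a), 0, m$intensity_a),
    hpaII_intensity = ifelse(is.na(m$intensity_b), 0, m$intensity_b),
    call = call, zygosity = zyg, stringsAsFactors = FALSE
  )

  if (!is.null(reference)) {
    ref_m <- match_spots(reference, pattern_mspI, tol)
    ref_h <- match_spots(reference, pattern_hpaII, tol)
    miss_m <- ref_m$locus[ref_m$status == "a_only"]
    miss_h <- ref_h$locus[ref_h$status == "a_only"]
    gone <- intersect(miss_m, miss_h)
    if (length(gone)) {
      ref_rows <- reference$spots[match(gone, reference$spots$loci),
                                  , drop = FALSE]
      res <- rbind(res, data.frame(
        locus = gone, len_1d = ref_rows$len_1d, len_2d = ref_rows$len_2d,
        mspI_intensity = 0, hpaII_intensity = 0,
        call = "blocked_or_absent", zygosity = NA_character_,
        stringsAsFactors = FALSE
      ))
    }
  }

  if (!include_unmethylated)
    res <- res[res$call != "unmethylated", , drop = FALSE]
  rownames(res) <- NULL
  res
}
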