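#' Gel model: detection windows and log-linear mobility
#'
#' Fragment-length detection windows for the two gel dimensions and a
#' normalised log-linear mobility map. The windows bracket typical RLGS
#' agarose (1D) and polyacrylamide (2D) resolution; only relative spot
#' positions matter for pattern comparison, so no gel physics beyond
#' monotone log-length mobility is modelled.
#'
#' @param window_1d,window_2d Length-2 numeric `(min bp, max bp)`.
#' @return An object of class `rlgs_gel`.
#' @export
gel_model <- function(window_1d = c(500, 25000), window_2d = c(100, 5000)) {
  stopifnot(length(window_1d) == 2L, length(window_2d) == 2L,
            window_1d[1L] > 0, window_2d[1L] > 0,
            window_1d[1L] < window_1d[2L], window_2d[1L] < window_2d[2L])
  structure(list(window_1d = as.numeric(window_1d),
                 window_2d = as.numeric(window_2d)),
            class = "rlgs_gel")
}

same_gel <- function(a, b) {
  isTRUE(all.equal(a$window_1d, b$window_1d)) &&
    isTRUE(all.equal(a$window_2d, b$window_2d))
}

#' Map a fragment length to a gel coordinate
#'
#' `x = (log10(Lmax) - log10(L)) / (log10(Lmax) - log10(Lmin))`: strictly
#' decreasing in length, 0 at the window maximum, 1 at the minimum.
#'
#' @param length Fragment length(s) in bp.
#' @param dimension 1 or 2.
#' @param gel A [gel_model()].
#' @return Coordinate(s) in `[0, 1]`.
#' @export
mobility <- function(length, dimension, gel = gel_model()) {
  stopifnot(inherits(gel, "rlgs_gel"), dimension %in% c(1L, 2L))
  w <- if (dimension == 1L) gel$window_1d else gel$window_2d
  if (any(length < w[1L] | length > w[2L]))
    stop("fragment length outside the detection window [",
         w[1L], ", ", w[2L], "] bp", call. = FALSE)
  (log10(w[2L]) - log10(length)) / (log10(w[2L]) - log10(w[1L]))
}

#' Enumerate NotI-anchored RLGS fragments of a haplotype
#'
#' For every cleavable NotI landmark, walks outward in both directions. The
#' 1D extent runs from the landmark cut to the nearest cleavable cut of the
#' second enzyme or the next cleavable NotI cut (`end_1d_kind` records
#' which); hitting a chromosome boundary yields `sequence_end`. The 2D
#' extent runs to the nearest cleavable BamHI cut strictly inside the 1D
#' extent, else equals the 1D extent (`end_2d_kind = "same_as_1d"`, the gel
#' diagonal). Blocked (methylated) sites are transparent to the walk: the
#' first *cleavable* cut in walking order wins. Fragment lengths are
#' differences of top-strand cut coordinates.
#'
#' @param hap An [haplotype()].
#' @param second_enzyme `"MspI"` or `"HpaII"`.
#' @param enzymes Enzyme set; must contain NotI, BamHI and `second_enzyme`.
#' @return Data frame with one row per (landmark, direction): columns
#'   `chrom`, `landmark_cut`, `direction`, `len_1d`, `end_1d_kind`,
#'   `len_2d`, `end_2d_kind`, `haplotype`.
#' @export
enumerate_fragments <- function(hap, second_enzyme = c("MspI", "HpaII"),
                                enzymes = default_enzymes()) {
  stopifnot(inherits(hap, "rlgs_haplotype"))
  second_enzyme <- match.arg(second_enzyme)
  for (nm in c("NotI", second_enzyme, "BamHI"))
    if (is.null(enzymes[[nm]])) stop("enzyme set lacks ", nm)
  sites <- hap_sites(hap, enzymes)
  sites <- apply_overlay(sites, hap$overlay, hap$id)

  empty <- data.frame(chrom = character(), landmark_cut = integer(),
                      direction = character(), len_1d = integer(),
                      end_1d_kind = character(), len_2d = integer(),
                      end_2d_kind = character(), haplotype = character(),
                      stringsAsFactors = FALSE)
  if (is.null(sites) || !nrow(sites)) return(empty)

  out <- list()
  for (chrom in names(hap$sequences)) {
    chrom_len <- nchar(hap$sequences[[chrom]])
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    cleavable_cuts <- function(enz_name) {
      sel <- s$enzyme == enz_name
      cuts <- s$cut_pos[sel][is_cleavable(s$state[sel], enzymes[[enz_name]])]
      sort(unique(cuts))
    }
    n_cuts <- cleavable_cuts("NotI")
    if (!length(n_cuts)) next
    m_cuts <- cleavable_cuts(second_enzyme)
    b_cuts <- cleavable_cuts("BamHI")
    ends <- sort(unique(c(n_cuts, m_cuts)))

    walk <- function(direction) {
      if (direction == "+") {
        i <- findInterval(n_cuts, ends) + 1L        # first end strictly > cut
        nxt <- ends[ifelse(i <= length(ends), i, NA_integer_)]
        len1 <- ifelse(is.na(nxt), chrom_len - n_cuts, nxt - n_cuts)
        kind1 <- ifelse(is.na(nxt), "sequence_end",
                        ifelse(nxt %in% m_cuts, "second_enzyme", "NotI"))
        j <- findInterval(n_cuts, b_cuts) + 1L      # first BamHI cut > cut
        b <- b_cuts[ifelse(j <= length(b_cuts), j, NA_integer_)]
        inside <- !is.na(b) & b < n_cuts + len1
        len2 <- ifelse(inside, b - n_cuts, len1)
      } else {
        i <- findInterval(n_cuts - 1L, ends)        # last end strictly < cut
        prv <- ends[ifelse(i >= 1L, i, NA_integer_)]
        len1 <- ifelse(is.na(prv), n_cuts, n_cuts - prv)
        kind1 <- ifelse(is.na(prv), "sequence_end",
                        ifelse(prv %in% m_cuts, "second_enzyme", "NotI"))
        j <- findInterval(n_cuts - 1L, b_cuts)
        b <- b_cuts[ifelse(j >= 1L, j, NA_integer_)]
        inside <- !is.na(b) & b > n_cuts - len1
        len2 <- ifelse(inside, n_cuts - b, len1)
      }
      data.frame(chrom = chrom, landmark_cut = n_cuts, direction = direction,
                 len_1d = as.integer(len1), end_1d_kind = kind1,
                 len_2d = as.integer(len2),
                 end_2d_kind = ifelse(inside, "BamHI", "same_as_1d"),
                 haplotype = hap$id, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- walk("+")
    out[[length(out) + 1L]] <- walk("-")
  }
  if (!length(out)) return(empty)
  fr <- do.call(rbind, out)
  fr <- fr[fr$len_1d > 0L, , drop = FALSE]      # landmark flush with boundary
  fr <- fr[order(fr$chrom, fr$landmark_cut, fr$direction), , drop = FALSE]
  rownames(fr) <- NULL
  fr
}

locus_key <- function(fr) {
  sprintf("%s:%d:%s:%s", fr$chrom, fr$landmark_cut, fr$direction, fr$haplotype)
}

rel_diff <- function(a, b) abs(a - b) / pmax(a, b)

# Single-linkage merge of co-migrating fragments: relative length difference
# <= tol in BOTH dimensions links two fragments; connected components merge.
# Representative lengths come from the first fragment in (chrom,
# landmark_cut, direction, haplotype) order, the deterministic tie-break.
merge_comigrating <- function(fr, tol) {
  n <- nrow(fr)
  comp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (comp[i] == comp[j]) next
        if (rel_diff(fr$len_1d[i], fr$len_1d[j]) <= tol &&
            rel_diff(fr$len_2d[i], fr$len_2d[j]) <= tol) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  groups <- split(seq_len(n), comp)
  groups <- groups[order(vapply(groups, min, 1L))]
  rows <- lapply(groups, function(idx) {
    rep_row <- fr[min(idx), , drop = FALSE]
    data.frame(len_1d = rep_row$len_1d, len_2d = rep_row$len_2d,
               intensity = 0.5 * length(idx),
               loci = paste(locus_key(fr[idx, , drop = FALSE]), collapse = ";"),
               n_loci = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spot pattern container
#'
#' @param sample_id Sample identifier.
#' @param combo `"MspI"` or `"HpaII"` (the second enzyme of the run).
#' @param spots Spot data frame (`x1`, `x2`, `len_1d`, `len_2d`,
#'   `intensity`, `loci`, `n_loci`).
#' @param gel The [gel_model()] used.
#' @return An object of class `rlgs_pattern`.
#' @export
spot_pattern <- function(sample_id, combo, spots, gel) {
  structure(list(sample_id = sample_id, combo = combo,
                 spots = spots, gel = gel),
            class = "rlgs_pattern")
}

#' @export
print.rlgs_pattern <- function(x, ...) {
  cat(sprintf("<rlgs_pattern> %s [%s]: %d spot(s), total intensity %.1f\n",
              x$sample_id, x$combo, nrow(x$spots), sum(x$spots$intensity)))
  invisible(x)
}

empty_spots <- function() {
  data.frame(x1 = numeric(), x2 = numeric(), len_1d = integer(),
             len_2d = integer(), intensity = numeric(), loci = character(),
             n_loci = integer(), stringsAsFactors = FALSE)
}

build_pattern <- function(fr, sample_id, combo, gel, include_sequence_end,
                          include_diagonal, merge_tol) {
  if (!include_sequence_end)
    fr <- fr[fr$end_1d_kind != "sequence_end", , drop = FALSE]
  if (!include_diagonal)
    fr <- fr[fr$end_2d_kind != "same_as_1d", , drop = FALSE]
  fr <- fr[fr$len_1d >= gel$window_1d[1L] & fr$len_1d <= gel$window_1d[2L] &
           fr$len_2d >= gel$window_2d[1L] & fr$len_2d <= gel$window_2d[2L],
           , drop = FALSE]
  if (!nrow(fr))
    return(spot_pattern(sample_id, combo, empty_spots(), gel))
  fr <- fr[order(fr$chrom, fr$landmark_cut, fr$direction, fr$haplotype),
           , drop = FALSE]
  spots <- merge_comigrating(fr, merge_tol)
  spots$x1 <- mobility(spots$len_1d, 1L, gel)
  spots$x2 <- mobility(spots$len_2d, 2L, gel)
  spots <- spots[, c("x1", "x2", "len_1d", "len_2d", "intensity",
                     "loci", "n_loci")]
  rownames(spots) <- NULL
  spot_pattern(sample_id, combo, spots, gel)
}

#' Synthesize the spot pattern of a single haplotype
#'
#' Enumerates fragments, drops `sequence_end` fragments (physical ends are
#' blocked from labelling and unknowable in silico; configurable), filters
#' to both detection windows, assigns each retained fragment the
#' per-haplotype intensity quantum 0.5, and merges co-migrating spots.
#' Fragments with no internal BamHI cut run on the 2D diagonal and are
#' retained by default.
#'
#' @param hap An [haplotype()].
#' @param combo Second enzyme: `"MspI"` or `"HpaII"`.
#' @param gel A [gel_model()].
#' @param enzymes Enzyme set.
#' @param include_sequence_end Keep fragments ending at a chromosome
#'   boundary?
#' @param include_diagonal Keep fragments with no internal BamHI cut?
#' @param merge_tol Co-migration tolerance: relative length difference in
#'   both dimensions at or below which spots merge.
#' @param sample_id Label for the pattern (defaults to the haplotype id).
#' @return An `rlgs_pattern`.
#' @export
haplotype_pattern <- function(hap, combo = c("MspI", "HpaII"),
                              gel = gel_model(), enzymes = default_enzymes(),
                              include_sequence_end = FALSE,
                              include_diagonal = TRUE,
                              merge_tol = 0.01, sample_id = hap$id) {
  combo <- match.arg(combo)
  fr <- enumerate_fragments(hap, combo, enzymes)
  build_pattern(fr, sample_id, combo, gel, include_sequence_end,
                include_diagonal, merge_tol)
}

#' Synthesize the diploid spot pattern of an individual
#'
#' Union of the two haplotype patterns with co-migrating merge: a fragment
#' produced by both alleles yields intensity 1.0, by one allele 0.5.
#'
#' @param individual An [diploid()] individual.
#' @inheritParams haplotype_pattern
#' @return An `rlgs_pattern`.
#' @export
diploid_pattern <- function(individual, combo = c("MspI", "HpaII"),
                            gel = gel_model(), enzymes = default_enzymes(),
                            include_sequence_end = FALSE,
                            include_diagonal = TRUE,
                            merge_tol = 0.01, sample_id = individual$id) {
  stopifnot(inherits(individual, "rlgs_diploid"))
  combo <- match.arg(combo)
  fr <- rbind(enumerate_fragments(individual$haplotypes[[1L]], combo, enzymes),
              enumerate_fragments(individual$haplotypes[[2L]], combo, enzymes))
  build_pattern(fr, sample_id, combo, gel, include_sequence_end,
                include_diagonal, merge_tol)
}
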