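#' Random background DNA
#'
#' Uniform A/C/G/T sequence of length `n` (uses the current RNG stream).
#'
#' @param n Length in bp.
#' @return A character string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specification of a planted RLGS locus
#'
#' Describes a NotI(N)...BamHI(B)...MspI/HpaII(M) cassette by the distances
#' between top-strand cut positions: `spacing_nb` bp from the N cut to the
#' B cut and `spacing_bm` bp from the B cut to the M cut, so the landmark
#' fragment runs `spacing_nb + spacing_bm` bp in the 1D gel and
#' `spacing_nb` bp in the 2D gel. `b_present = FALSE` plants a one-base
#' disabled BamHI motif (GGATCA) at the same position, keeping alleles
#' alignable. An optional further NotI cut can be planted `next_notI` bp
#' downstream of the N cut.
#'
#' @param name Locus name.
#' @param spacing_nb,spacing_bm Cut-to-cut spacings in bp.
#' @param b_present Is the spot-defining BamHI site present?
#' @param next_notI Optional spacing from the N cut to a second NotI cut.
#' @return An object of class `rlgs_locus_spec`.
#' @export
locus_spec <- function(name = "focal", spacing_nb = 1400, spacing_bm = 1000,
                       b_present = TRUE, next_notI = NULL) {
  spacing_nb <- as.integer(spacing_nb)
  spacing_bm <- as.integer(spacing_bm)
  # motif windows: N [0,8), B [nb+1, nb+7), M [nb+bm+1, nb+bm+5)
  if (is.na(spacing_nb) || spacing_nb < 7L || is.na(spacing_bm) ||
      spacing_bm < 6L)
    stop("planted sites overlap: spacing_nb must be >= 7 and spacing_bm >= 6")
  if (!is.null(next_notI)) {
    next_notI <- as.integer(next_notI)
    # second NotI motif window [next_notI, next_notI + 8) must not
    # overlap the N, B or M motif windows (it may sit before or after M:
    # a next landmark closer than M is the NotI-NotI fragment case)
    win <- rbind(c(0L, 8L),
                 c(spacing_nb + 1L, spacing_nb + 7L),
                 c(spacing_nb + spacing_bm + 1L, spacing_nb + spacing_bm + 5L))
    n2 <- c(next_notI, next_notI + 8L)
    if (n2[1L] < 0L ||
        any(n2[1L] < win[, 2L] & n2[2L] > win[, 1L]))
      stop("planted sites overlap: next_notI window collides with N, B or M")
  }
  structure(list(name = name, spacing_nb = spacing_nb,
                 spacing_bm = spacing_bm, b_present = isTRUE(b_present),
                 next_notI = next_notI),
            class = "rlgs_locus_spec")
}

cassette_length <- function(spec) {
  max(spec$spacing_nb + spec$spacing_bm + 5L,
      if (!is.null(spec$next_notI)) spec$next_notI + 8L else 0L)
}

# Plant the cassette motifs over random background; returns the cassette as
# a character vector plus the 0-based windows of the planted motifs.
plant_cassette <- function(spec) {
  len <- cassette_length(spec)
  chars <- strsplit(random_dna(len), "", fixed = TRUE)[[1L]]
  keep <- list()
  place <- function(motif, at, protect = TRUE) {
    m <- strsplit(motif, "", fixed = TRUE)[[1L]]
    chars[at + seq_along(m)] <<- m
    if (protect)
      keep[[length(keep) + 1L]] <<- data.frame(start = at, width = length(m))
  }
  place("GCGGCCGC", 0L)
  place(if (spec$b_present) "GGATCC" else "GGATCA", spec$spacing_nb + 1L,
        protect = spec$b_present)
  place("CCGG", spec$spacing_nb + spec$spacing_bm + 1L)
  if (!is.null(spec$next_notI)) place("GCGGCCGC", spec$next_notI)
  list(chars = chars,
       keep = if (length(keep)) do.call(rbind, keep)
              else data.frame(start = integer(), width = integer()))
}

# Rewrite accidental NotI/CCGG/BamHI motifs overlapping [lo, hi) (0-based)
# so the planted geometry is the only cut geometry there. keep: 0-based
# motif windows that must stay untouched.
screen_region <- function(chars, lo, hi, keep) {
  pats <- c("GCGGCCGC", "CCGG", "GGATCC")
  in_keep <- function(pos) {
    if (!nrow(keep)) return(rep(FALSE, length(pos)))
    vapply(pos, function(p)
      any(p >= keep$start & p < keep$start + keep$width), TRUE)
  }
  for (iter in seq_len(200L)) {
    txt <- paste(chars, collapse = "")
    offenders <- NULL
    for (pat in pats) {
      m <- gregexpr(pat, txt, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      st <- as.integer(m) - 1L
      w <- nchar(pat)
      hit <- st < hi & st + w > lo
      planted <- st %in% keep$start[keep$width == w]
      st <- st[hit & !planted]
      if (length(st))
        offenders <- rbind(offenders, data.frame(start = st, width = w))
    }
    if (is.null(offenders)) return(chars)
    for (r in seq_len(nrow(offenders))) {
      pos <- offenders$start[r] + seq_len(offenders$width[r]) - 1L
      pos <- pos[!in_keep(pos)]
      if (!length(pos)) next
      p <- if (length(pos) == 1L) pos else sample(pos, 1L)
      chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1L]), 1L)
    }
  }
  stop("failed to screen accidental recognition sites after 200 passes")
}

#' Build a haplotype with one planted locus in random background
#'
#' Embeds the cassette of a [locus_spec()] at the centre of a random
#' background sequence. The cassette span plus a 100 bp guard on each side
#' is screened free of accidental NotI/CCGG/BamHI motifs, so the planted
#' sites are the only cuts governing the landmark fragment; accidental
#' sites elsewhere are left in place (they form background spots).
#'
#' @param spec A [locus_spec()].
#' @param background_length Total chromosome length in bp.
#' @param seed Integer seed (background and screening are reproducible).
#' @param m_state Methylation state planted at the M site of this allele.
#' @param chrom Chromosome name.
#' @param id Haplotype id.
#' @param enzymes Enzyme set used to pre-scan sites.
#' @return An [haplotype()] carrying `focal` metadata (`chrom`, `n_cut`,
#'   `b_start`, `m_start`, `b_present`, `len_1d`, `len_2d`).
#' @examples
#' hap <- build_locus(locus_spec(spacing_nb = 1400, spacing_bm = 1000),
#'                    background_length = 6000, seed = 1)
#' @export
build_locus <- function(spec, background_length = 10000, seed = 1,
                        m_state = "unmethylated", chrom = "chr1",
                        id = spec$name, enzymes = default_enzymes()) {
  stopifnot(inherits(spec, "rlgs_locus_spec"))
  stopifnot(m_state %in% methylation_states())
  clen <- cassette_length(spec)
  guard <- 100L
  if (background_length < clen + 2L * (guard + 50L))
    stop("background_length too short for the cassette plus guard regions")
  with_seed(seed, {
    chars <- strsplit(random_dna(background_length), "", fixed = TRUE)[[1L]]
    offset <- as.integer((background_length - clen) %/% 2L)
    cas <- plant_cassette(spec)
    chars[offset + seq_len(clen)] <- cas$chars
    keep <- cas$keep
    keep$start <- keep$start + offset
    chars <- screen_region(chars, max(0L, offset - guard),
                           min(background_length, offset + clen + guard),
                           keep)
    seqs <- stats::setNames(paste(chars, collapse = ""), chrom)
    m_start <- offset + spec$spacing_nb + spec$spacing_bm + 1L
    ov <- if (m_state == "unmethylated") NULL
          else overlay_table(chrom, m_start, m_start + 4L, m_state, id)
    hap <- haplotype(id, seqs, ov)
    hap$focal <- list(chrom = chrom, n_cut = offset + 2L,
                      b_start = offset + spec$spacing_nb + 1L,
                      m_start = m_start, b_present = spec$b_present,
                      len_1d = spec$spacing_nb + spec$spacing_bm,
                      len_2d = if (spec$b_present) spec$spacing_nb
                               else spec$spacing_nb + spec$spacing_bm)
    hap <- precompute_sites(hap, enzymes)
    validate_overlay(hap, enzymes)
    hap
  })
}

#' Epigenetic transmission model for simulated crosses
#'
#' `mendelian`: each parent transmits one of its two (allele, epiallele)
#' pairs with probability 1/2, independently per individual.
#' `maintain_heterozygous`: allele transmission is Mendelian, but in any
#' progeny carrying the focal spot-capable allele from the focal
#' (methylation-heterozygous) parent, the M-site methylation is
#' re-established heterozygously with probability `maintenance_prob`, so
#' the individual reproduces the parent's half-intensity configuration.
#' This operationalises the observed selfed-progeny behaviour; it is a
#' phenomenological model, not a mechanistic claim (maintenance and
#' re-establishment are indistinguishable here). `demethylate_progeny`:
#' transmitted focal epialleles are reset to unmethylated.
#'
#' @param name Model name.
#' @param maintenance_prob Probability in `[0, 1]` of re-establishment per
#'   individual (maintenance model only).
#' @return An object of class `rlgs_transmission_model`.
#' @export
transmission_model <- function(name = c("mendelian", "maintain_heterozygous",
                                        "demethylate_progeny"),
                               maintenance_prob = 1) {
  name <- match.arg(name)
  stopifnot(is.numeric(maintenance_prob), length(maintenance_prob) == 1L,
            maintenance_prob >= 0, maintenance_prob <= 1)
  structure(list(name = name, maintenance_prob = maintenance_prob),
            class = "rlgs_transmission_model")
}

focal_m_state <- function(hap) {
  f <- hap$focal
  if (is.null(f)) return(NA_character_)
  ov <- hap$overlay
  sel <- ov$chrom == f$chrom & ov$start == f$m_start
  if (any(sel)) ov$state[sel][1L] else "unmethylated"
}

set_focal_m_state <- function(hap, state) {
  f <- hap$focal
  stopifnot(!is.null(f), state %in% methylation_states())
  ov <- hap$overlay
  keep <- !(ov$chrom == f$chrom & ov$start == f$m_start)
  ov <- ov[keep, , drop = FALSE]
  if (state != "unmethylated")
    ov <- rbind(ov, overlay_table(f$chrom, f$m_start, f$m_start + 4L,
                                  state, hap$id))
  hap$overlay <- ov
  hap
}

#' Does an allele produce the focal spot?
#'
#' TRUE when the allele carries the spot-defining BamHI site and its M-site
#' methylation state is cleavable by the given second enzyme.
#'
#' @param hap A haplotype built by [build_locus()] (or fixture).
#' @param combo Second enzyme name.
#' @param enzymes Enzyme set.
#' @return Logical scalar.
#' @export
allele_produces_spot <- function(hap, combo = "MspI",
                                 enzymes = default_enzymes()) {
  f <- hap$focal
  if (is.null(f)) stop("haplotype carries no focal-locus metadata")
  f$b_present && is_cleavable(focal_m_state(hap), enzymes[[combo]])
}

#' Focal spot genotype of a diploid individual
#'
#' @param ind An `rlgs_diploid` whose haplotypes carry focal metadata.
#' @inheritParams allele_produces_spot
#' @return Logical length-2 vector (one entry per allele).
#' @export
spot_genotype <- function(ind, combo = "MspI", enzymes = default_enzymes()) {
  vapply(ind$haplotypes, allele_produces_spot, TRUE,
         combo = combo, enzymes = enzymes)
}

parent_is_focal_het <- function(parent) {
  f1 <- parent$haplotypes[[1L]]$focal
  f2 <- parent$haplotypes[[2L]]$focal
  if (is.null(f1) || is.null(f2)) return(FALSE)
  s <- c(focal_m_state(parent$haplotypes[[1L]]),
         focal_m_state(parent$haplotypes[[2L]]))
  s[1L] != s[2L]
}

parent_blocked_state <- function(parent) {
  s <- c(focal_m_state(parent$haplotypes[[1L]]),
         focal_m_state(parent$haplotypes[[2L]]))
  s <- setdiff(s, "unmethylated")
  if (length(s)) s[1L] else "outer_C"
}

relabel_hap <- function(hap, new_id) {
  if (nrow(hap$overlay)) {
    own <- is.na(hap$overlay$haplotype) | hap$overlay$haplotype == "" |
      hap$overlay$haplotype == hap$id
    hap$overlay$haplotype[own] <- new_id
  }
  hap$id <- new_id
  hap
}

#' Simulate a cross panel
#'
#' Draws `n` progeny of `mother` x `father` under a transmission model.
#' Reproducible: identical `(parents, model, seed)` give byte-identical
#' panels.
#'
#' @param mother,father `rlgs_diploid` parents built over the same locus
#'   universe (selfing: pass the same individual twice).
#' @param n Number of progeny (>= 0).
#' @param model A [transmission_model()] or its name.
#' @param seed Integer seed.
#' @return An object of class `rlgs_cross_panel`: parent ids, `n`, `seed`,
#'   `model` and the list of progeny `rlgs_diploid`s.
#' @export
simulate_cross <- function(mother, father, n,
                           model = transmission_model("mendelian"),
                           seed = 1) {
  stopifnot(inherits(mother, "rlgs_diploid"), inherits(father, "rlgs_diploid"))
  if (is.character(model)) model <- transmission_model(model)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")

  focal_mother <- parent_is_focal_het(mother)
  focal_father <- parent_is_focal_het(father)
  blocked <- if (focal_mother) parent_blocked_state(mother)
             else if (focal_father) parent_blocked_state(father)
             else "outer_C"

  individuals <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ind_id <- sprintf("%s_x_%s_%03d", mother$id, father$id, i)
      mi <- sample.int(2L, 1L)
      fi <- sample.int(2L, 1L)
      h1 <- relabel_hap(mother$haplotypes[[mi]], paste0(ind_id, ".m"))
      h2 <- relabel_hap(father$haplotypes[[fi]], paste0(ind_id, ".p"))
      if (model$name == "demethylate_progeny") {
        if (!is.null(h1$focal)) h1 <- set_focal_m_state(h1, "unmethylated")
        if (!is.null(h2$focal)) h2 <- set_focal_m_state(h2, "unmethylated")
      } else if (model$name == "maintain_heterozygous") {
        from_focal <- c(focal_mother, focal_father)
        haps <- list(h1, h2)
        carried <- which(from_focal &
                           vapply(haps, function(h)
                             !is.null(h$focal) && h$focal$b_present, TRUE))
        if (length(carried) && stats::runif(1L) < model$maintenance_prob) {
          first <- TRUE
          for (k in carried) {
            haps[[k]] <- set_focal_m_state(haps[[k]],
                                           if (first) "unmethylated" else blocked)
            first <- FALSE
          }
          h1 <- haps[[1L]]; h2 <- haps[[2L]]
        }
      }
      diploid(h1, h2, ind_id)
    })
  })
  structure(list(mother = mother$id, father = father$id, n = n,
                 seed = seed, model = model, individuals = individuals),
            class = "rlgs_cross_panel")
}

#' @export
print.rlgs_cross_panel <- function(x, ...) {
  cat(sprintf("<rlgs_cross_panel> %s x %s: n = %d, model = %s, seed = %d\n",
              x$mother, x$father, x$n, x$model$name, x$seed))
  invisible(x)
}

#' Classify the focal spot across a cross panel
#'
#' Digests every individual, reads off the intensity of the spot at the
#' reference fragment lengths and classifies it against a full-intensity
#' baseline of 1 (both alleles of one locus).
#'
#' @param panel An `rlgs_cross_panel`.
#' @param len_1d,len_2d Reference fragment lengths of the focal spot.
#' @param combo Second enzyme.
#' @param gel A [gel_model()].
#' @param enzymes Enzyme set.
#' @param tol Relative length tolerance for locating the spot.
#' @param baseline Full-intensity reference.
#' @param intensity_tol Relative tolerance of the intensity classes.
#' @return Data frame: `individual`, `intensity`, `class`.
#' @export
panel_spot_classes <- function(panel, len_1d, len_2d, combo = "MspI",
                               gel = gel_model(), enzymes = default_enzymes(),
                               tol = 0.01, baseline = 1, intensity_tol = 0.1) {
  stopifnot(inherits(panel, "rlgs_cross_panel"))
  rows <- lapply(panel$individuals, function(ind) {
    pat <- diploid_pattern(ind, combo, gel, enzymes)
    int <- spot_intensity_at(pat, len_1d, len_2d, tol)
    data.frame(individual = ind$id, intensity = int,
               class = classify_intensity(int, baseline, intensity_tol),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows) %||%
    data.frame(individual = character(), intensity = numeric(),
               class = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Packaged two-parent fixture with reciprocal F1 and selfed panels
#'
#' Emulates the spot-200 geometry: one ~27 kb chromosome carrying three
#' unmethylated background cassettes plus the focal N...B...M cassette
#' (spacings 1400/1000 bp, landmark fragment 2400 bp in 1D, 2400 bp to the
#' BamHI cut at 1400 bp in 2D). The Nipponbare-like parent is
#' B-present/B-present with the M site heterozygously outer-cytosine
#' blocked (spot at half intensity in both combos); the Kasalath-like
#' parent is B-absent/B-absent and unmethylated (focal spot absent). Both
#' parents share an identical background, so every non-focal spot matches
#' between them. Returns reciprocal F1 panels and selfed panels simulated
#' under the given models.
#'
#' @param seed Integer seed; panel seeds are derived from it.
#' @param n_f1 Individuals per reciprocal F1 panel.
#' @param n_selfed_N,n_selfed_K Individuals in the selfed panels.
#' @param f1_model,selfed_N_model,selfed_K_model [transmission_model()]s
#'   (or names) per panel.
#' @param enzymes Enzyme set.
#' @return An object of class `rlgs_fixture`: `parent_N`, `parent_K`,
#'   `panels` (NKF1, KNF1, selfed_N, selfed_K), `focal` metadata (`chrom`,
#'   `len_1d`, `len_2d`, cut/site coordinates) and `seed`.
#' @export
nipponbare_kasalath_fixture <- function(seed = 1, n_f1 = 9,
                                        n_selfed_N = 9, n_selfed_K = 4,
                                        f1_model = "mendelian",
                                        selfed_N_model = "maintain_heterozygous",
                                        selfed_K_model = "mendelian",
                                        enzymes = default_enzymes()) {
  chrom <- "chr1"
  guard <- 100L
  specs <- list(
    bg1   = locus_spec("bg1",   spacing_nb = 800,  spacing_bm = 550),
    focal = locus_spec("focal", spacing_nb = 1400, spacing_bm = 1000),
    bg2   = locus_spec("bg2",   spacing_nb = 3000, spacing_bm = 900),
    bg3   = locus_spec("bg3",   spacing_nb = 1200, spacing_bm = 450)
  )
  fillers <- c(4000L, 3500L, 3500L, 3500L, 3000L)

  built <- with_seed(seed, {
    chars <- character(0)
    keep <- data.frame(start = integer(), width = integer())
    spans <- list()
    pos <- 0L
    for (k in seq_along(specs)) {
      fill <- strsplit(random_dna(fillers[k]), "", fixed = TRUE)[[1L]]
      chars <- c(chars, fill); pos <- pos + fillers[k]
      cas <- plant_cassette(specs[[k]])
      kk <- cas$keep; kk$start <- kk$start + pos
      keep <- rbind(keep, kk)
      spans[[names(specs)[k]]] <-
        c(offset = pos, len = cassette_length(specs[[k]]))
      chars <- c(chars, cas$chars)
      pos <- pos + cassette_length(specs[[k]])
    }
    chars <- c(chars, strsplit(random_dna(fillers[length(fillers)]),
                               "", fixed = TRUE)[[1L]])
    for (sp in spans)
      chars <- screen_region(chars, max(0L, sp["offset"] - guard),
                             min(length(chars), sp["offset"] + sp["len"] + guard),
                             keep)
    list(chars = chars, spans = spans)
  })

  f_off <- built$spans$focal[["offset"]]
  f_spec <- specs$focal
  focal <- list(chrom = chrom, n_cut = f_off + 2L,
                b_start = f_off + f_spec$spacing_nb + 1L,
                m_start = f_off + f_spec$spacing_nb + f_spec$spacing_bm + 1L,
                len_1d = f_spec$spacing_nb + f_spec$spacing_bm,
                len_2d = f_spec$spacing_nb)

  seq_N <- stats::setNames(paste(built$chars, collapse = ""), chrom)
  chars_K <- built$chars
  chars_K[focal$b_start + 6L] <- "A"          # GGATCC -> GGATCA, 0-based +5
  seq_K <- stats::setNames(paste(chars_K, collapse = ""), chrom)

  focal_meta <- function(b_present)
    c(focal[c("chrom", "n_cut", "b_start", "m_start")],
      list(b_present = b_present, len_1d = focal$len_1d,
           len_2d = if (b_present) focal$len_2d else focal$len_1d))

  mk_hap <- function(id, seqs, sites, m_state, b_present) {
    ov <- if (m_state == "unmethylated") NULL
          else overlay_table(chrom, focal$m_start, focal$m_start + 4L,
                             m_state, id)
    hap <- haplotype(id, seqs, ov, sites = sites)
    hap$focal <- focal_meta(b_present)
    hap
  }
  sites_N <- scan_sites(haplotype("tmpN", seq_N), enzymes)
  sites_K <- scan_sites(haplotype("tmpK", seq_K), enzymes)

  parent_N <- diploid(mk_hap("N.1", seq_N, sites_N, "unmethylated", TRUE),
                      mk_hap("N.2", seq_N, sites_N, "outer_C", TRUE),
                      "Nipponbare_like")
  parent_K <- diploid(mk_hap("K.1", seq_K, sites_K, "unmethylated", FALSE),
                      mk_hap("K.2", seq_K, sites_K, "unmethylated", FALSE),
                      "Kasalath_like")

  panels <- list(
    NKF1 = simulate_cross(parent_N, parent_K, n_f1, f1_model, seed + 101),
    KNF1 = simulate_cross(parent_K, parent_N, n_f1, f1_model, seed + 102),
    selfed_N = simulate_cross(parent_N, parent_N, n_selfed_N,
                              selfed_N_model, seed + 103),
    selfed_K = simulate_cross(parent_K, parent_K, n_selfed_K,
                              selfed_K_model, seed + 104)
  )
  structure(list(parent_N = parent_N, parent_K = parent_K, panels = panels,
                 focal = focal, seed = seed),
            class = "rlgs_fixture")
}

#' @export
print.rlgs_fixture <- function(x, ...) {
  cat(sprintf(paste0("<rlgs_fixture> seed %d: focal landmark fragment ",
                     "%d bp (1D) / %d bp (2D) on %s\n"),
              x$seed, x$focal$len_1d, x$focal$len_2d, x$focal$chrom))
  for (nm in names(x$panels)) {
    p <- x$panels[[nm]]
    cat(sprintf("  %s: %s x %s, n = %d, model = %s\n", nm, p$mother,
                p$father, p$n, p$model$name))
  }
  invisible(x)
}
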