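# Independent brute-force digestion oracle: performs the literal three-step
# digestion piece-wise (cut at every cleavable NotI; keep the NotI-ended
# piece; cut it with the second enzyme keeping the NotI-ended piece; cut
# that with BamHI keeping the NotI-ended piece). Uses gregexpr scanning and
# its own blocked-state tables so it shares no code with the walking
# implementation it checks.

oracle_blocked <- list(
  NotI  = "cpg_methylated",
  MspI  = c("outer_C", "both_C", "cpg_methylated"),
  HpaII = c("internal_C", "outer_C", "both_C", "cpg_methylated"),
  BamHI = character(0)
)
oracle_motifs <- c(NotI = "GCGGCCGC", MspI = "CCGG", HpaII = "CCGG",
                   BamHI = "GGATCC")
oracle_offsets <- c(NotI = 2L, MspI = 1L, HpaII = 1L, BamHI = 1L)

oracle_scan <- function(seq, motif) {
  # overlapping matches must each be reported (GCGGCCGC can self-overlap
  # at distance 6), so advance one base at a time past each hit
  starts <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(motif, substring(seq, from), fixed = TRUE)
    if (m == -1L) break
    st <- from + as.integer(m) - 1L     # 1-based absolute
    starts <- c(starts, st - 1L)
    from <- st + 1L
  }
  starts
}

oracle_cuts <- function(seq, chrom, enzyme_name, overlay) {
  st <- oracle_scan(seq, oracle_motifs[[enzyme_name]])
  states <- rep("unmethylated", length(st))
  if (!is.null(overlay) && nrow(overlay)) {
    ov <- overlay[overlay$chrom == chrom, , drop = FALSE]
    idx <- match(st, ov$start)
    states[!is.na(idx)] <- ov$state[idx[!is.na(idx)]]
  }
  keep <- !(states %in% oracle_blocked[[enzyme_name]])
  sort(st[keep] + oracle_offsets[[enzyme_name]])
}

oracle_fragments <- function(hap, second = "MspI") {
  rows <- list()
  for (chrom in names(hap$sequences)) {
    seq <- hap$sequences[[chrom]]
    L <- nchar(seq)
    n_cuts <- oracle_cuts(seq, chrom, "NotI", hap$overlay)
    m_cuts <- oracle_cuts(seq, chrom, second, hap$overlay)
    b_cuts <- oracle_cuts(seq, chrom, "BamHI", hap$overlay)
    for (c0 in n_cuts) {
      for (dir in c("+", "-")) {
        if (dir == "+") {
          other_n <- n_cuts[n_cuts > c0]
          piece_end <- if (length(other_n)) min(other_n) else L
          if (piece_end == c0) next
          m_in <- m_cuts[m_cuts > c0 & m_cuts < piece_end]
          if (length(m_in)) {
            end1 <- min(m_in); kind1 <- "second_enzyme"
          } else {
            end1 <- piece_end
            kind1 <- if (length(other_n)) "NotI" else "sequence_end"
          }
          b_in <- b_cuts[b_cuts > c0 & b_cuts < end1]
          end2 <- if (length(b_in)) min(b_in) else end1
          len1 <- end1 - c0; len2 <- end2 - c0
        } else {
          other_n <- n_cuts[n_cuts < c0]
          piece_end <- if (length(other_n)) max(other_n) else 0L
          if (piece_end == c0) next
          m_in <- m_cuts[m_cuts < c0 & m_cuts > piece_end]
          if (length(m_in)) {
            end1 <- max(m_in); kind1 <- "second_enzyme"
          } else {
            end1 <- piece_end
            kind1 <- if (length(other_n)) "NotI" else "sequence_end"
          }
          if (end1 == c0) next
          b_in <- b_cuts[b_cuts < c0 & b_cuts > end1]
          end2 <- if (length(b_in)) max(b_in) else end1
          len1 <- c0 - end1; len2 <- c0 - end2
        }
        if (len1 <= 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, landmark_cut = c0, direction = dir,
          len_1d = as.integer(len1), end_1d_kind = kind1,
          len_2d = as.integer(len2),
          end_2d_kind = if (len2 < len1) "BamHI" else "same_as_1d",
          haplotype = hap$id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(enumerate_fragments(haplotype("empty", c(chr = "A")), second)[0, ])
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$landmark_cut, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random genome with planted NotI/BamHI motifs and a random methylation
# overlay over its CCGG and NotI sites.
random_test_hap <- function(seed, length = 5000, n_notI = 3, n_bamHI = 4,
                            overlay_frac = 0.3, id = paste0("rand", seed)) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  plant <- function(motif, n) {
    m <- strsplit(motif, "")[[1L]]
    for (k in seq_len(n)) {
      at <- sample.int(length - 8L, 1L)
      chars[at + seq_along(m) - 1L] <<- m
    }
  }
  plant("GCGGCCGC", n_notI)
  plant("GGATCC", n_bamHI)
  seq <- paste(chars, collapse = "")
  ccgg <- oracle_scan(seq, "CCGG")
  noti <- oracle_scan(seq, "GCGGCCGC")
  ov <- NULL
  pick <- function(starts, states, width) {
    n <- max(0L, rbinom(1L, length(starts), overlay_frac))
    if (!n) return(NULL)
    st <- starts[sample.int(length(starts), n)]
    data.frame(chrom = "chr1", start = st, end = st + width,
               state = sample(states, n, replace = TRUE),
               haplotype = id, stringsAsFactors = FALSE)
  }
  if (length(ccgg))
    ov <- rbind(ov, pick(ccgg, c("internal_C", "outer_C", "both_C"), 4L))
  if (length(noti))
    ov <- rbind(ov, pick(noti, "cpg_methylated", 8L))
  haplotype(id, c(chr1 = seq), if (is.null(ov)) NULL else ov)
}
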