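# Hand-built single-locus sequence: NotI cut at 7, BamHI cut at 21,
# MspI cut at 31 on a 40 bp chromosome, no other recognition sites.
#   positions (0-based): NotI motif 5-12, BamHI 20-25, CCGG 30-33
tiny_locus_seq <- function() {
  paste0("AAAAA", "GCGGCCGC", "AAAAAAA", "GGATCC", "AAAA", "CCGG", "AAAAAA")
}

tiny_hap <- function(m_state = "unmethylated", drop_bamHI = FALSE,
                     id = "tiny") {
  seq <- tiny_locus_seq()
  if (drop_bamHI) seq <- sub("GGATCC", "GGATCA", seq, fixed = TRUE)
  ov <- if (m_state == "unmethylated") NULL
        else overlay_table("chr1", 30L, 34L, m_state, id)
  haplotype(id, c(chr1 = seq), ov)
}

# Gel wide open in both dimensions, for tests on small fragments.
open_gel <- function() gel_model(c(1, 1e6), c(1, 1e6))
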