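#' Methylation overlay table
#'
#' A BED-like table assigning methylation states to recognition sites of
#' one haplotype: columns `chrom`, `start`, `end` (0-based half-open window
#' of the recognition site), `state` (see [methylation_states()]) and
#' `haplotype` (allele id; empty/NA applies to every haplotype). Sites not
#' listed are unmethylated.
#'
#' @param chrom,start,end,state,haplotype Column vectors (recycled).
#' @return Overlay data frame.
#' @export
overlay_table <- function(chrom = character(), start = integer(),
                          end = integer(), state = character(),
                          haplotype = NA_character_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   state = rep_len(as.character(state), n),
                   haplotype = rep_len(as.character(haplotype), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$state), methylation_states())
  if (length(bad))
    stop("unknown methylation state(s) in overlay: ",
         paste(bad, collapse = ", "))
  df
}

#' Construct a haplotype
#'
#' A haplotype is a named set of chromosome sequences plus a methylation
#' overlay giving per-site states for this allele. An optional cached
#' recognition-site table (`sites`) avoids rescanning identical sequences;
#' it is filled by [precompute_sites()] and carried through simulated
#' crosses, where sequences are immutable and only overlays change.
#'
#' @param id Haplotype (allele) identifier.
#' @param sequences Named character vector or `DNAStringSet`, one entry per
#'   chromosome.
#' @param overlay An [overlay_table()] (or NULL for fully unmethylated).
#' @param sites Optional cached site table (internal use).
#' @return An object of class `rlgs_haplotype`.
#' @export
haplotype <- function(id, sequences, overlay = NULL, sites = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  stopifnot(is.character(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every chromosome sequence must be named")
  sequences[] <- toupper(sequences)
  if (is.null(overlay)) overlay <- overlay_table()
  structure(
    list(id = id, sequences = sequences, overlay = overlay,
         sites = sites, focal = NULL),
    class = "rlgs_haplotype"
  )
}

#' @export
print.rlgs_haplotype <- function(x, ...) {
  cat(sprintf("<rlgs_haplotype> %s: %d chromosome(s), %d bp, %d overlay entr%s\n",
              x$id, length(x$sequences), sum(nchar(x$sequences)),
              nrow(x$overlay), if (nrow(x$overlay) == 1L) "y" else "ies"))
  invisible(x)
}

#' Scan and cache recognition sites on a haplotype
#'
#' @param hap An [haplotype()].
#' @param enzymes Named list of [enzyme()]s (default [default_enzymes()]).
#' @return The haplotype with its `sites` table filled.
#' @export
precompute_sites <- function(hap, enzymes = default_enzymes()) {
  stopifnot(inherits(hap, "rlgs_haplotype"))
  hap$sites <- scan_sites(hap, enzymes)
  hap
}

scan_sites <- function(hap, enzymes) {
  out <- list()
  for (chrom in names(hap$sequences)) {
    for (enz in enzymes) {
      out[[length(out) + 1L]] <- find_sites(hap$sequences[[chrom]], enz, chrom)
    }
  }
  do.call(rbind, out)
}

hap_sites <- function(hap, enzymes) {
  if (!is.null(hap$sites)) hap$sites else scan_sites(hap, enzymes)
}

#' Apply a methylation overlay to a site table
#'
#' Overlay rows are matched to sites by (chrom, start); rows carrying a
#' `haplotype` id are applied only when it equals `haplotype_id`.
#'
#' @param sites Site table from [find_sites()].
#' @param overlay An [overlay_table()].
#' @param haplotype_id Id of the haplotype being annotated (or NULL).
#' @return The site table with updated `state` column.
#' @export
apply_overlay <- function(sites, overlay, haplotype_id = NULL) {
  if (is.null(overlay) || !nrow(overlay) || !nrow(sites)) return(sites)
  if (!is.null(haplotype_id) && "haplotype" %in% names(overlay)) {
    keep <- is.na(overlay$haplotype) | overlay$haplotype == "" |
      overlay$haplotype == haplotype_id
    overlay <- overlay[keep, , drop = FALSE]
  }
  if (!nrow(overlay)) return(sites)
  idx <- match(paste(sites$chrom, sites$start),
               paste(overlay$chrom, overlay$start))
  hit <- !is.na(idx)
  sites$state[hit] <- overlay$state[idx[hit]]
  sites
}

#' Validate that every overlay entry sits on a recognition site
#'
#' @param hap An [haplotype()].
#' @param enzymes Enzyme set used for validation.
#' @return Invisibly TRUE; errors listing offending rows otherwise.
#' @export
validate_overlay <- function(hap, enzymes = default_enzymes()) {
  ov <- hap$overlay
  if (!nrow(ov)) return(invisible(TRUE))
  bad_state <- setdiff(unique(ov$state), methylation_states())
  if (length(bad_state))
    stop("overlay of haplotype ", hap$id, " uses unknown state(s): ",
         paste(bad_state, collapse = ", "))
  sites <- hap_sites(hap, enzymes)
  key <- paste(sites$chrom, sites$start)
  miss <- !(paste(ov$chrom, ov$start) %in% key)
  if (any(miss))
    stop("overlay of haplotype ", hap$id, " has ", sum(miss),
         " entr", if (sum(miss) == 1L) "y" else "ies",
         " not coinciding with any recognition site (rows ",
         paste(which(miss), collapse = ", "), ")")
  invisible(TRUE)
}

#' Pair two haplotypes into a diploid individual
#'
#' @param hap_a,hap_b The two allelic haplotypes.
#' @param id Individual identifier.
#' @return An object of class `rlgs_diploid`.
#' @export
diploid <- function(hap_a, hap_b, id) {
  stopifnot(inherits(hap_a, "rlgs_haplotype"), inherits(hap_b, "rlgs_haplotype"),
            is.character(id), length(id) == 1L)
  if (hap_a$id == hap_b$id)
    stop("the two haplotypes of one individual must have distinct ids")
  structure(list(id = id, haplotypes = list(hap_a, hap_b)),
            class = "rlgs_diploid")
}

#' @export
print.rlgs_diploid <- function(x, ...) {
  cat(sprintf("<rlgs_diploid> %s: alleles %s / %s\n", x$id,
              x$haplotypes[[1L]]$id, x$haplotypes[[2L]]$id))
  invisible(x)
}
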