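#' @importFrom Biostrings DNAString matchPattern reverseComplement readDNAStringSet
#' @importFrom BiocGenerics start width
NULL

#' Methylation states of a recognition site
#'
#' The five per-site states understood by the cleavability model. For a CCGG
#' (MspI/HpaII) site, `internal_C` is methylation of the inner cytosine
#' (C-meC-G-G), `outer_C` of the outer cytosine (meC-C-G-G) and `both_C` of
#' both; `cpg_methylated` covers CpG methylation of sites that are not CCGG
#' (such as the NotI landmark). Unannotated sites are `unmethylated`.
#'
#' @return Character vector of the recognised state names.
#' @export
methylation_states <- function() {
  c("unmethylated", "internal_C", "outer_C", "both_C", "cpg_methylated")
}

#' Define a restriction enzyme
#'
#' An enzyme couples an IUPAC recognition sequence, the 0-based top-strand
#' cut position within that window, and a methylation-sensitivity table
#' saying which site states it can cleave.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC nucleotide string.
#' @param cut_offset Integer in `[0, nchar(recognition)]`: top-strand cut
#'   position within the recognition window.
#' @param sensitivity Named logical vector covering every state from
#'   [methylation_states()]; `TRUE` means the enzyme cleaves a site in that
#'   state.
#' @return An object of class `rlgs_enzyme`.
#' @examples
#' enzyme("MspI", "CCGG", 1,
#'        c(unmethylated = TRUE, internal_C = TRUE, outer_C = FALSE,
#'          both_C = FALSE, cpg_methylated = FALSE))
#' @export
enzyme <- function(name, recognition, cut_offset, sensitivity) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  chars <- strsplit(recognition, "", fixed = TRUE)[[1L]]
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!length(chars) || !all(chars %in% iupac))
    stop("recognition sequence for ", name,
         " contains characters that are not IUPAC nucleotide codes")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > length(chars))
    stop("cut_offset for ", name, " must lie within the recognition window")
  states <- methylation_states()
  if (is.null(names(sensitivity)) || !all(states %in% names(sensitivity)))
    stop("sensitivity table for ", name,
         " must name every methylation state: ",
         paste(states, collapse = ", "))
  cleaves <- as.logical(sensitivity[states])
  names(cleaves) <- states
  if (anyNA(cleaves))
    stop("sensitivity table for ", name, " contains missing values")
  structure(
    list(name = name, recognition = recognition,
         cut_offset = cut_offset, cleaves = cleaves),
    class = "rlgs_enzyme"
  )
}

#' @export
print.rlgs_enzyme <- function(x, ...) {
  cat(sprintf("<rlgs_enzyme> %s  %s (cut at +%d)\n  cleaves: %s\n",
              x$name, x$recognition, x$cut_offset,
              paste(names(x$cleaves)[x$cleaves], collapse = ", ")))
  invisible(x)
}

#' Built-in RLGS enzyme set
#'
#' The four enzymes of the NotI-MspI/HpaII-BamHI RLGS combinations.
#' MspI cleaves CCGG with a methylated internal cytosine (C-meC-G-G) while
#' HpaII does not; neither cleaves when the outer (or both) cytosines are
#' methylated. BamHI (GGATCC, no CpG) is insensitive. NotI is treated as
#' blocked by CpG methylation of its site by default, since RLGS uses it as
#' a methylation-sensitive landmark; set `notI_methylation_sensitive =
#' FALSE` to make it cut regardless.
#'
#' @param notI_methylation_sensitive Should `cpg_methylated` block NotI?
#' @return Named list of `rlgs_enzyme` objects (NotI, MspI, HpaII, BamHI).
#' @export
default_enzymes <- function(notI_methylation_sensitive = TRUE) {
  all_yes <- c(unmethylated = TRUE, internal_C = TRUE, outer_C = TRUE,
               both_C = TRUE, cpg_methylated = TRUE)
  notI <- all_yes
  notI["cpg_methylated"] <- !isTRUE(notI_methylation_sensitive)
  list(
    NotI  = enzyme("NotI", "GCGGCCGC", 2L, notI),
    MspI  = enzyme("MspI", "CCGG", 1L,
                   c(unmethylated = TRUE, internal_C = TRUE, outer_C = FALSE,
                     both_C = FALSE, cpg_methylated = FALSE)),
    HpaII = enzyme("HpaII", "CCGG", 1L,
                   c(unmethylated = TRUE, internal_C = FALSE, outer_C = FALSE,
                     both_C = FALSE, cpg_methylated = FALSE)),
    BamHI = enzyme("BamHI", "GGATCC", 1L, all_yes)
  )
}

#' Read enzyme definitions from a TSV config file
#'
#' One row per (enzyme, state): columns `name`, `recognition`, `cut_offset`,
#' `state`, `cleaves` (TRUE/FALSE). Every enzyme must cover every state.
#'
#' @param path Path to the TSV file.
#' @return Named list of `rlgs_enzyme` objects.
#' @export
read_enzyme_config <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset", "state", "cleaves")
  if (!all(need %in% names(tab)))
    stop("enzyme config ", path, " must have columns: ",
         paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$name), function(d) {
    sens <- as.logical(d$cleaves)
    names(sens) <- d$state
    enzyme(d$name[1L], d$recognition[1L], d$cut_offset[1L], sens)
  })
  out[unique(tab$name)]
}

is_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  identical(rc, recognition)
}

#' Scan a chromosome sequence for recognition sites
#'
#' IUPAC-aware forward-strand scan; enzymes whose recognition sequence is
#' not palindromic are additionally scanned on the reverse strand (reported
#' in top-strand coordinates with `strand == "-"`). Overlapping matches are
#' each reported. All coordinates are 0-based, half-open.
#'
#' @param sequence Chromosome sequence: a single character string (uppercase
#'   A/C/G/T/N) or a `DNAString`.
#' @param enz An [enzyme()].
#' @param chrom Chromosome name recorded in the output.
#' @return A site-match data frame with columns `chrom`, `start`, `end`,
#'   `enzyme`, `strand`, `cut_pos` (top-strand cut coordinate) and `state`
#'   (initialised to `"unmethylated"`), sorted by position.
#' @examples
#' enz <- default_enzymes()
#' find_sites("TTGCGGCCGCTT", enz$NotI)
#' @export
find_sites <- function(sequence, enz, chrom = "chr1") {
  stopifnot(inherits(enz, "rlgs_enzyme"))
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence is empty")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters other than A/C/G/T/N; ",
         "lowercase or non-IUPAC input is not accepted")
  subj <- Biostrings::DNAString(sequence)
  L <- nchar(enz$recognition)

  scan_one <- function(pattern, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    st <- BiocGenerics::start(m) - 1L
    if (!length(st)) return(NULL)
    cut <- if (strand == "+") st + enz$cut_offset else st + (L - enz$cut_offset)
    data.frame(chrom = chrom, start = st, end = st + L,
               enzyme = enz$name, strand = strand, cut_pos = cut,
               state = "unmethylated", stringsAsFactors = FALSE)
  }

  hits <- scan_one(enz$recognition, "+")
  if (!is_palindromic(enz$recognition)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enz$recognition)))
    hits <- rbind(hits, scan_one(rc, "-"))
  }
  if (is.null(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), enzyme = character(),
                      strand = character(), cut_pos = integer(),
                      state = character(), stringsAsFactors = FALSE))
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Can an enzyme cleave a site in a given methylation state?
#'
#' Pure lookup into the enzyme's sensitivity table. Vectorised over states.
#'
#' @param site Either a character vector of methylation states or a
#'   site-match data frame with a `state` column (as from [find_sites()]).
#' @param enz An [enzyme()].
#' @return Logical vector.
#' @examples
#' enz <- default_enzymes()
#' is_cleavable("internal_C", enz$MspI)   # TRUE
#' is_cleavable("internal_C", enz$HpaII)  # FALSE
#' @export
is_cleavable <- function(site, enz) {
  stopifnot(inherits(enz, "rlgs_enzyme"))
  state <- if (is.data.frame(site)) site$state else site
  state <- as.character(state)
  bad <- setdiff(unique(state), names(enz$cleaves))
  if (length(bad))
    stop("methylation state(s) missing from the sensitivity table of ",
         enz$name, ": ", paste(bad, collapse = ", "))
  unname(enz$cleaves[state])
}
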