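#' Read genome sequences from a FASTA file
#'
#' @param path FASTA file, one record per chromosome.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # keep only the first word of each FASTA header
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a methylation overlay from a BED-like TSV
#'
#' Tab-separated, `#` comment lines allowed, header optional. Columns:
#' `chrom`, `start`, `end` (0-based half-open), `state`, and optionally
#' `haplotype`. Errors cite the offending line numbers.
#'
#' @param path Path to the overlay file.
#' @return An [overlay_table()].
#' @export
read_overlay <- function(path) {
  if (!file.exists(path)) stop("overlay file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(body)) return(overlay_table())
  rows <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  has_header <- identical(rows[[1L]][1L], "chrom")
  if (has_header) { rows <- rows[-1L]; lineno <- lineno[-1L] }
  if (!length(rows)) return(overlay_table())
  nf <- vapply(rows, length, 0L)
  if (any(nf < 4L))
    stop("overlay ", path, ": expected at least 4 tab-separated fields ",
         "(chrom, start, end, state) on line(s) ",
         paste(lineno[nf < 4L], collapse = ", "))
  get <- function(i) vapply(rows, function(r) r[i], "")
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("overlay ", path, ": non-integer coordinates on line(s) ",
         paste(lineno[bad], collapse = ", "))
  state <- get(4L)
  bad <- !(state %in% methylation_states())
  if (any(bad))
    stop("overlay ", path, ": unknown methylation state on line(s) ",
         paste(lineno[bad], collapse = ", "))
  hap <- if (all(nf >= 5L)) get(5L) else NA_character_
  overlay_table(get(1L), start, end, state, hap)
}

#' Write a methylation overlay
#'
#' @param overlay An [overlay_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(overlay, path) {
  utils::write.table(overlay, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sprintf("%.17g", x))
}

#' Write a spot pattern to TSV
#'
#' One header line; `#` comment lines echo the sample, combo and gel
#' windows (plus any extra `config` entries) so the pattern round-trips
#' through [read_spot_table()] exactly.
#'
#' @param pattern An `rlgs_pattern`.
#' @param path Output path.
#' @param config Optional named character vector echoed as comments.
#' @return Invisibly, `path`.
#' @export
write_spot_table <- function(pattern, path, config = NULL) {
  stopifnot(inherits(pattern, "rlgs_pattern"))
  g <- pattern$gel
  hdr <- c(sprintf("#sample_id=%s", pattern$sample_id),
           sprintf("#combo=%s", pattern$combo),
           sprintf("#gel_1d_min=%s", fmt_num(g$window_1d[1L])),
           sprintf("#gel_1d_max=%s", fmt_num(g$window_1d[2L])),
           sprintf("#gel_2d_min=%s", fmt_num(g$window_2d[1L])),
           sprintf("#gel_2d_max=%s", fmt_num(g$window_2d[2L])))
  if (!is.null(config))
    hdr <- c(hdr, sprintf("#%s=%s", names(config), as.character(config)))
  sp <- pattern$spots
  body <- paste(sprintf("%.17g", sp$x1), sprintf("%.17g", sp$x2),
                sp$len_1d, sp$len_2d, sprintf("%.17g", sp$intensity),
                sp$loci, sp$n_loci, sep = "\t")
  writeLines(c(hdr,
               paste("x1", "x2", "len_1d", "len_2d", "intensity",
                     "loci", "n_loci", sep = "\t"),
               body), path)
  invisible(path)
}

#' Read a spot pattern written by [write_spot_table()]
#'
#' @param path Path to the TSV file.
#' @return An `rlgs_pattern`.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(vals, keys)
  need <- c("sample_id", "combo", "gel_1d_min", "gel_1d_max",
            "gel_2d_min", "gel_2d_max")
  if (!all(need %in% keys))
    stop("spot table ", path, " lacks config echo line(s): ",
         paste(setdiff(need, keys), collapse = ", "))
  gel <- gel_model(as.numeric(meta[c("gel_1d_min", "gel_1d_max")]),
                   as.numeric(meta[c("gel_2d_min", "gel_2d_max")]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) <= 1L) {
    spots <- empty_spots()
  } else {
    spots <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE)
    spots$len_1d <- as.integer(spots$len_1d)
    spots$len_2d <- as.integer(spots$len_2d)
    spots$n_loci <- as.integer(spots$n_loci)
  }
  spot_pattern(unname(meta["sample_id"]), unname(meta["combo"]), spots, gel)
}

#' Write an enumerated-fragment table (pre-filter debugging output)
#'
#' @param fragments Data frame from [enumerate_fragments()].
#' @param path Output path.
#' @param config Optional named character vector echoed as `#` comments.
#' @return Invisibly, `path`.
#' @export
write_fragment_table <- function(fragments, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("#%s=%s", names(config), as.character(config)), con)
  utils::write.table(fragments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a segregation report
#'
#' @param result Data frame from [flag_non_mendelian()].
#' @param path Output path.
#' @param config Optional named character vector echoed as `#` comments.
#' @return Invisibly, `path`.
#' @export
write_segregation_table <- function(result, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("#%s=%s", names(config), as.character(config)), con)
  utils::write.table(result, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write fixture files so every stage can run from disk alone
#'
#' Emits one FASTA per parental haplotype, a combined overlay TSV covering
#' parents and progeny, and a panel manifest TSV (individual id, panel,
#' source haplotype FASTA per allele, model, seed). Progeny sequences are
#' identical to a parental haplotype sequence; the manifest records which.
#'
#' @param fixture An `rlgs_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "rlgs_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parents <- list(fixture$parent_N, fixture$parent_K)
  seq_file <- character(0)
  ov_all <- list()
  for (p in parents) {
    for (h in p$haplotypes) {
      f <- file.path(dir, paste0(h$id, ".fasta"))
      write_genome_fasta(h$sequences, f)
      seq_file[h$id] <- basename(f)
      if (nrow(h$overlay)) ov_all[[length(ov_all) + 1L]] <- h$overlay
    }
  }
  manifest <- list()
  for (nm in names(fixture$panels)) {
    panel <- fixture$panels[[nm]]
    for (k in seq_along(panel$individuals)) {
      ind <- panel$individuals[[k]]
      src <- vapply(ind$haplotypes, function(h) {
        i <- which(vapply(parents, function(p)
          any(vapply(p$haplotypes, function(ph)
            identical(ph$sequences, h$sequences), TRUE)), TRUE))[1L]
        ph <- parents[[i]]$haplotypes[[
          which(vapply(parents[[i]]$haplotypes, function(ph)
            identical(ph$sequences, h$sequences), TRUE))[1L]]]
        seq_file[ph$id]
      }, "")
      for (h in ind$haplotypes)
        if (nrow(h$overlay)) ov_all[[length(ov_all) + 1L]] <- h$overlay
      manifest[[length(manifest) + 1L]] <- data.frame(
        panel = nm, individual = ind$id,
        hap1 = ind$haplotypes[[1L]]$id, hap1_fasta = src[1L],
        hap2 = ind$haplotypes[[2L]]$id, hap2_fasta = src[2L],
        model = panel$model$name, seed = panel$seed,
        stringsAsFactors = FALSE)
    }
  }
  ov <- if (length(ov_all)) do.call(rbind, ov_all) else overlay_table()
  write_overlay(ov, file.path(dir, "overlay.tsv"))
  utils::write.table(do.call(rbind, manifest) %||%
                       data.frame(panel = character()),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed=%d", fixture$seed),
               sprintf("focal_chrom=%s", fixture$focal$chrom),
               sprintf("focal_len_1d=%d", fixture$focal$len_1d),
               sprintf("focal_len_2d=%d", fixture$focal$len_2d),
               sprintf("focal_m_start=%d", fixture$focal$m_start),
               sprintf("focal_b_start=%d", fixture$focal$b_start)),
             file.path(dir, "fixture_config.txt"))
  invisible(dir)
}
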