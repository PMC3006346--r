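## Multilocus sequential PHYLIP: one block per locus, concatenated.
## Each block: "<n> <len>" header, then n records of "<name> <sequence>"
## (sequence may wrap over several lines until <len> characters are read).
## This is the dialect consumed by multispecies-coalescent MCMC programs.

#' Construct a single-locus alignment
#'
#' @param locus_id locus identifier.
#' @param sequences named character vector of equal-length nucleotide
#'   strings (`A`, `C`, `G`, `T`, `N`); names are sample labels.
#' @param sample_map named character vector mapping sample label to taxon
#'   code (see [default_sample_map()]).
#' @return object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, sequences, sample_map = default_sample_map()) {
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("locus '", locus_id, "': sequences have unequal lengths")
  unknown <- setdiff(names(sequences), names(sample_map))
  if (length(unknown))
    warning("locus '", locus_id, "': unknown sample labels: ",
            paste(unknown, collapse = ", "))
  structure(
    list(locus_id = as.character(locus_id),
         sequences = sequences,
         sample_to_taxon = sample_map[names(sequences)],
         length = unname(lens[1])),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", length(x$sequences),
      " sequences x ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read a multilocus sequential PHYLIP file
#'
#' Parses a concatenation of sequential-PHYLIP blocks into a list of
#' [locus_alignment()] objects. Malformed headers, sequence-length
#' mismatches and an empty file raise errors naming the offending block.
#'
#' @param path file path.
#' @param sample_map named character vector mapping sample labels to taxon
#'   codes.
#' @return list of `locus_alignment` (class `multilocus_alignment`).
#' @export
read_phylip_multilocus <- function(path, sample_map = default_sample_map()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  loci <- list()
  i <- 1L
  block <- 0L
  while (i <= length(lines)) {
    block <- block + 1L
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    n <- suppressWarnings(as.integer(hdr[1]))
    len <- suppressWarnings(as.integer(hdr[2]))
    if (length(hdr) < 2 || is.na(n) || is.na(len) || n < 1 || len < 1)
      stop("malformed PHYLIP header in block ", block, ": '", lines[i], "'")
    i <- i + 1L
    seqs <- character(n); nms <- character(n)
    for (s in seq_len(n)) {
      if (i > length(lines))
        stop("block ", block, ": file truncated before sequence ", s)
      rec <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      nms[s] <- rec[1]
      sq <- paste(rec[-1], collapse = "")
      i <- i + 1L
      ## sequence may continue on following lines until `len` reached
      while (nchar(sq) < len && i <= length(lines) &&
             !grepl("^\\s*\\d+\\s+\\d+\\s*$", lines[i])) {
        sq <- paste0(sq, gsub("\\s+", "", lines[i]))
        i <- i + 1L
      }
      if (nchar(sq) != len)
        stop("block ", block, ", sequence '", nms[s], "': header declares ",
             len, " bp but ", nchar(sq), " were found")
      seqs[s] <- toupper(sq)
    }
    loci[[block]] <- locus_alignment(paste0("L", block), setNames(seqs, nms),
                                     sample_map)
  }
  structure(loci, class = "multilocus_alignment")
}

#' Write a multilocus sequential PHYLIP file
#'
#' @param alignments list of [locus_alignment()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phylip_multilocus <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in alignments) {
    writeLines(sprintf("%d %d", length(aln$sequences), aln$length), con)
    nm <- names(aln$sequences)
    ## classic PHYLIP caps labels at 10 characters
    writeLines(sprintf("%-10s  %s", substr(nm, 1, 10), aln$sequences), con)
  }
  invisible(path)
}

#' Total alignment length over loci
#'
#' @param alignments a `multilocus_alignment`.
#' @return integer, summed locus lengths in bp.
#' @export
total_bp <- function(alignments) {
  sum(vapply(alignments, function(a) a$length, numeric(1)))
}
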