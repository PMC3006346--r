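## Divergent-site table: one row per biallelic site, grouped by locus.
## Genotype columns hold copies of the `allele_der` allele per taxon
## (diploids 0/1/2; the haploid outgroup O 0/1; NA = missing call).
## Before polarization the anc/der orientation is provisional (the
## outgroup allele is used when available); polarize() makes it definite.

site_table_cols <- c("locus_id", "pos", "allele_anc", "allele_der", ALL_TAXA)

#' Construct a divergent-site table
#'
#' @param df data.frame with columns `locus_id`, `pos`, `allele_anc`,
#'   `allele_der` and one genotype column per taxon code (`F`, `S`, `A`,
#'   `M` coded 0/1/2 copies of the derived allele, `O` coded 0/1; `NA`
#'   means missing). An optional `A2` column holds the second Asian
#'   individual.
#' @param polarized logical; `TRUE` once `allele_anc` is the outgroup
#'   allele at every site.
#' @param counts named list of accounting counts carried through filters.
#' @return object of class `div_sites` (a data.frame).
#' @export
div_sites <- function(df, polarized = FALSE, counts = list()) {
  missing_cols <- setdiff(site_table_cols, names(df))
  if (length(missing_cols))
    stop("site table lacks columns: ", paste(missing_cols, collapse = ", "))
  df$locus_id <- as.character(df$locus_id)
  df$pos <- as.integer(df$pos)
  for (tx in ALL_TAXA) df[[tx]] <- as.integer(df[[tx]])
  bad <- !is.na(df$O) & !(df$O %in% 0:1)
  if (any(bad))
    stop("outgroup genotypes must be 0/1; offending site ",
         df$locus_id[which(bad)[1]], ":", df$pos[which(bad)[1]])
  for (tx in ELEPHANTID_TAXA) {
    bad <- !is.na(df[[tx]]) & !(df[[tx]] %in% 0:2)
    if (any(bad))
      stop("genotypes for ", tx, " must be 0/1/2; offending site ",
           df$locus_id[which(bad)[1]], ":", df$pos[which(bad)[1]])
  }
  ## allele fields must be single, distinct bases (two observed alleles)
  one_base <- function(a) !is.na(a) & grepl("^[ACGTacgt]$", a)
  bad <- !(one_base(df$allele_anc) & one_base(df$allele_der)) |
    toupper(df$allele_anc) == toupper(df$allele_der)
  if (any(bad)) {
    k <- which(bad)[1]
    stop("site ", df$locus_id[k], ":", df$pos[k],
         " does not carry exactly two single-base alleles (found '",
         df$allele_anc[k], "'/'", df$allele_der[k], "')")
  }
  df$allele_anc <- toupper(df$allele_anc)
  df$allele_der <- toupper(df$allele_der)
  structure(df,
            class = c("div_sites", "data.frame"),
            polarized = isTRUE(polarized),
            counts = counts)
}

#' @export
print.div_sites <- function(x, ...) {
  cat("<div_sites> ", nrow(x), " biallelic sites over ",
      length(unique(x$locus_id)), " loci",
      if (isTRUE(attr(x, "polarized"))) " (polarized)", "\n", sep = "")
  NextMethod()
}

#' Is the table polarized?
#' @param table a `div_sites` table.
#' @return logical.
#' @export
is_polarized <- function(table) isTRUE(attr(table, "polarized"))

#' Accounting counts attached to a site table
#' @param table a `div_sites` table.
#' @return named list of counts logged by the filters.
#' @export
site_counts <- function(table) attr(table, "counts")

with_counts <- function(table, ...) {
  cts <- attr(table, "counts")
  new <- list(...)
  cts[names(new)] <- new
  attr(table, "counts") <- cts
  table
}

## subset preserving class/attrs
subset_sites <- function(table, keep) {
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$class <- class(table)
  attr(out, "polarized") <- attr(table, "polarized")
  attr(out, "counts") <- attr(table, "counts")
  out
}

#' Derived-allele frequencies per taxon
#'
#' @param table a polarized `div_sites` table.
#' @param taxa taxon codes (columns of the result).
#' @return numeric matrix, sites x taxa, entries in `{0, 0.5, 1, NA}`.
#' @export
derived_freq <- function(table, taxa = ELEPHANTID_TAXA) {
  stopifnot(is_polarized(table))
  m <- sapply(taxa, function(tx) table[[tx]] / taxon_ploidy(tx))
  matrix(m, nrow = nrow(table), dimnames = list(NULL, taxa))
}

#' Restrict to sites called in all five taxa
#' @param table a `div_sites` table.
#' @return the complete-site subset.
#' @export
complete_sites <- function(table) {
  keep <- rowSums(is.na(as.matrix(table[ALL_TAXA]))) == 0
  subset_sites(table, keep)
}

#' Which sites are polymorphic among the elephantids?
#'
#' A polarized site is elephantid-polymorphic when the pooled derived
#' frequency over the eight elephantid chromosomes is strictly between 0
#' and 1 (the complement is a fixed elephantid--outgroup difference).
#'
#' @param table a polarized `div_sites` table.
#' @return logical vector over sites.
#' @export
is_elephantid_polymorphic <- function(table) {
  stopifnot(is_polarized(table))
  tot <- rowSums(as.matrix(table[ELEPHANTID_TAXA]))
  !is.na(tot) & tot > 0 & tot < 8
}

#' Read a divergent-site table
#'
#' Tab-separated, header row, columns `locus_id`, `pos`, `allele_anc`,
#' `allele_der`, `F`, `S`, `A`, `M`, `O` (optional `A2`), genotypes coded
#' 0/1/2 (O: 0/1) with `.` for missing. Rows that do not carry exactly two
#' single-base alleles are rejected with their coordinates.
#'
#' @param path file path.
#' @param polarized logical, whether the file is already polarized.
#' @return a `div_sites` table.
#' @export
read_site_table <- function(path, polarized = TRUE) {
  df <- read.delim(path, na.strings = ".", colClasses = "character",
                   check.names = FALSE)
  extra <- setdiff(names(df), c(site_table_cols, "A2"))
  if (length(extra))
    stop("unknown taxon column(s) in site table: ", paste(extra, collapse = ", "))
  for (cl in intersect(c(ALL_TAXA, "A2", "pos"), names(df)))
    df[[cl]] <- as.integer(df[[cl]])
  div_sites(df, polarized = polarized,
            counts = list(n_read = nrow(df)))
}

#' Write a divergent-site table
#'
#' Inverse of [read_site_table()]; the round trip is the identity on the
#' canonical column layout (missing genotypes written as `.`).
#'
#' @param table a `div_sites` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  df <- as.data.frame(table)
  keep <- intersect(c(site_table_cols, "A2"), names(df))
  df <- df[keep]
  for (cl in keep) df[[cl]] <- as.character(df[[cl]])
  df[is.na(df)] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
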