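## Site calling, outgroup polarization and the recurrent-mutation filter.

#' Call biallelic divergent sites from multilocus alignments
#'
#' Emits every alignment column at which exactly two distinct alleles are
#' observed among non-`N` calls across all samples. Loci with more than
#' `max_poly_per_locus` positions polymorphic *within the elephantids* are
#' dropped entirely (a guard against paralogous amplification) and listed
#' in the `dropped_loci` attribute.
#'
#' A taxon's diploid genotype at a site is the number of copies of the
#' second allele carried by its two chromosomes; it is missing when any of
#' the taxon's chromosomes is `N` there. When the outgroup is called, the
#' provisional `allele_anc` is the outgroup allele (made definitive by
#' [polarize()]).
#'
#' @param alignments a `multilocus_alignment` (list of [locus_alignment()]).
#' @param max_poly_per_locus integer QC threshold (default 3).
#' @return an unpolarized `div_sites` table; attributes `dropped_loci`
#'   (character) and counts.
#' @export
call_divergent_sites <- function(alignments, max_poly_per_locus = 3) {
  rows <- list()
  dropped <- character()
  for (aln in alignments) {
    mat <- do.call(rbind, strsplit(aln$sequences, ""))
    rownames(mat) <- names(aln$sequences)
    taxa_of <- aln$sample_to_taxon
    eleph_rows <- which(taxa_of %in% ELEPHANTID_TAXA)
    ## columns polymorphic among elephantid chromosomes (QC count)
    n_poly <- 0L
    site_rows <- list()
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      obs <- col[col %in% c("A", "C", "G", "T")]
      alle <- unique(obs)
      ecol <- col[eleph_rows]
      eobs <- unique(ecol[ecol %in% c("A", "C", "G", "T")])
      if (length(eobs) > 1) n_poly <- n_poly + 1L
      if (length(alle) != 2) next
      ## orient on the outgroup allele when available
      o_idx <- which(taxa_of == "O")
      o_call <- if (length(o_idx) && col[o_idx[1]] %in% alle) col[o_idx[1]] else NA
      a1 <- if (!is.na(o_call)) o_call else alle[1]
      a2 <- setdiff(alle, a1)
      geno <- lapply(ALL_TAXA, function(tx) {
        calls <- col[which(taxa_of == tx)]
        if (!length(calls) || any(!calls %in% c("A", "C", "G", "T")))
          return(NA_integer_)
        sum(calls == a2)
      })
      names(geno) <- ALL_TAXA
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(locus_id = aln$locus_id, pos = j,
                   allele_anc = a1, allele_der = a2,
                   geno, check.names = FALSE)
    }
    if (n_poly > max_poly_per_locus) {
      dropped <- c(dropped, aln$locus_id)
      next
    }
    rows <- c(rows, site_rows)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), pos = integer(),
               allele_anc = character(), allele_der = character(),
               F = integer(), S = integer(), A = integer(), M = integer(),
               O = integer(), check.names = FALSE)
  out <- div_sites(df, polarized = FALSE,
                   counts = list(n_called = nrow(df),
                                 n_loci_dropped = length(dropped)))
  attr(out, "dropped_loci") <- dropped
  out
}

#' Polarize a divergent-site table on the mastodon outgroup
#'
#' Sets `allele_anc` to the outgroup allele at every site and recodes the
#' genotype columns as derived-allele copies. Sites with no outgroup call
#' cannot be polarized; they are excluded and counted
#' (`n_unpolarizable` in [site_counts()]). Polarizing twice is a no-op.
#'
#' @param table a `div_sites` table containing an `O` column.
#' @return a polarized `div_sites` table.
#' @export
polarize <- function(table) {
  if (!("O" %in% names(table)) || all(is.na(table$O)))
    stop("cannot polarize: no mastodon (outgroup) calls in the site table; ",
         "supply an 'O' column with 0/1 genotypes")
  if (is_polarized(table)) return(table)
  n_in <- nrow(table)
  usable <- !is.na(table$O)
  out <- subset_sites(table, usable)
  flip <- out$O == 1L
  if (any(flip)) {
    anc <- out$allele_anc
    out$allele_anc[flip] <- out$allele_der[flip]
    out$allele_der[flip] <- anc[flip]
    for (tx in ELEPHANTID_TAXA)
      out[[tx]][flip] <- 2L - out[[tx]][flip]
    out$O[flip] <- 0L
    if ("A2" %in% names(out)) out$A2[flip] <- 2L - out$A2[flip]
  }
  attr(out, "polarized") <- TRUE
  with_counts(out,
              n_input = n_in,
              n_unpolarizable = n_in - nrow(out),
              n_polarized = nrow(out))
}

## Configurations of derived presence across the African/Eurasian split
## explainable by one mutation plus at most one deep-coalescing lineage:
## any partial carrier set on one side can coalesce into a single deep
## lineage before crossing the split, so one mutation suffices exactly
## when the other side is fully fixed derived. Patterns partial on BOTH
## sides need two independently deep lineages (or recurrent mutation).
one_mutation_ok <- function(f, s, a, m) {
  (f == 2 & s == 2) | (a == 2 & m == 2)
}

#' Remove sites with a high probability of recurrent mutation
#'
#' The symptom targeted is a derived allele seen on both sides of the
#' African/Eurasian split in a configuration better explained by
#' sequencing error or recurrent mutation than by a single mutation on
#' the species tree.
#'
#' Two rules are available:
#' \describe{
#'   \item{`"two-mutation"` (default)}{remove sites where the derived
#'     allele is present on both sides of the split but the configuration
#'     cannot be produced by a single mutation even allowing one
#'     deep-coalescing lineage. Since any partial carrier set on one side
#'     can ride a single deep lineage across the split, one mutation
#'     suffices exactly when the other side is fully fixed derived; the
#'     rule therefore removes cross-clade sites where *neither* side is
#'     fixed. Sites segregating on both sides are a strict subset.}
#'   \item{`"segregating-both-sides"`}{remove only sites whose derived
#'     allele segregates (frequency 0.5, i.e. a heterozygote) in at least
#'     one African *and* at least one Eurasian taxon.}
#' }
#'
#' Sites with missing elephantid genotypes are never removed by this
#' filter (they are excluded later by completeness restriction). Site
#' accounting is conserved: `n_removed + nrow(result) = nrow(input)`.
#'
#' @param table a polarized `div_sites` table.
#' @param rule filtering rule, see Details.
#' @return filtered `div_sites`; counts gain `n_before_recurrent`,
#'   `n_removed_recurrent`, `n_retained`; the removed subset is attached
#'   as attribute `removed_sites`.
#' @export
filter_recurrent <- function(table,
                             rule = c("two-mutation", "segregating-both-sides")) {
  rule <- match.arg(rule)
  stopifnot(is_polarized(table))
  f <- table$F; s <- table$S; a <- table$A; m <- table$M
  cc <- !(is.na(f) | is.na(s) | is.na(a) | is.na(m))
  remove <- rep(FALSE, nrow(table))
  if (rule == "segregating-both-sides") {
    remove[cc] <- (f[cc] == 1L | s[cc] == 1L) & (a[cc] == 1L | m[cc] == 1L)
  } else {
    both <- (f[cc] + s[cc]) > 0L & (a[cc] + m[cc]) > 0L
    remove[cc] <- both & !one_mutation_ok(f[cc], s[cc], a[cc], m[cc])
  }
  out <- subset_sites(table, !remove)
  out <- with_counts(out,
                     n_before_recurrent = nrow(table),
                     n_removed_recurrent = sum(remove),
                     n_retained = nrow(out))
  attr(out, "removed_sites") <- subset_sites(table, remove)
  out
}
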