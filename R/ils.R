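## Seven-class polarized site-pattern spectrum for a taxon triple with
## the mastodon outgroup, and the incomplete-lineage-sorting ratio test.
##
## For a triple (1, 2, 3) with derived frequencies (f1, f2, f3) at a
## site, the expected rate of a class b = (b1 b2 b3) in {0,1}^3 \ {000}
## is the frequency product prod_i f_i^{b_i} (1 - f_i)^{1 - b_i}: the
## probability that one chromosome drawn per taxon shows exactly that
## derived-allele configuration. Class 111 is reported as "mastodon"
## (all elephantids derived relative to the outgroup). Discordant
## classes 13 and 23 — a non-sister pair sharing the derived allele —
## diagnose incomplete lineage sorting.

CLADE_CODES <- list(E = EURASIAN_TAXA, L = AFRICAN_TAXA)
SITE_CLASSES <- c("1", "2", "3", "12", "13", "23", "mastodon")

#' Merged-clade derived-allele frequency
#'
#' The derived frequency of a merged clade (Eurasian = \{A, M\} or
#' Loxodonta = \{F, S\}) is the chromosome-weighted mean of the member
#' frequencies (each member contributes two chromosomes). Sites with a
#' missing member are excluded upstream.
#'
#' @param freqs numeric vector/matrix of member derived frequencies.
#' @return mean frequency in \[0, 1\].
#' @export
merge_clade_frequency <- function(freqs) {
  if (is.matrix(freqs)) rowMeans(freqs) else mean(freqs)
}

## per-site derived frequencies for a triple member ("F","S","A","M","E","L")
triple_freqs <- function(table, triple) {
  stopifnot(is_polarized(table), length(triple) == 3)
  f <- sapply(triple, function(tx) {
    if (tx %in% names(CLADE_CODES))
      merge_clade_frequency(derived_freq(table, CLADE_CODES[[tx]]))
    else
      derived_freq(table, tx)[, 1]
  })
  matrix(f, nrow = nrow(table), dimnames = list(NULL, triple))
}

#' Polarized site-class spectrum for a taxon triple
#'
#' Accumulates, over the polarized and recurrence-filtered sites called
#' in all taxa, the frequency-product rate of each of the seven derived
#' site classes for the ordered triple. Members `"E"` and `"L"` denote
#' the merged Eurasian (\{A, M\}) and Loxodonta (\{F, S\}) clades.
#'
#' @param table polarized `div_sites` table.
#' @param triple character vector of three members, e.g. `c("S","F","E")`.
#' @return object of class `site_spectrum`: list with `triple`, `rates`
#'   (named over `1, 2, 3, 12, 13, 23, mastodon`), `n_sites`.
#' @export
site_class_spectrum <- function(table, triple) {
  tab <- complete_sites(table)
  f <- triple_freqs(tab, triple)
  rates <- setNames(numeric(7), SITE_CLASSES)
  class_bits <- list("1" = c(1, 0, 0), "2" = c(0, 1, 0), "3" = c(0, 0, 1),
                     "12" = c(1, 1, 0), "13" = c(1, 0, 1), "23" = c(0, 1, 1),
                     "mastodon" = c(1, 1, 1))
  for (cl in SITE_CLASSES) {
    b <- class_bits[[cl]]
    w <- rep(1, nrow(f))
    for (i in 1:3) w <- w * (if (b[i] == 1) f[, i] else 1 - f[, i])
    rates[cl] <- sum(w)
  }
  structure(list(triple = triple, rates = rates, n_sites = nrow(f)),
            class = "site_spectrum")
}

#' @export
print.site_spectrum <- function(x, ...) {
  cat("<site_spectrum> triple ", paste(x$triple, collapse = "-"),
      "-mastodon over ", x$n_sites, " sites\n", sep = "")
  print(round(x$rates, 1))
  invisible(x)
}

#' Incomplete-lineage-sorting rate of a spectrum
#'
#' The summed rate of the two discordant classes (a non-sister taxon
#' sharing the derived allele with the third member), divided by the
#' savanna-Asian divergence.
#'
#' @param spectrum a `site_spectrum`.
#' @param t_sa positive normalizer (savanna-Asian divergence).
#' @return non-negative scalar.
#' @export
ils_rate <- function(spectrum, t_sa) {
  stopifnot(inherits(spectrum, "site_spectrum"))
  if (t_sa <= 0) stop("normalizer t_SA must be positive")
  unname((spectrum$rates["13"] + spectrum$rates["23"]) / t_sa)
}

ils_rates_of <- function(tab) {
  t_sa <- pairwise_divergence(tab, "S", "A")
  c(fs = ils_rate(site_class_spectrum(tab, c("S", "F", "E")), t_sa),
    am = ils_rate(site_class_spectrum(tab, c("A", "M", "L")), t_sa))
}

#' Forest/savanna versus Asian/mammoth ILS ratio test
#'
#' Computes the ILS rate for the (S, F, Eurasian) and (A, M, Loxodonta)
#' triples, their ratio, a one-sided p value for the ratio exceeding
#' unity (z on the log-ratio) and a two-sided p value for the rate
#' difference, all with weighted-jackknife uncertainty over loci.
#'
#' @param table polarized, recurrence-filtered `div_sites` table.
#' @return object of class `ils_result`: list with `rate_fs`, `rate_am`,
#'   `ratio`, `p_exceed_unity`, `p_two_sided`, and the two underlying
#'   `jackknife_result`s (`jk_log_ratio`, `jk_diff`).
#' @export
ils_ratio_test <- function(table) {
  tab <- complete_sites(table)
  rates <- ils_rates_of(tab)
  if (rates["am"] <= 0)
    return(structure(list(rate_fs = unname(rates["fs"]),
                          rate_am = unname(rates["am"]),
                          ratio = NA_real_, degenerate = TRUE),
                     class = "ils_result"))
  ## the log-ratio jackknife needs every delete-one subtable to retain a
  ## positive rate on both sides; sparse tables (few discordant sites)
  ## cannot support it, in which case only the difference test is reported
  jk_lr <- tryCatch(
    weighted_jackknife(function(tt) {
      r <- ils_rates_of(tt)
      if (any(r <= 0)) stop("degenerate ILS rate in delete-one subtable")
      log(r["fs"]) - log(r["am"])
    }, tab, one_sided = TRUE),
    error = function(e) NULL)
  jk_diff <- weighted_jackknife(function(tt) {
    r <- ils_rates_of(tt); r["fs"] - r["am"]
  }, tab)
  structure(list(rate_fs = unname(rates["fs"]),
                 rate_am = unname(rates["am"]),
                 ratio = unname(rates["fs"] / rates["am"]),
                 p_exceed_unity = if (is.null(jk_lr)) NA_real_ else jk_lr$p,
                 p_two_sided = jk_diff$p,
                 jk_log_ratio = jk_lr, jk_diff = jk_diff,
                 degenerate = FALSE),
            class = "ils_result")
}

#' @export
print.ils_result <- function(x, ...) {
  cat("<ils_result> ILS rate F/S =", signif(x$rate_fs, 3),
      ", A/M =", signif(x$rate_am, 3), "\n")
  if (!isTRUE(x$degenerate))
    cat("  ratio =", signif(x$ratio, 3),
        " P(>1) =", signif(x$p_exceed_unity, 3),
        " two-sided p =", signif(x$p_two_sided, 3), "\n")
  invisible(x)
}

#' Table-2-shaped ILS report
#'
#' One row per triple with the seven class rates, the normalized
#' sister-pair divergence and the ILS rate.
#'
#' @param table polarized, recurrence-filtered `div_sites` table.
#' @return data.frame.
#' @export
ils_report <- function(table) {
  tab <- complete_sites(table)
  t_sa <- pairwise_divergence(tab, "S", "A")
  triples <- list(c("S", "F", "E"), c("A", "M", "L"))
  rows <- lapply(triples, function(tr) {
    sp <- site_class_spectrum(tab, tr)
    sister_div <- pairwise_divergence(tab, tr[1], tr[2]) / t_sa
    cbind(data.frame(triple = paste(c(tr, "mastodon"), collapse = "-")),
          as.data.frame(as.list(sp$rates), check.names = FALSE),
          data.frame(sister_divergence = sister_div,
                     ils_rate = ils_rate(sp, t_sa)))
  })
  do.call(rbind, rows)
}
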