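## Normalized genetic divergence, heterozygosity, relative-rate tests and
## absolute-time calibration.
##
## Divergence uses expected-mismatch (frequency product) counting: the
## contribution of a site to the x-y divergence is the probability that
## one chromosome drawn from x and one from y carry different alleles,
## f_x(1-f_y) + f_y(1-f_x). Summed over polarized sites this reproduces
## the fractional site counts of the published site-class tables, and
## sites fixed derived in both taxa contribute zero, so restricting to
## elephantid-polymorphic sites leaves cross-taxon divergences unchanged.

div_site_contrib <- function(table, x, y) {
  fx <- table[[x]] / taxon_ploidy(x)
  fy <- table[[y]] / taxon_ploidy(y)
  fx * (1 - fy) + fy * (1 - fx)
}

#' Pairwise genetic divergence or heterozygosity
#'
#' For distinct taxa, the expected number of allele mismatches between one
#' chromosome drawn from each taxon, summed over sites. For `x == y`, the
#' heterozygosity: the count of heterozygous genotypes of the designated
#' individual.
#'
#' @param table a polarized `div_sites` table, restricted to complete
#'   sites (see [complete_sites()]).
#' @param x,y taxon codes.
#' @return non-negative scalar.
#' @export
pairwise_divergence <- function(table, x, y) {
  stopifnot(is_polarized(table), x %in% ALL_TAXA, y %in% ALL_TAXA)
  if (nrow(table) == 0) stop("empty site table")
  if (x == y) {
    if (x == "O") return(0)
    return(sum(table[[x]] == 1L, na.rm = TRUE))
  }
  sum(div_site_contrib(table, x, y), na.rm = TRUE)
}

#' Divergence matrix over taxa, normalized by savanna-Asian divergence
#'
#' Computes all cross-taxon divergences and within-taxon heterozygosities
#' on the complete-site subset of `table`, normalizes by the savanna-Asian
#' divergence \eqn{t_{SA}}, and (optionally) attaches weighted-jackknife
#' standard errors to every normalized entry. The normalizing entry has
#' zero uncertainty by construction.
#'
#' @param table a polarized `div_sites` table.
#' @param taxa taxon codes to include (default all five).
#' @param jackknife logical; attach SEs via [weighted_jackknife()].
#' @return object of class `div_matrix`: list with `raw` and `normalized`
#'   symmetric matrices (diagonals = heterozygosities), `se` (or NULL),
#'   `t_sa`, `n_sites`.
#' @export
divergence_matrix <- function(table, taxa = ALL_TAXA, jackknife = TRUE) {
  tab <- complete_sites(table)
  if (nrow(tab) == 0) stop("no complete sites in table")
  k <- length(taxa)
  raw <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k)) for (j in i:k) {
    v <- pairwise_divergence(tab, taxa[i], taxa[j])
    raw[i, j] <- raw[j, i] <- v
  }
  t_sa <- pairwise_divergence(tab, "S", "A")
  if (t_sa <= 0) stop("savanna-Asian divergence is zero; cannot normalize")
  se <- NULL
  if (jackknife) {
    se <- matrix(NA_real_, k, k, dimnames = list(taxa, taxa))
    for (i in seq_len(k)) for (j in i:k) {
      stat <- local({
        xi <- taxa[i]; yj <- taxa[j]
        function(tt) pairwise_divergence(tt, xi, yj) /
          pairwise_divergence(tt, "S", "A")
      })
      jk <- weighted_jackknife(stat, tab)
      se[i, j] <- se[j, i] <- jk$se
    }
  }
  structure(list(raw = raw, normalized = raw / t_sa, se = se,
                 t_sa = t_sa, n_sites = nrow(tab)),
            class = "div_matrix")
}

#' @export
print.div_matrix <- function(x, ...) {
  cat("<div_matrix> normalized by savanna-Asian divergence t_SA =",
      signif(x$t_sa, 5), "over", x$n_sites, "sites\n")
  print(round(100 * x$normalized, 1))
  invisible(x)
}

#' Relative-rate test between two taxa
#'
#' Compares the number of divergent sites accumulated on each lineage
#' since the two taxa split, polarized on the mastodon root:
#' \eqn{n_x = \sum f_x (1 - f_y)} counts derived alleles private to `x`
#' (and symmetrically \eqn{n_y}). The statistic is the normalized
#' difference \eqn{(n_x - n_y)/(n_x + n_y)}; its z score and two-sided
#' normal p value come from the weighted jackknife over loci. Equal rates
#' give 0.
#'
#' @param table polarized `div_sites` table (complete sites are used).
#' @param x,y elephantid taxon codes.
#' @return a `jackknife_result`, with `n_x`, `n_y` attached; if
#'   `n_x + n_y == 0` the test is undefined and a list with
#'   `undefined = TRUE` is returned.
#' @export
relative_rate_test <- function(table, x, y) {
  tab <- complete_sites(table)
  stopifnot(is_polarized(tab))
  nx <- sum(derived_contrast(tab, x, y))
  ny <- sum(derived_contrast(tab, y, x))
  if (nx + ny == 0)
    return(list(undefined = TRUE, n_x = nx, n_y = ny))
  stat <- function(tt) {
    a <- sum(derived_contrast(tt, x, y)); b <- sum(derived_contrast(tt, y, x))
    if (a + b == 0) return(0)
    (a - b) / (a + b)
  }
  res <- weighted_jackknife(stat, tab)
  res$n_x <- nx; res$n_y <- ny
  res
}

## derived in x, absent in y: f_x (1 - f_y)
derived_contrast <- function(table, x, y) {
  fx <- table[[x]] / taxon_ploidy(x)
  fy <- table[[y]] / taxon_ploidy(y)
  v <- fx * (1 - fy)
  v[!is.na(v)]
}

#' Fossil calibration window for the African-Eurasian split
#'
#' @param t_lox_eur_mya numeric length-2, fossil interval for the
#'   African-Eurasian population split, in Mya (default 4.2--9.0).
#' @param generation_years average generation time in years (default 31).
#' @return list of class `calibration_window`.
#' @export
calibration_window <- function(t_lox_eur_mya = c(4.2, 9.0),
                               generation_years = 31) {
  stopifnot(length(t_lox_eur_mya) == 2, all(t_lox_eur_mya > 0),
            t_lox_eur_mya[1] <= t_lox_eur_mya[2], generation_years > 0)
  structure(list(t_lox_eur_mya = t_lox_eur_mya,
                 generation_years = generation_years),
            class = "calibration_window")
}

#' Convert a split-time ratio into absolute time
#'
#' Multiplies a (point or interval) ratio of a split time to the
#' African-Eurasian split time by the fossil calibration window,
#' producing a conservative interval in Mya: `[ratio_low x window_low,
#' ratio_high x window_high]`.
#'
#' @param ratio numeric scalar or length-2 interval, dimensionless,
#'   strictly positive.
#' @param calibration a [calibration_window()].
#' @return numeric length-2 interval in Mya.
#' @export
calibrate_absolute <- function(ratio, calibration = calibration_window()) {
  stopifnot(inherits(calibration, "calibration_window"),
            all(ratio > 0), length(ratio) %in% 1:2)
  r <- range(ratio)
  c(r[1] * calibration$t_lox_eur_mya[1], r[2] * calibration$t_lox_eur_mya[2])
}

#' Convert a scaled population size to a diploid effective size
#'
#' \eqn{N = \theta / (4 \mu g)} with `mu` the per-site per-year mutation
#' rate and `g` the generation time in years.
#'
#' @param theta scaled size (4N mu g), mutation units.
#' @param mu mutation rate per site per year.
#' @param generation_years generation time (default 31).
#' @return diploid effective population size.
#' @export
theta_to_N <- function(theta, mu, generation_years = 31) {
  stopifnot(all(theta > 0), mu > 0, generation_years > 0)
  theta / (4 * mu * generation_years)
}

#' Table-1-shaped divergence and rate-test report
#'
#' Convenience wrapper producing one row per taxon pair: normalized
#' divergence (or heterozygosity), jackknife SE, and the relative-rate
#' test p value for cross-taxon pairs.
#'
#' @param table polarized `div_sites` table.
#' @return data.frame with columns `first`, `second`, `estimate`, `se`, `p_rate`.
#' @export
divergence_report <- function(table) {
  tab <- complete_sites(table)
  dm <- divergence_matrix(tab, taxa = ELEPHANTID_TAXA, jackknife = TRUE)
  pairs <- list(c("S", "F"), c("S", "M"), c("S", "A"),
                c("F", "M"), c("F", "A"), c("M", "A"))
  rows <- lapply(pairs, function(pr) {
    rt <- relative_rate_test(tab, pr[1], pr[2])
    data.frame(first = pr[1], second = pr[2],
               estimate = dm$normalized[pr[1], pr[2]],
               se = dm$se[pr[1], pr[2]],
               p_rate = if (isTRUE(rt$undefined)) NA_real_ else rt$p)
  })
  het <- lapply(ELEPHANTID_TAXA, function(tx)
    data.frame(first = tx, second = tx,
               estimate = dm$normalized[tx, tx],
               se = dm$se[tx, tx], p_rate = NA_real_))
  out <- do.call(rbind, c(rows, het))
  rownames(out) <- NULL
  out
}
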