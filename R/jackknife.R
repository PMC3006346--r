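## Weighted delete-one-block jackknife (Busing, Meijer & van der Leeden,
## Stat. Comput. 1999): the uncertainty engine for every headline number.
## Blocks are loci; the weight of a block is its number of divergent
## sites, so loci contributing more data perturb the statistic more when
## dropped and the variance formula corrects for the unequal block sizes.

#' Combine delete-one-block estimates into a weighted-jackknife SE
#'
#' Low-level kernel of the weighted jackknife. Given the full-sample
#' estimate, the estimates with each block deleted, and the block weights
#' \eqn{m_j}, computes (with \eqn{n = \sum m_j}, \eqn{g} blocks,
#' \eqn{h_j = n / m_j}):
#' \deqn{\hat\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\,\tilde\theta_j,}
#' pseudo-values \eqn{p_j = h_j\hat\theta - (h_j - 1)\tilde\theta_j}, and
#' \deqn{\widehat{var} = \frac{1}{g}\sum_j \frac{(p_j - \hat\theta_J)^2}{h_j - 1}.}
#' With all weights equal this reduces exactly to the classical
#' delete-one jackknife.
#'
#' @param theta_hat full-sample estimate (numeric scalar or vector).
#' @param leave_out numeric matrix (blocks x components) or vector of
#'   delete-one-block estimates.
#' @param weights positive block weights \eqn{m_j}.
#' @return list with `estimate`, `estimate_jack`, `se` (per component).
#' @export
wjack_combine <- function(theta_hat, leave_out, weights) {
  lo <- if (is.matrix(leave_out)) leave_out else matrix(leave_out, ncol = 1)
  g <- nrow(lo)
  stopifnot(length(weights) == g, all(weights > 0), g >= 2)
  n <- sum(weights)
  h <- n / weights
  theta_hat <- as.numeric(theta_hat)
  stopifnot(length(theta_hat) == ncol(lo))
  est_j <- se <- numeric(ncol(lo))
  for (k in seq_len(ncol(lo))) {
    tj <- lo[, k]
    est_j[k] <- g * theta_hat[k] - sum((1 - weights / n) * tj)
    pseudo <- h * theta_hat[k] - (h - 1) * tj
    se[k] <- sqrt(sum((pseudo - est_j[k])^2 / (h - 1)) / g)
  }
  list(estimate = theta_hat, estimate_jack = est_j, se = se)
}

#' Weighted delete-one-locus jackknife of a site-table statistic
#'
#' Recomputes `statistic` with each locus removed in turn and converts the
#' variability into a standard error via [wjack_combine()], weighting each
#' locus by its number of divergent sites. Loci contributing no sites are
#' skipped (their removal cannot change a site-count statistic and their
#' weight would be zero). The z score is `estimate / se` and the p value
#' is two-sided normal unless `one_sided = TRUE`.
#'
#' @param statistic function taking a `div_sites` table and returning a
#'   numeric scalar (or vector; then `se`, `z`, `p` are per component).
#' @param table a `div_sites` table.
#' @param one_sided logical; if `TRUE`, `p = P(Z >= z)`.
#' @return object of class `jackknife_result`: list with `estimate`,
#'   `estimate_jack`, `se`, `z`, `p`, `blocks`, `weights`, and the
#'   per-locus `leave_out` estimates.
#' @export
weighted_jackknife <- function(statistic, table, one_sided = FALSE) {
  loci <- unique(table$locus_id)
  m <- vapply(loci, function(l) sum(table$locus_id == l), numeric(1))
  keep <- m > 0
  loci <- loci[keep]; m <- m[keep]
  if (length(loci) < 2)
    stop("weighted jackknife needs >= 2 loci with divergent sites")
  theta_hat <- statistic(table)
  lo <- matrix(NA_real_, nrow = length(loci), ncol = length(theta_hat))
  for (j in seq_along(loci)) {
    sub <- subset_sites(table, table$locus_id != loci[j])
    val <- tryCatch(statistic(sub), error = function(e)
      stop("statistic undefined when locus '", loci[j], "' is removed: ",
           conditionMessage(e)))
    lo[j, ] <- as.numeric(val)
  }
  cmb <- wjack_combine(theta_hat, lo, m)
  z <- ifelse(cmb$se > 0, cmb$estimate / cmb$se,
              ifelse(cmb$estimate == 0, 0, sign(cmb$estimate) * Inf))
  p <- if (one_sided) pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  structure(list(estimate = cmb$estimate, estimate_jack = cmb$estimate_jack,
                 se = cmb$se, z = z, p = p,
                 blocks = length(loci),
                 weights = setNames(m, loci),
                 leave_out = lo),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat("<jackknife_result> estimate =", signif(x$estimate, 4),
      " se =", signif(x$se, 4),
      " z =", signif(x$z, 3),
      " p =", signif(x$p, 3),
      " (", x$blocks, "loci )\n")
  invisible(x)
}
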