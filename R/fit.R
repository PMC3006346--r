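## Composite-likelihood estimation of the species-tree parameters (tau's
## and theta's in mutation units) from the joint polarized site-pattern
## spectrum. The full Bayesian gene-tree-sampling MCMC is deliberately
## not re-implemented: the estimator maximizes a Poisson composite
## likelihood over the 80 polarized derived-copy patterns
## (nF, nS, nA, nM), whose expected per-bp rates are obtained by
## Monte-Carlo simulation of genealogies (Rcpp kernel) with common
## random numbers across objective evaluations. Interval estimates come
## from a weighted delete-one-block jackknife over loci.

PARAM_NAMES <- c("tau_fs", "tau_am", "tau_le", "tau_root",
                 "theta_f", "theta_s", "theta_a", "theta_m",
                 "theta_fs", "theta_am", "theta_le", "theta_root")

model_params <- function(model) {
  setNames(c(model$tau, model$theta), PARAM_NAMES)
}

params_model <- function(p) {
  species_tree_model(tau_fs = p[["tau_fs"]], tau_am = p[["tau_am"]],
                     tau_le = p[["tau_le"]], tau_root = p[["tau_root"]],
                     theta_f = p[["theta_f"]], theta_s = p[["theta_s"]],
                     theta_a = p[["theta_a"]], theta_m = p[["theta_m"]],
                     theta_fs = p[["theta_fs"]], theta_am = p[["theta_am"]],
                     theta_le = p[["theta_le"]], theta_root = p[["theta_root"]])
}

#' Prior bounds for the model parameters
#'
#' Box constraints mapped from fossil-record priors (in Mya) through a
#' reference mutation rate: African-Eurasian split 4.2--9 Mya,
#' Asian-mammoth 3.0--8.5 Mya, forest-savanna 0.5--9 Mya (deliberately
#' uninformative), elephantid-mastodon 24--30 Mya. Population-size
#' bounds span well beyond the observed savanna-to-forest diversity
#' range. `mu` is per site per year; the default is the rate implied by
#' placing the African-Eurasian split at the centre of its fossil
#' window.
#'
#' @param mu reference mutation rate per site per year.
#' @return object of class `prior_bounds`: matrix (parameters x 2).
#' @export
prior_bounds <- function(mu = 3.3e-10) {
  stopifnot(mu > 0)
  mya <- 1e6 * mu
  b <- rbind(tau_fs = c(0.5, 9) * mya,
             tau_am = c(3.0, 8.5) * mya,
             tau_le = c(4.2, 9) * mya,
             tau_root = c(24, 30) * mya,
             matrix(rep(c(1e-4, 8e-3), 8), ncol = 2, byrow = TRUE,
                    dimnames = list(PARAM_NAMES[5:12], NULL)))
  colnames(b) <- c("lower", "upper")
  structure(b, class = c("prior_bounds", class(b)), mu = mu)
}

#' Monte-Carlo expected site-pattern rates of a model
#'
#' Expected per-bp rates of the 80 polarized derived-copy patterns
#' (`nF`, `nS`, `nA`, `nM` copies of the derived allele, each 0..2, not
#' all zero), estimated by simulating `mc_reps` genealogies and summing
#' branch lengths by the pattern a mutation on each branch would
#' produce.
#'
#' @param model an [species_tree_model()].
#' @param mc_reps number of simulated genealogies.
#' @param seed integer seed (reset before simulation).
#' @return numeric vector of length 81 (index `nF + 3 nS + 9 nA + 27 nM`
#'   plus one; entry 1 is structurally zero).
#' @export
msc_pattern_rates <- function(model, mc_reps = 4000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  msc_pattern_rates_cpp(unname(model$tau), unname(model$theta), mc_reps)
}

#' Expected site-class rates for a taxon triple under a model
#'
#' Monte-Carlo expectation of the seven-class spectrum of
#' [site_class_spectrum()] under the multispecies coalescent: joint
#' pattern rates are estimated by simulation and folded into the triple's
#' classes with the frequency-product weights. The Monte-Carlo standard
#' error of every class rate is estimated from independent chunks.
#'
#' @param model an [species_tree_model()].
#' @param triple three members among `F, S, A, M, E, L` (see
#'   [site_class_spectrum()]).
#' @param mc_reps total genealogies simulated.
#' @param seed integer seed.
#' @param chunks number of independent chunks for the SE estimate.
#' @return list with `rates` (expected per-bp class rates), `se`
#'   (Monte-Carlo SEs), `triple`.
#' @export
pattern_probabilities <- function(model, triple, mc_reps = 20000,
                                  seed = NULL, chunks = 10) {
  if (!is.null(seed)) set.seed(seed)
  per <- max(1L, floor(mc_reps / chunks))
  member_freq <- function(counts_fsam, member) {
    switch(member,
           "F" = counts_fsam[1] / 2, "S" = counts_fsam[2] / 2,
           "A" = counts_fsam[3] / 2, "M" = counts_fsam[4] / 2,
           "E" = (counts_fsam[3] + counts_fsam[4]) / 4,
           "L" = (counts_fsam[1] + counts_fsam[2]) / 4,
           stop("unknown triple member: ", member))
  }
  class_bits <- list("1" = c(1, 0, 0), "2" = c(0, 1, 0), "3" = c(0, 0, 1),
                     "12" = c(1, 1, 0), "13" = c(1, 0, 1), "23" = c(0, 1, 1),
                     "mastodon" = c(1, 1, 1))
  ## per-pattern triple frequencies (pattern index -> f1 f2 f3)
  idx <- 0:80
  cnt <- cbind(idx %% 3, (idx %/% 3) %% 3, (idx %/% 9) %% 3, (idx %/% 27) %% 3)
  fmat <- sapply(triple, function(m) apply(cnt, 1, member_freq, member = m))
  w <- sapply(SITE_CLASSES, function(cl) {
    b <- class_bits[[cl]]
    apply(seq_len(3) |> sapply(function(i)
      if (b[i] == 1) fmat[, i] else 1 - fmat[, i]), 1, prod)
  })
  chunk_rates <- t(sapply(seq_len(chunks), function(ch) {
    r <- msc_pattern_rates_cpp(unname(model$tau), unname(model$theta), per)
    as.numeric(crossprod(r, w))
  }))
  colnames(chunk_rates) <- SITE_CLASSES
  list(rates = colMeans(chunk_rates),
       se = apply(chunk_rates, 2, sd) / sqrt(chunks),
       triple = triple)
}

#' Observed polarized pattern counts of a site table
#'
#' @param table polarized `div_sites` table (complete sites used; the
#'   recurrence filter is *not* expected here — the model accommodates
#'   deep coalescence and, in `jc69` data, recurrent mutation).
#' @return integer vector of length 81 indexed as in
#'   [msc_pattern_rates()].
#' @export
observed_pattern_counts <- function(table) {
  tab <- complete_sites(table)
  stopifnot(is_polarized(tab))
  idx <- tab$F + 3L * tab$S + 9L * tab$A + 27L * tab$M
  tabulate(idx + 1L, nbins = 81)
}

## Poisson composite log-likelihood of counts given per-bp rates
pattern_loglik <- function(counts, rates, bp) {
  lam <- pmax(rates * bp, 1e-12)
  sum(counts[-1] * log(lam[-1])) - sum(lam[-1])
}

moment_init <- function(table, bp, bounds) {
  tab <- complete_sites(table)
  clip <- function(x, nm) min(max(x, bounds[nm, 1] * 1.02), bounds[nm, 2] * 0.98)
  th <- vapply(ELEPHANTID_TAXA, function(tx)
    pairwise_divergence(tab, tx, tx) / bp, numeric(1))
  ## ancestral sizes are started at the deepest current-taxon diversity:
  ## cross-taxon divergence is 2*tau + theta_anc along the ancestral
  ## path, and the highest extant diversity is the least-shrunken proxy
  ## for the ancestral interval sizes
  th_anc <- max(th)
  d <- function(x, y) pairwise_divergence(tab, x, y) / bp
  p <- c(tau_fs = (d("F", "S") - th_anc) / 2,
         tau_am = (d("A", "M") - th_anc) / 2,
         tau_le = (mean(c(d("F", "A"), d("F", "M"), d("S", "A"), d("S", "M"))) -
                     th_anc) / 2,
         tau_root = NA,
         theta_f = th[["F"]], theta_s = th[["S"]],
         theta_a = th[["A"]], theta_m = th[["M"]],
         theta_fs = th_anc, theta_am = th_anc, theta_le = th_anc,
         theta_root = th_anc)
  p[["tau_root"]] <- 4 * p[["tau_le"]]
  for (nm in PARAM_NAMES) p[[nm]] <- clip(p[[nm]], nm)
  ## respect ordering
  p[["tau_fs"]] <- min(p[["tau_fs"]], 0.95 * p[["tau_le"]])
  p[["tau_am"]] <- min(p[["tau_am"]], 0.95 * p[["tau_le"]])
  p[["tau_root"]] <- max(p[["tau_root"]], 1.5 * p[["tau_le"]])
  p
}

fit_objective <- function(counts, bp, bounds, mc_reps, obj_seed) {
  force(counts); force(bp)
  function(logp) {
    p <- setNames(exp(logp), PARAM_NAMES)
    if (any(p < bounds[, 1]) || any(p > bounds[, 2])) return(1e10)
    if (!(p[["tau_fs"]] < p[["tau_le"]] && p[["tau_am"]] < p[["tau_le"]] &&
          p[["tau_le"]] < p[["tau_root"]])) return(1e10)
    set.seed(obj_seed)
    r <- msc_pattern_rates_cpp(p[1:4], p[5:12], mc_reps)
    -pattern_loglik(counts, r, bp)
  }
}

## Weighted delete-one-locus jackknife with one-step (Gauss-Newton)
## refits. Full refits per deleted locus are both expensive and pinned
## by the Monte-Carlo roughness of the objective; the one-step jackknife
## (Shao & Tu style) instead linearizes around the optimum: with
## lambda(t) the expected pattern counts at log-parameters t,
##   score_l(t-hat) = sum_p (n_pl / lambda_p - bp_l / bp) dlambda_p/dt,
##   H = sum_p (1/lambda_p) d_p d_p^T   (Gauss-Newton information),
## the delete-one-locus estimate is t-hat + H^{-1} score_l, and the
## estimates are combined with the Busing weighted-jackknife formula.
fit_jackknife <- function(est, derived, tab, bp, jk_mc_reps, obj_seed) {
  t_hat <- log(est)
  k <- length(t_hat)
  rate_at <- function(t) {
    p <- exp(t)
    set.seed(obj_seed)
    msc_pattern_rates_cpp(p[1:4], p[5:12], jk_mc_reps)
  }
  r0 <- rate_at(t_hat)
  lam <- pmax(r0 * bp, 1e-12)
  ## CRN central differences of the 81 pattern rates wrt log-parameters
  h <- 0.04
  D <- matrix(0, nrow = 81, ncol = k)
  for (j in seq_len(k)) {
    tp <- t_hat; tp[j] <- tp[j] + h
    tm <- t_hat; tm[j] <- tm[j] - h
    D[, j] <- (rate_at(tp) - rate_at(tm)) / (2 * h) * bp
  }
  use <- lam > 1e-9 & seq_len(81) > 1
  H <- crossprod(D[use, , drop = FALSE] / sqrt(lam[use]))
  Hi <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
  loci <- unique(tab$locus_id)
  m_l <- vapply(loci, function(l) sum(tab$locus_id == l), numeric(1))
  keep <- m_l > 0
  loci <- loci[keep]; m_l <- m_l[keep]
  est_named <- setNames(exp(t_hat), PARAM_NAMES)
  stat_full <- c(est_named, derived(est_named))
  lo <- matrix(NA_real_, nrow = length(loci), ncol = length(stat_full))
  idx_of <- function(sub) sub$F + 3L * sub$S + 9L * sub$A + 27L * sub$M + 1L
  for (l in seq_along(loci)) {
    sub <- tab[tab$locus_id == loci[l], , drop = FALSE]
    n_l <- tabulate(idx_of(sub), nbins = 81)
    bp_frac <- m_l[l] / sum(m_l) # exposure share, approximated by site share
    score_l <- as.numeric(crossprod(D[use, , drop = FALSE],
                                    (n_l[use] / lam[use] - bp_frac)))
    t_l <- t_hat + as.numeric(Hi %*% score_l)
    p_l <- setNames(exp(t_l), PARAM_NAMES)
    lo[l, ] <- c(p_l, derived(p_l))
  }
  ## all quantities are positive (sizes, times, their ratios): combine
  ## the delete-one estimates on the log scale, where their sampling
  ## distributions are far closer to normal
  cmb <- wjack_combine(log(stat_full), log(lo), m_l)
  list(se_log = setNames(cmb$se, names(stat_full)),
       se = setNames(stat_full * cmb$se, names(stat_full)),
       leave_out = lo, weights = setNames(m_l, loci))
}

## minimal Moore-Penrose fallback (avoids a MASS dependency)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the species-tree model by composite likelihood
#'
#' Maximizes the Poisson composite likelihood of the joint polarized
#' site-pattern counts over the model's split times and population
#' sizes, with Monte-Carlo pattern rates (common random numbers: the
#' simulation seed is reset at every objective evaluation) and a
#' bounded Nelder-Mead search on log parameters from `restarts` seeded
#' starting points around a method-of-moments initialization.
#'
#' When `jackknife = TRUE`, 90% intervals come from a weighted
#' delete-one-locus jackknife with one-step refits: at the optimum, the
#' Jacobian of the pattern rates is estimated by common-random-number
#' central differences at high Monte-Carlo resolution, each locus's
#' delete-one estimate is obtained by a Gauss-Newton step away from the
#' full-data optimum (the classical one-step jackknife), and the
#' delete-one estimates are combined with locus weights equal to their
#' divergent-site counts, on the log scale (all fitted quantities are
#' positive and ratio-like, so intervals are symmetric in the log).
#' Loci contributing no sites are skipped.
#'
#' @param data a polarized `div_sites` table, an `msc_dataset`, or a
#'   `multilocus_alignment`.
#' @param bp total alignment length in bp backing the site table
#'   (required when `data` is a site table).
#' @param bounds a [prior_bounds()] matrix.
#' @param mc_reps genealogies per objective evaluation.
#' @param restarts number of optimizer starts (>= 1).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed integer seed controlling the common random numbers and
#'   restart jitter.
#' @param jackknife logical; compute delete-one-locus jackknife SEs and
#'   90% intervals (default FALSE).
#' @param jk_mc_reps Monte-Carlo resolution for the rate Jacobian used
#'   by the jackknife.
#' @param max_poly_per_locus QC threshold used when calling sites from
#'   alignments.
#' @return object of class `msc_fit`: list with `estimate` (named
#'   parameter vector), `ratios` (named derived ratios), `se`, `ci90`
#'   (when jackknifed), `objective`, `convergence`, `n_sites`, `bp`,
#'   `warnings`.
#' @export
fit_msc <- function(data, bp = NULL, bounds = prior_bounds(),
                    mc_reps = 6000, restarts = 2, maxit = 1200, seed = 1,
                    jackknife = FALSE, jk_mc_reps = 150000,
                    max_poly_per_locus = Inf) {
  if (inherits(data, "msc_dataset")) data <- data$alignments
  if (inherits(data, "multilocus_alignment")) {
    bp <- total_bp(data)
    data <- polarize(call_divergent_sites(data,
                                          max_poly_per_locus = max_poly_per_locus))
  }
  stopifnot(inherits(data, "div_sites"), is_polarized(data))
  if (is.null(bp)) stop("supply total alignment length `bp` with a site table")
  tab <- complete_sites(data)
  n_loci <- length(unique(tab$locus_id))
  warn <- character()
  if (n_loci < 50)
    warn <- c(warn, sprintf("only %d loci: estimates may be unstable", n_loci))
  counts <- observed_pattern_counts(tab)
  obj_seed <- (seed * 7919L) %% .Machine$integer.max
  obj <- fit_objective(counts, bp, bounds, mc_reps, obj_seed)
  init <- moment_init(tab, bp, bounds)
  set.seed(seed)
  starts <- lapply(seq_len(restarts), function(r) {
    if (r == 1) log(init)
    else log(init) + stats::rnorm(length(init), 0, 0.25)
  })
  best <- NULL
  for (st in starts) {
    fit <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish the winning start at higher Monte-Carlo resolution under
  ## three independent common-random-number streams; the average of the
  ## three log-optima is the estimate (averaging out residual MC noise)
  ## and their dispersion measures the estimator's remaining MC variance
  polish_pars <- matrix(NA_real_, nrow = 3, ncol = length(best$par))
  converged <- TRUE
  polish_value <- Inf
  for (k in 1:3) {
    seed_k <- ((obj_seed + k * 104729L) %% .Machine$integer.max)
    obj_fine <- fit_objective(counts, bp, bounds, 4L * mc_reps, seed_k)
    start_value <- obj_fine(best$par)
    polish <- optim(best$par, obj_fine, method = "Nelder-Mead",
                    control = list(maxit = ceiling(maxit / 2), reltol = 1e-8))
    polish_pars[k, ] <- polish$par
    polish_value <- min(polish_value, polish$value)
    converged <- converged &&
      (polish$convergence == 0 ||
         (start_value - polish$value) < max(1, 1e-4 * abs(polish$value)))
  }
  best <- list(par = colMeans(polish_pars), value = polish_value)
  ## residual MC variance of each log-parameter after averaging
  mc_var_log <- apply(polish_pars, 2, var) / 3
  est <- setNames(exp(best$par), PARAM_NAMES)
  derived <- function(p) c(tau_fs_over_le = p[["tau_fs"]] / p[["tau_le"]],
                           tau_am_over_le = p[["tau_am"]] / p[["tau_le"]],
                           tau_am_over_fs = p[["tau_am"]] / p[["tau_fs"]],
                           nf_over_ns = p[["theta_f"]] / p[["theta_s"]])
  se <- ci90 <- NULL
  if (isTRUE(jackknife)) {
    jk <- fit_jackknife(est, derived, tab, bp, jk_mc_reps, obj_seed)
    stat_full <- c(est, derived(est))
    ## residual MC variance of the derived ratios, from the same three
    ## polish replicates
    der_reps <- t(apply(polish_pars, 1, function(tp)
      log(derived(setNames(exp(tp), PARAM_NAMES)))))
    mc_var_der <- apply(der_reps, 2, var) / 3
    se_log <- sqrt(jk$se_log^2 + c(mc_var_log, mc_var_der))
    se <- stat_full * se_log
    ## 90% intervals are symmetric on the log scale (all quantities are
    ## positive and ratio-like)
    ci90 <- cbind(lower = stat_full * exp(-1.645 * se_log),
                  upper = stat_full * exp(1.645 * se_log))
  }
  structure(list(estimate = est, ratios = derived(est), se = se, ci90 = ci90,
                 objective = -best$value, convergence = converged,
                 n_sites = nrow(tab), n_loci = n_loci, bp = bp,
                 bounds = bounds, warnings = warn,
                 root_note = paste("tau_root and theta_root are weakly",
                                   "identified (outgroup-dominated) and",
                                   "should be treated as low-confidence")),
            class = "msc_fit")
}

#' @export
print.msc_fit <- function(x, ...) {
  cat("<msc_fit> composite-likelihood fit over", x$n_sites, "sites /",
      x$n_loci, "loci (", x$bp, "bp )\n")
  print(signif(x$estimate, 4))
  cat("  tau_FS/tau_LoxEur =", signif(x$ratios[["tau_fs_over_le"]], 3), "\n")
  if (!x$convergence) cat("  WARNING: optimizer did not converge\n")
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Ratio tables of split times and population sizes
#'
#' All pairwise column-to-row ratios of the fitted split times
#' (forest-savanna, Asian-mammoth, African-Eurasian) and of the fitted
#' population sizes, mirroring the shape of the published relative-value
#' tables. The identity diagonal is 1 and `r[i,j] * r[j,i] = 1`.
#'
#' @param fit an `msc_fit`.
#' @return list with matrices `tau_ratios` (3x3) and `n_ratios` (7x7).
#' @export
report_ratios <- function(fit) {
  stopifnot(inherits(fit, "msc_fit"))
  p <- fit$estimate
  tau <- setNames(p[c("tau_fs", "tau_am", "tau_le")],
                  c("T_FS", "T_AM", "T_LoxEur"))
  th <- setNames(p[c("theta_f", "theta_s", "theta_a", "theta_m",
                     "theta_fs", "theta_am", "theta_le")],
                 c("N_F", "N_S", "N_A", "N_M", "N_FS", "N_AM", "N_LoxEur"))
  ratio_mat <- function(v) outer(v, v, function(a, b) b / a)
  list(tau_ratios = ratio_mat(tau), n_ratios = ratio_mat(th))
}
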