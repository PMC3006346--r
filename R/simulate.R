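## Structured-coalescent simulator of multilocus data under the
## five-taxon species tree (((F,S),(A,M)),O) with interval-specific
## population sizes. All simulation is carried out in mutation units:
## times are tau = T * mu (split time times per-year mutation rate) and
## sizes are theta = 4 N mu g, so a branch's length is directly its
## expected number of mutations per base pair. Conversion to years and
## individuals happens only at reporting time via the generation time g
## and a user-supplied mu.

#' Species-tree demographic model
#'
#' Fixed topology (((F,S),(A,M)),O) with split times `tau` and
#' interval-specific scaled population sizes `theta`, all in mutation
#' units. Defaults are the multilocus point estimates for the elephantid
#' system; the root interval (mastodon-elephantid) is poorly constrained
#' by data of this kind and its defaults come from the fossil prior
#' midpoint at the reference mutation rate.
#'
#' @param tau_fs,tau_am,tau_le,tau_root split times (forest-savanna,
#'   Asian-mammoth, African-Eurasian, elephantid-mastodon).
#' @param theta_f,theta_s,theta_a,theta_m current population sizes.
#' @param theta_fs,theta_am,theta_le,theta_root ancestral interval sizes.
#' @param generation_years generation time g (default 31).
#' @param mu optional mutation rate per site per year, for unit
#'   conversions only.
#' @return object of class `msc_model`.
#' @export
species_tree_model <- function(tau_fs = 0.00135, tau_am = 0.00131,
                               tau_le = 0.00220, tau_root = 0.0087,
                               theta_f = 0.00238, theta_s = 0.00068,
                               theta_a = 0.00113, theta_m = 0.00093,
                               theta_fs = 0.00263, theta_am = 0.00181,
                               theta_le = 0.00259, theta_root = 0.0026,
                               generation_years = 31, mu = NULL) {
  tau <- c(FS = tau_fs, AM = tau_am, LE = tau_le, root = tau_root)
  theta <- c(F = theta_f, S = theta_s, A = theta_a, M = theta_m,
             FS = theta_fs, AM = theta_am, LE = theta_le, root = theta_root)
  if (!(tau["FS"] > 0 && tau["AM"] > 0 &&
        tau["FS"] < tau["LE"] && tau["AM"] < tau["LE"] &&
        tau["LE"] < tau["root"]))
    stop("split times must satisfy 0 < tau_FS, tau_AM < tau_LE < tau_root")
  if (any(theta <= 0)) stop("all theta must be positive")
  structure(list(tau = tau, theta = theta,
                 generation_years = generation_years, mu = mu),
            class = "msc_model")
}

#' @export
print.msc_model <- function(x, ...) {
  cat("<msc_model> (((F,S),(A,M)),O), mutation units\n")
  cat("  tau:  ", paste(names(x$tau), signif(x$tau, 4), sep = "=",
                        collapse = "  "), "\n")
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4), sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

## sample labels and tip masks: bits 1..9 for F_1 F_2 S_1 S_2 A_1 A_2 M_1 M_2 O
sim_tip_labels <- function() c(paste(rep(ELEPHANTID_TAXA, each = 2),
                                     1:2, sep = "_"), "O")

#' Simulate a gene tree under the multispecies coalescent
#'
#' Samples one genealogy for two chromosomes per elephantid plus one
#' mastodon chromosome. Within each species-tree interval, each pair of
#' extant lineages coalesces at rate \eqn{2/\theta} of the interval's
#' population on the mutation-unit time axis; lineages merge into the
#' ancestral population at each split. Uses the current R RNG stream.
#'
#' @param model an [species_tree_model()].
#' @return object of class `gene_tree`: list with `tips` (labels),
#'   `merge` (matrix of merged lineage ids), `times` (coalescence times,
#'   mutation units), and `masks` (tip bitmask of every node).
#' @export
simulate_gene_tree <- function(model) {
  stopifnot(inherits(model, "msc_model"))
  tau <- model$tau; theta <- model$theta
  ## lineages: id, mask (bitmask over 9 tips), pop, birth time
  n_tip <- 9L
  pop <- c("F", "F", "S", "S", "A", "A", "M", "M", "O")
  mask <- bitwShiftL(1L, 0:8)
  birth <- numeric(n_tip)
  alive <- seq_len(n_tip)
  next_id <- n_tip + 1L
  merge <- matrix(0L, nrow = n_tip - 1L, ncol = 2L)
  times <- numeric(n_tip - 1L)
  all_masks <- c(mask, integer(n_tip - 1L))
  ev <- 0L
  events <- data.frame(time = c(tau[["FS"]], tau[["AM"]], tau[["LE"]],
                                tau[["root"]], Inf),
                       from1 = c("F", "A", "FS", "LE", NA),
                       from2 = c("S", "M", "AM", "O", NA),
                       to = c("FS", "AM", "LE", "root", NA))
  events <- events[order(events$time), ]
  t <- 0
  for (k in seq_len(nrow(events))) {
    t_end <- events$time[k]
    repeat {
      pops <- unique(pop[alive])
      kp <- vapply(pops, function(p) sum(pop[alive] == p), numeric(1))
      ## a population with a single lineage (e.g. the mastodon before the
      ## root merge) has no coalescent rate and may lack a theta entry
      rate_p <- ifelse(kp > 1, kp * (kp - 1) / theta[pops], 0)
      total <- sum(rate_p)
      if (total <= 0) { t <- t_end; break }
      w <- rexp(1, total)
      if (t + w >= t_end) { t <- t_end; break }
      t <- t + w
      p <- pops[sample.int(length(pops), 1, prob = rate_p)]
      cand <- alive[pop[alive] == p]
      pick <- cand[sample.int(length(cand), 2)]
      ev <- ev + 1L
      merge[ev, ] <- pick
      times[ev] <- t
      new_mask <- bitwOr(all_masks[pick[1]], all_masks[pick[2]])
      all_masks[n_tip + ev] <- new_mask
      pop <- c(pop, p); mask <- c(mask, new_mask); birth <- c(birth, t)
      alive <- c(setdiff(alive, pick), next_id)
      next_id <- next_id + 1L
    }
    if (is.finite(t_end)) {
      relab <- pop %in% c(events$from1[k], events$from2[k])
      pop[relab] <- events$to[k]
    }
    if (length(alive) == 1L) break
  }
  structure(list(tips = sim_tip_labels(), merge = merge, times = times,
                 masks = all_masks),
            class = "gene_tree")
}

#' Branch table of a gene tree
#'
#' @param gt a `gene_tree`.
#' @return data.frame with one row per non-root node: `node`, `length`
#'   (mutation units), `mask` (bitmask of descendant tips).
#' @export
gene_tree_branches <- function(gt) {
  n_tip <- length(gt$tips)
  n_nodes <- n_tip + nrow(gt$merge)
  node_time <- c(numeric(n_tip), gt$times)
  parent_time <- rep(NA_real_, n_nodes)
  for (e in seq_len(nrow(gt$merge)))
    parent_time[gt$merge[e, ]] <- gt$times[e]
  keep <- !is.na(parent_time)
  data.frame(node = which(keep),
             length = parent_time[keep] - node_time[keep],
             mask = gt$masks[keep])
}

mask_tips <- function(mask, tips) tips[bitwAnd(mask, bitwShiftL(1L, seq_along(tips) - 1L)) != 0]

#' Drop mutations onto a gene tree
#'
#' Poisson mutation placement: the expected number of mutations on a
#' branch is its length (mutation units) times the locus length in bp.
#' `"infinite_sites"` assigns each mutation a fresh column;
#' `"jc69"` evolves every column along the tree with equal exchange
#' rates, allowing recurrent substitution.
#'
#' @param gt a `gene_tree`.
#' @param length locus length in bp.
#' @param mode `"infinite_sites"` or `"jc69"`.
#' @param locus_id identifier for the produced alignment.
#' @return list with `alignment` (a [locus_alignment()]) and `ledger`
#'   (data.frame of placed mutations: `column`, `anc`, `der`, `carriers`;
#'   for `jc69` the ledger lists each substitution event).
#' @export
drop_mutations <- function(gt, length, mode = c("infinite_sites", "jc69"),
                           locus_id = "L1") {
  mode <- match.arg(mode)
  bases <- c("A", "C", "G", "T")
  br <- gene_tree_branches(gt)
  tips <- gt$tips
  anc_seq <- sample(bases, length, replace = TRUE)
  seq_mat <- matrix(rep(anc_seq, each = base::length(tips)),
                    nrow = base::length(tips),
                    dimnames = list(tips, NULL))
  ledger <- list()
  if (mode == "infinite_sites") {
    n_mut <- rpois(nrow(br), br$length * length)
    total <- sum(n_mut)
    if (total > length)
      stop("locus of ", length, " bp cannot hold ", total,
           " infinite-sites mutations; increase length or use jc69")
    cols <- if (total > 0) sample.int(length, total) else integer()
    ci <- 0L
    for (b in seq_len(nrow(br))) {
      if (n_mut[b] == 0) next
      carriers <- mask_tips(br$mask[b], tips)
      for (mm in seq_len(n_mut[b])) {
        ci <- ci + 1L
        col <- cols[ci]
        der <- sample(setdiff(bases, anc_seq[col]), 1)
        seq_mat[carriers, col] <- der
        ledger[[ci]] <- data.frame(locus_id = locus_id, column = col,
                                   anc = anc_seq[col], der = der,
                                   carriers = paste(carriers, collapse = ","))
      }
    }
  } else {
    ## evolve columns root-to-tips; process nodes in decreasing age
    n_tip <- base::length(tips)
    node_seq <- matrix(NA_character_, nrow = n_tip + nrow(gt$merge),
                       ncol = length)
    root <- n_tip + nrow(gt$merge)
    node_seq[root, ] <- anc_seq
    parent_of <- rep(NA_integer_, n_tip + nrow(gt$merge))
    for (e in seq_len(nrow(gt$merge)))
      parent_of[gt$merge[e, ]] <- n_tip + e
    ord <- order(c(numeric(n_tip), gt$times)[seq_len(n_tip + nrow(gt$merge))],
                 decreasing = TRUE)
    li <- 0L
    for (nd in ord) {
      if (nd == root) next
      p <- parent_of[nd]
      blen <- br$length[br$node == nd]
      sq <- node_seq[p, ]
      n_ev <- rpois(length, blen)
      for (col in which(n_ev > 0)) {
        for (k in seq_len(n_ev[col])) {
          new <- sample(setdiff(bases, sq[col]), 1)
          li <- li + 1L
          ledger[[li]] <- data.frame(locus_id = locus_id, column = col,
                                     anc = sq[col], der = new,
                                     carriers = paste(mask_tips(gt$masks[nd], tips),
                                                      collapse = ","))
          sq[col] <- new
        }
      }
      node_seq[nd, ] <- sq
    }
    seq_mat <- node_seq[seq_len(n_tip), , drop = FALSE]
    rownames(seq_mat) <- tips
  }
  ledger <- if (base::length(ledger)) do.call(rbind, ledger) else
    data.frame(locus_id = character(), column = integer(), anc = character(),
               der = character(), carriers = character())
  aln <- locus_alignment(locus_id,
                         setNames(apply(seq_mat, 1, paste, collapse = ""),
                                  tips))
  list(alignment = aln, ledger = ledger)
}

#' Apply an ancient-DNA damage channel to the outgroup sequence
#'
#' Each `C` is replaced by `T` and each `G` by `A`, independently with
#' probability `rate` — the deamination-driven misincorporation pattern
#' characteristic of ancient DNA.
#'
#' @param alignment a [locus_alignment()].
#' @param taxon taxon whose sequences are damaged (default the mastodon).
#' @param rate per-base damage probability in \[0, 1\].
#' @return the modified alignment.
#' @export
apply_damage <- function(alignment, taxon = "O", rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(alignment)
  targets <- names(alignment$sequences)[alignment$sample_to_taxon == taxon]
  for (nm in targets) {
    ch <- strsplit(alignment$sequences[[nm]], "")[[1]]
    hit <- ch %in% c("C", "G") & runif(length(ch)) < rate
    ch[hit & ch == "C"] <- "T"
    ch[hit & ch == "G"] <- "A"
    alignment$sequences[[nm]] <- paste(ch, collapse = "")
  }
  alignment
}

#' Simulate a complete multilocus dataset
#'
#' Composes gene-tree simulation, mutation dropping and (optionally) the
#' outgroup damage channel over `n_loci` unlinked loci. Locus lengths are
#' drawn from a shifted geometric distribution with the given mean and
#' minimum unless an explicit `lengths` vector is supplied. A single
#' `seed` drives per-locus substreams, so datasets are reproducible and
#' individual loci are independent of the others' draws.
#'
#' @param model an [species_tree_model()].
#' @param n_loci number of loci (default 375).
#' @param mean_length,min_length locus length distribution in bp
#'   (defaults 106 and 50).
#' @param lengths optional explicit locus lengths (overrides the
#'   distribution).
#' @param seed integer seed.
#' @param mode mutation model, see [drop_mutations()].
#' @param damage_rate outgroup damage probability (default 0).
#' @return object of class `msc_dataset`: list with `alignments`
#'   (`multilocus_alignment`), `gene_trees`, `ledger` (all placed
#'   mutations), `model`, `seed`.
#' @export
simulate_dataset <- function(model, n_loci = 375, mean_length = 106,
                             min_length = 50, lengths = NULL, seed = NULL,
                             mode = "infinite_sites", damage_rate = 0) {
  stopifnot(n_loci >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lengths)) {
    lengths <- if (n_loci > 0)
      min_length + rgeom(n_loci, 1 / (mean_length - min_length + 1))
    else integer()
  }
  stopifnot(length(lengths) == n_loci)
  locus_seeds <- if (n_loci > 0) sample.int(.Machine$integer.max, n_loci) else integer()
  alignments <- vector("list", n_loci)
  gene_trees <- vector("list", n_loci)
  ledgers <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    set.seed(locus_seeds[i])
    gt <- simulate_gene_tree(model)
    dm <- drop_mutations(gt, lengths[i], mode = mode,
                         locus_id = sprintf("L%03d", i))
    aln <- dm$alignment
    if (damage_rate > 0) aln <- apply_damage(aln, rate = damage_rate)
    alignments[[i]] <- aln
    gene_trees[[i]] <- gt
    ledgers[[i]] <- dm$ledger
  }
  structure(list(alignments = structure(alignments,
                                        class = "multilocus_alignment"),
                 gene_trees = gene_trees,
                 ledger = do.call(rbind, c(ledgers,
                                           list(make.row.names = FALSE))),
                 model = model, seed = seed),
            class = "msc_dataset")
}

#' @export
print.msc_dataset <- function(x, ...) {
  cat("<msc_dataset> ", length(x$alignments), " loci, ",
      total_bp(x$alignments), " bp, ",
      nrow(x$ledger), " placed mutations\n", sep = "")
  invisible(x)
}
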