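# Fixtures are built in code: small polarized site tables, toy
# alignments and brute-force oracles used across the test files.

# polarized site table from a compact specification: each row gives
# locus, position and the derived-copy counts for F, S, A, M (O = 0).
make_sites <- function(geno, loci = NULL, pos = NULL) {
  g <- matrix(geno, ncol = 4, byrow = TRUE,
              dimnames = list(NULL, c("F", "S", "A", "M")))
  n <- nrow(g)
  if (is.null(loci)) loci <- if (n) paste0("L", seq_len(n)) else character(0)
  if (is.null(pos)) pos <- rep(1L, n) + sequence(rle(loci)$lengths) - 1L
  div_sites(data.frame(locus_id = as.character(loci), pos = pos,
                       allele_anc = rep("A", n), allele_der = rep("G", n),
                       F = g[, "F"], S = g[, "S"], A = g[, "A"], M = g[, "M"],
                       O = rep(0L, n), check.names = FALSE),
            polarized = TRUE)
}

# a deliberately asymmetric two-locus alignment set with known columns
toy_alignments <- function() {
  #            1234567890
  f1 <- paste0("ACGTACGTAC")
  seqs1 <- c(F_1 = f1, F_2 = f1, S_1 = f1, S_2 = f1,
             A_1 = "ACGTACGTAC", A_2 = "ACGTACGTAC",
             M_1 = "ACGTACGTAC", M_2 = "ACGTACGTAC",
             O   = "ACGTACGTAC")
  # locus 2: column 2 biallelic C/T (derived in F, het), column 5
  # fixed difference vs mastodon, column 8 has an N in all samples
  seqs2 <- c(F_1 = "ATGTGCGNAC", F_2 = "ACGTGCGNAC", S_1 = "ACGTGCGNAC",
             S_2 = "ACGTGCGNAC", A_1 = "ACGTGCGNAC", A_2 = "ACGTGCGNAC",
             M_1 = "ACGTGCGNAC", M_2 = "ACGTGCGNAC",
             O   = "ACGTACGTAC")
  structure(list(locus_alignment("L1", seqs1), locus_alignment("L2", seqs2)),
            class = "multilocus_alignment")
}

# explicit delete-one-locus weighted jackknife, written independently of
# the package implementation (direct transcription of the variance
# formula), used as the oracle for weighted_jackknife()
brute_jackknife <- function(statistic, table) {
  loci <- unique(table$locus_id)
  m <- sapply(loci, function(l) sum(table$locus_id == l))
  theta_hat <- statistic(table)
  theta_j <- sapply(loci, function(l) {
    sub <- table[table$locus_id != l, , drop = FALSE]
    attr(sub, "polarized") <- attr(table, "polarized")
    class(sub) <- class(table)
    statistic(sub)
  })
  n <- sum(m); g <- length(loci); h <- n / m
  est_j <- g * theta_hat - sum((1 - m / n) * theta_j)
  pseudo <- h * theta_hat - (h - 1) * theta_j
  se <- sqrt(sum((pseudo - est_j)^2 / (h - 1)) / g)
  list(estimate = theta_hat, se = se)
}

# small but non-degenerate model for fast simulator tests
fast_model <- function() species_tree_model()
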