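# Oracles: closed-form structured-coalescent probabilities. For two
# lineages in an interval of length L with population size theta, the
# no-coalescence probability is exp(-2 L / theta); the probability that
# a specific non-sister pairing is produced among three lineages that
# reach a common ancestral population is (2/3) of the deep-coalescence
# probability.

coal_time_of <- function(gt, tip_a, tip_b) {
  bits <- bitwOr(bitwShiftL(1L, tip_a - 1L), bitwShiftL(1L, tip_b - 1L))
  times <- c(numeric(9), gt$times)
  min(times[bitwAnd(gt$masks, bits) == bits])
}

test_that("fixed seeds give byte-identical datasets", {
  s1 <- simulate_dataset(fast_model(), n_loci = 8, seed = 5)
  s2 <- simulate_dataset(fast_model(), n_loci = 8, seed = 5)
  expect_identical(lapply(s1$alignments, `[[`, "sequences"),
                   lapply(s2$alignments, `[[`, "sequences"))
  expect_identical(s1$ledger, s2$ledger)
  s3 <- simulate_dataset(fast_model(), n_loci = 8, seed = 6)
  expect_false(identical(s1$ledger, s3$ledger))
  # empty dataset is valid
  s0 <- simulate_dataset(fast_model(), n_loci = 0, seed = 1)
  expect_length(s0$alignments, 0)
  path <- withr::local_tempfile()
  write_phylip_multilocus(s0$alignments, path)
  expect_true(file.exists(path))
})

test_that("sister lineages coalesce instantly as the ancestral size shrinks", {
  m <- species_tree_model(theta_fs = 1e-7)
  set.seed(2)
  times <- replicate(300, coal_time_of(simulate_gene_tree(m), 1, 3))
  # F_1 and S_1 cannot coalesce before tau_FS; with theta_FS -> 0 they
  # coalesce (essentially) at the split itself
  expect_true(all(times >= m$tau[["FS"]]))
  expect_lt(max(times) - m$tau[["FS"]], 1e-5)
})

test_that("no-coalescence fraction matches exp(-2 dtau / theta)", {
  m <- fast_model()
  set.seed(31)
  n <- 4000
  deep <- replicate(n, coal_time_of(simulate_gene_tree(m), 1, 3) >= m$tau[["LE"]])
  # by sampling consistency of the coalescent the marginal genealogy of
  # F_1, S_1 is the two-lineage law even though seven other lineages are
  # simulated alongside them
  p_theory <- exp(-2 * (m$tau[["LE"]] - m$tau[["FS"]]) / m$theta[["FS"]])
  mc_se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(mean(deep) - p_theory), 3 * mc_se)
})

test_that("triplet discordance matches (2/3) exp(-2 dtau / theta)", {
  m <- fast_model()
  set.seed(37)
  n <- 4000
  disc <- replicate(n, {
    gt <- simulate_gene_tree(m)
    # F_1 vs S_1 vs A_1: discordant if F_1 joins A_1 before S_1 or
    # S_1 joins A_1 before F_1
    t_fs <- coal_time_of(gt, 1, 3)
    min(coal_time_of(gt, 1, 5), coal_time_of(gt, 3, 5)) < t_fs
  })
  p_theory <- (2 / 3) * exp(-2 * (m$tau[["LE"]] - m$tau[["FS"]]) / m$theta[["FS"]])
  mc_se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(mean(disc) - p_theory), 3 * mc_se)
})

test_that("within-interval coalescence times are exponential", {
  # two lineages held in a single ancestral population: times beyond the
  # split are Exp(2/theta); Kolmogorov-Smirnov goodness of fit
  m <- fast_model()
  set.seed(41)
  t_am <- replicate(2000, coal_time_of(simulate_gene_tree(m), 5, 7))
  excess <- (t_am - m$tau[["AM"]])[t_am < m$tau[["LE"]]]
  ks <- suppressWarnings(stats::ks.test(
    excess, function(q) {
      # truncated exponential on [0, L]
      L <- m$tau[["LE"]] - m$tau[["AM"]]; r <- 2 / m$theta[["AM"]]
      (1 - exp(-r * pmin(q, L))) / (1 - exp(-r * L))
    }))
  expect_gt(ks$p.value, 0.01)
})

test_that("expected within-taxon diversity per site approaches theta", {
  m <- fast_model()
  sim <- simulate_dataset(m, n_loci = 250, seed = 13)
  bp <- total_bp(sim$alignments)
  for (tx in c("F", "S")) {
    pair <- paste0(tx, c("_1", "_2"))
    diffs <- sum(sapply(sim$alignments, function(a) {
      x <- strsplit(a$sequences[[pair[1]]], "")[[1]]
      y <- strsplit(a$sequences[[pair[2]]], "")[[1]]
      sum(x != y)
    }))
    th <- m$theta[[tx]]
    # Poisson-plus-coalescent variance; allow 4 relative SEs
    se <- sqrt(2 * th * bp)  # conservative overdispersion allowance
    expect_lt(abs(diffs - th * bp), 4 * se)
  }
})

test_that("infinite-sites ledger equals the polymorphic columns", {
  sim <- simulate_dataset(fast_model(), n_loci = 30, seed = 19)
  for (i in seq_along(sim$alignments)) {
    a <- sim$alignments[[i]]
    mat <- do.call(rbind, strsplit(a$sequences, ""))
    n_poly <- sum(apply(mat, 2, function(cl) length(unique(cl)) > 1))
    expect_equal(n_poly, sum(sim$ledger$locus_id == a$locus_id))
  }
})

test_that("damage channel hits only outgroup C/G bases at the given rate", {
  sim <- simulate_dataset(fast_model(), n_loci = 10, seed = 23)
  a <- sim$alignments[[1]]
  expect_identical(apply_damage(a, rate = 0), a)
  set.seed(1)
  full <- apply_damage(a, rate = 1)
  o <- strsplit(full$sequences[["O"]], "")[[1]]
  expect_false(any(o %in% c("C", "G")))
  # non-outgroup sequences untouched
  expect_identical(full$sequences[names(full$sequences) != "O"],
                   a$sequences[names(a$sequences) != "O"])
})

test_that("outgroup damage inflates apparent divergence but not polarized polymorphism calls", {
  m <- fast_model()
  set.seed(3)
  base <- simulate_dataset(m, n_loci = 120, seed = 29, damage_rate = 0)
  set.seed(3)
  dmg <- simulate_dataset(m, n_loci = 120, seed = 29, damage_rate = 0.01)
  poly_of <- function(s) {
    tab <- complete_sites(polarize(call_divergent_sites(s$alignments,
                                                        max_poly_per_locus = Inf)))
    tab[is_elephantid_polymorphic(tab), c("locus_id", "pos", "F", "S", "A", "M")]
  }
  n_div <- function(s) nrow(call_divergent_sites(s$alignments,
                                                 max_poly_per_locus = Inf))
  # damage creates extra apparent mastodon-elephantid divergent sites
  expect_gt(n_div(dmg), n_div(base))
  # but the elephantid-polymorphic calls are (near-)unchanged: the rare
  # exceptions are pre-existing C/T (G/A) sites whose outgroup call was
  # itself hit, flipping the polarization of that site
  pb <- poly_of(base); pd <- poly_of(dmg)
  shared <- merge(pb, pd, by = c("locus_id", "pos"))
  expect_gt(nrow(shared), 0.95 * nrow(pb))
  same <- rowSums(sapply(ELEPHANTID_TAXA, function(tx)
    shared[[paste0(tx, ".x")]] == shared[[paste0(tx, ".y")]])) == 4
  expect_gt(mean(same), 0.98)
})

test_that("pairwise coalescence times match an independent coalescent engine", {
  # msprime, configured with matched demography (time rescaled so one
  # unit equals one mutation unit: haploid population size theta/2 gives
  # pair-coalescence rate 2/theta), is the independent oracle for the
  # F_1-A_1 coalescence-time distribution
  m <- fast_model()
  script <- sprintf('
import msprime, sys
dem = msprime.Demography()
dem.add_population(name="F", initial_size=%g)
dem.add_population(name="A", initial_size=%g)
dem.add_population(name="FS", initial_size=%g)
dem.add_population(name="AM", initial_size=%g)
dem.add_population(name="LE", initial_size=%g)
dem.add_population_split(time=%g, derived=["F"], ancestral="FS")
dem.add_population_split(time=%g, derived=["A"], ancestral="AM")
dem.add_population_split(time=%g, derived=["FS","AM"], ancestral="LE")
dem.sort_events()
ts = [msprime.sim_ancestry(samples={"F":1, "A":1}, demography=dem, ploidy=1,
      random_seed=s).first().tmrca(0, 1) for s in range(1, 2001)]
for t in ts: print("%%.10g" %% t)
',
    m$theta[["F"]] / 2, m$theta[["A"]] / 2, m$theta[["FS"]] / 2,
    m$theta[["AM"]] / 2, m$theta[["LE"]] / 2,
    m$tau[["FS"]], m$tau[["AM"]], m$tau[["LE"]])
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE)
  t_msprime <- as.numeric(out)
  expect_length(t_msprime, 2000)
  set.seed(47)
  t_ours <- replicate(2000, coal_time_of(simulate_gene_tree(m), 1, 5))
  ks <- suppressWarnings(stats::ks.test(t_ours, t_msprime))
  expect_gt(ks$p.value, 0.01)
})
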