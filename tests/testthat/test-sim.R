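oli <- unname(oli_ancestor())
ext <- extend_by_self_priming(oli)

test_that("temperature regimes match the experimental design", {
  expect_equal(make_regime("control")$temps, rep(55, 11))
  expect_equal(make_regime("slow")$temps, 55 + 1.5 * 0:10)
  for (nm in c("sudden", "intermediate", "slow")) {
    r <- make_regime(nm)
    expect_length(r$temps, 11L)
    expect_equal(sum(diff(r$temps)), 15)
    expect_equal(r$temps[11L], 70)
    expect_equal(r$temps[1L], 55)
  }
  expect_error(make_regime("abrupt"))
})

test_that("mutation model honours its rates and spectrum", {
  expect_equal(mutate_seq(oli, mutation_model(0, 0), 5), rep(oli, 5))
  to_a <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  to_a[, "A"] <- 1; to_a["A", "A"] <- 0; to_a["A", "C"] <- 1
  set.seed(2)
  expect_equal(mutate_seq("GGG", mutation_model(1, 0, spectrum = to_a)), "AAA")
  # binomial expectation: 1000-base sequence at 0.008 -> about 8 substitutions
  set.seed(3)
  base <- paste(rep("ACGT", 250), collapse = "")
  m <- mutate_seq(base, mutation_model(0.008, 0), 3000)
  nsub <- as.integer(utils::adist(base, m))
  expect_equal(mean(nsub), 8, tolerance = 0.04)
  expect_error(mutation_model(sub_rate = 2), "rates")
})

test_that("self-priming step extends a temperature-dependent fraction", {
  pop <- oli_population(oli, 5000)
  # deep cold: the ancestral stem folds essentially always
  cold <- self_priming_step(pop, 10)
  expect_equal(sum(cold$count), 5000)
  expect_gt(sum(cold$count[cold$extended]) / 5000, 0.999)
  expect_equal(cold$seq[cold$extended], ext)
  # a stemless population never extends (no C or T, so no base can pair)
  flat <- self_priming_step(oli_population(strrep("AAG", 27), 500), 10)
  expect_false(any(flat$extended))
  set.seed(4)
  frac <- function(tc) {
    p <- self_priming_step(oli_population(oli, 20000), tc)
    sum(p$count[p$extended]) / 20000
  }
  expect_gt(frac(55), frac(70))
})

test_that("PCR growth is exponential, linear or plateaued as designed", {
  p_ext <- oli_population(ext, 1, extended = TRUE)
  r <- pcr_amplify(p_ext, 10, 1e9, mutation_model(0, 0))
  expect_equal(population_size(r$pop), 1024)
  expect_equal(r$curve$total_copies, 2^(0:10))
  r <- pcr_amplify(oli_population(oli, 1), 10, 1e9, mutation_model(0, 0))
  expect_equal(population_size(r$pop), 11)
  r <- pcr_amplify(p_ext, 10, 100, mutation_model(0, 0))
  expect_lte(population_size(r$pop), 101)
  expect_equal(tail(r$curve$total_copies, 1), 101)
  expect_true(all(diff(r$curve$total_copies) >= 0))
})

test_that("copy totals never exceed the primer-limited capacity", {
  set.seed(6)
  for (i in 1:5) {
    n0 <- sample(50:300, 1); pool <- sample(200:2000, 1)
    pop <- self_priming_step(oli_population(oli, n0), sample(c(50, 60, 70), 1))
    r <- pcr_amplify(pop, 15, pool, mutation_model())
    expect_lte(population_size(r$pop), n0 + pool)
    expect_true(all(diff(r$curve$total_copies) >= 0))
  }
})

test_that("digestion trims extended molecules and conserves copies", {
  pop <- oli_population(c(ext, oli), c(40, 10), extended = c(TRUE, FALSE))
  dig <- digest_population(pop)
  expect_equal(population_size(dig), 50)
  expect_equal(dig$seq, digest_trim(oli))
  expect_equal(dig$count, 50)
  expect_false(any(dig$extended))
  # a molecule with no cut site in its 3' half is untouched
  free <- oli_population(strrep("ACGT", 25), 7)
  expect_equal(digest_population(free)$seq, strrep("ACGT", 25))
})

test_that("bottleneck sampling is hypergeometric without replacement", {
  pop <- oli_population(c(oli, ext), c(300, 700), extended = c(FALSE, TRUE))
  expect_equal(bottleneck_sample(pop, 2000), pop)
  one <- bottleneck_sample(oli_population(oli, 500), 50)
  expect_equal(one$count, 50)
  set.seed(8)
  half <- oli_population(c(oli, strrep("ACGT", 26)), c(5000, 5000))
  fr <- replicate(300, {
    b <- bottleneck_sample(half, 1000)
    b$count[b$seq == oli] / 1000
  })
  expect_equal(mean(fr), 0.5, tolerance = 0.01)
  expect_error(bottleneck_sample(oli_population(oli, 0), 10), "empty")
})

test_that("sequencing reads are proportional and carry metadata", {
  set.seed(9)
  pop <- oli_population(oli, 37)
  reads <- sequence_population(pop, 25, treatment = "control", replicate = 3L)
  expect_equal(unname(reads), rep(oli, 25))
  expect_match(names(reads)[1L], "treatment=control")
  expect_match(names(reads)[1L], "replicate=3")
  mix <- oli_population(c(oli, strrep("ACGT", 26)), c(900, 100))
  reads <- sequence_population(mix, 5000)
  expect_equal(mean(unname(reads) == oli), 0.9, tolerance = 0.03)
})

test_that("a mutation-free control experiment preserves the ancestor only", {
  cfg <- sim_config(regime = "control", n_transfers = 3L, n_replicates = 1L,
                    founding_copies = 100, primer_copies = 2000,
                    qpcr_cycles = 8L, bottleneck_size = 200,
                    mutation = mutation_model(0, 0), read_depth = 50L,
                    sampled_transfers = c(1L, 3L), seed = 10L)
  res <- run_experiment(cfg)
  fin <- res$final_populations[[1L]]
  # the single surviving genotype is the founder in its digested form
  expect_equal(fin$seq, digest_trim(oli))
  expect_true(all(unname(res$reads[[1L]][["t3"]]) == digest_trim(oli)))
})

test_that("identical seeds reproduce an experiment exactly", {
  cfg <- sim_config(regime = "sudden", n_transfers = 4L, n_replicates = 2L,
                    founding_copies = 80, primer_copies = 1500,
                    qpcr_cycles = 10L, bottleneck_size = 150,
                    read_depth = 40L, sampled_transfers = c(1L, 3L), seed = 123L)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$growth_curves, b$growth_curves)
  expect_identical(a$final_populations, b$final_populations)
})

test_that("with folding guaranteed, genotype frequencies only drift", {
  # two genotypes that both carry the full amplicon footprints: frequency
  # changes across one transfer average out to zero (neutrality)
  v <- ext
  substr(v, 50, 50) <- ifelse(substr(v, 50, 50) == "A", "G", "A")
  set.seed(14)
  dfr <- replicate(200, {
    pop <- oli_population(c(ext, v), c(500, 500), extended = TRUE)
    amp <- pcr_amplify(pop, 6, 1e5, mutation_model(0, 0))$pop
    bt <- bottleneck_sample(amp, 1000)
    sum(bt$count[bt$seq == v]) / 1000 - 0.5
  })
  expect_lt(abs(mean(dfr)), 0.005)
})

test_that("experiment outputs round-trip to disk", {
  dir <- tempfile("olisim")
  cfg <- sim_config(regime = "slow", n_transfers = 3L, n_replicates = 1L,
                    founding_copies = 50, primer_copies = 800,
                    qpcr_cycles = 6L, bottleneck_size = 100, read_depth = 30L,
                    sampled_transfers = c(1L, 3L), seed = 2L)
  res <- run_experiment(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "growth_curves.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  fa <- list.files(dir, pattern = "\\.fasta$")
  expect_length(fa, 2L)
  back <- read_fasta(file.path(dir, fa[1L]))
  expect_length(back, 30L)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$regime, "slow")
  expect_equal(man$seed, 2L)
})
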