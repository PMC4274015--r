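test_that("reverse complement is correct and an involution", {
  expect_equal(revcomp("AAGCAGTG"), "CACTGCTT")
  expect_equal(revcomp("A"), "T")
  expect_error(revcomp("ACGN"), "non-ACGT")
  set.seed(11)
  s <- random_dna(25, c(1L, 60L))
  expect_equal(revcomp(revcomp(s)), s)
  expect_equal(nchar(revcomp(s)), nchar(s))
})

test_that("stem search finds the ancestral 3'-terminal duplex", {
  oli <- unname(oli_ancestor())
  st <- find_self_priming_stem(oli)
  orc <- stem_oracle(oli)
  expect_equal(st$length, orc$length)
  expect_equal(st$partner_span[1L], orc$partner_start)
  # the stem contains the designed 8-bp duplex (suffix 100-107 paired with
  # the complementary tract at 9-16)
  expect_lte(st$three_prime_span[1L], 100L)
  expect_equal(st$three_prime_span[2L], 107L)
  expect_lte(st$partner_span[1L], 9L)
  expect_gte(st$partner_span[2L], 16L)
  # spans are reverse-complementary base by base and do not overlap
  expect_equal(revcomp(substr(oli, st$three_prime_span[1L], st$three_prime_span[2L])),
               substr(oli, st$partner_span[1L], st$partner_span[2L]))
  expect_lt(st$partner_span[2L], st$three_prime_span[1L])
})

test_that("stem search edge cases and oracle agreement on random sequences", {
  expect_null(find_self_priming_stem("AAAAAAA"))
  st <- find_self_priming_stem("GGGGACGTACCCC", min_stem = 4L)
  expect_equal(st$length, 4L)
  expect_equal(st$partner_span, c(1L, 4L))
  expect_equal(st$three_prime_span, c(10L, 13L))
  set.seed(7)
  for (s in random_dna(60, c(12L, 50L))) {
    got <- find_self_priming_stem(s, min_stem = 3L)
    orc <- stem_oracle(s, min_stem = 3L)
    if (is.null(orc)) {
      expect_null(got)
    } else {
      expect_equal(got$length, orc$length, info = s)
      expect_equal(got$partner_span[1L], orc$partner_start, info = s)
    }
  }
})

test_that("stem free energy is calibrated and monotone in temperature", {
  st <- find_self_priming_stem(unname(oli_ancestor()))
  for (tc in c(45, 50, 55)) {
    expect_lt(stem_free_energy(st, celsius_to_kelvin(tc)), 0)
  }
  for (tc in c(65, 70)) {
    expect_gt(stem_free_energy(st, celsius_to_kelvin(tc)), 0)
  }
  tg <- celsius_to_kelvin(seq(20, 90, by = 5))
  expect_true(all(diff(stem_free_energy(st, tg)) > 0))
  # the zero crossing found by bisection matches the closed form
  tm <- stem_melting_temp(st)
  p <- thermo_params()
  tm_closed <- -((st$length - 1) * p$dH_per_stack + p$loop_penalty_dG) /
    (-(st$length - 1) * p$dS_per_stack)
  expect_equal(tm, tm_closed, tolerance = 1e-6)
  expect_gt(tm, celsius_to_kelvin(55))
  expect_lt(tm, celsius_to_kelvin(65))
  expect_error(stem_free_energy(1L, 300), "undefined")
})

test_that("self-priming probability is a two-state folded fraction", {
  oli <- unname(oli_ancestor())
  expect_equal(p_self_prime("AAAAAAAAAA", celsius_to_kelvin(55)), 0)
  # at the melting temperature the folded fraction is one half
  st <- find_self_priming_stem(oli)
  tm <- stem_melting_temp(st)
  expect_equal(p_self_prime(oli, tm), 0.5, tolerance = 1e-6)
  expect_gt(p_self_prime(oli, celsius_to_kelvin(45)),
            p_self_prime(oli, celsius_to_kelvin(70)))
  # monotone non-increasing in temperature for random sequences
  set.seed(21)
  tg <- celsius_to_kelvin(seq(30, 90, by = 2.5))
  for (s in random_dna(30, c(20L, 80L))) {
    ps <- p_self_prime(s, tg, min_stem = 3L)
    expect_true(all(ps >= 0 & ps <= 1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("self-primed extension creates the designed 3' end", {
  oli <- unname(oli_ancestor())
  ext <- extend_by_self_priming(oli)
  expect_equal(nchar(ext), 115L)
  expect_equal(substr(ext, 1L, 107L), oli)
  expect_equal(substr(ext, 108L, 115L), "CACTGCTT")
  expect_equal(substr(ext, 96L, 115L), "CCTTCGGTCTCCCACTGCTT")
  # the extension's 3' terminus is the reverse complement of the 5' terminus
  expect_equal(revcomp(substr(ext, nchar(ext) - 7L, nchar(ext))),
               substr(oli, 1L, 8L))
  # both qPCR primers find exact footprints on the extended product
  pr <- oli_primers()
  expect_equal(substr(ext, 1L, nchar(pr[["rev"]])), pr[["rev"]])
  expect_equal(revcomp(substr(ext, nchar(ext) - nchar(pr[["fwd"]]) + 1L, nchar(ext))),
               pr[["fwd"]])
  expect_error(extend_by_self_priming("ACGTACGTAA"), "not extendable")
})

test_that("re-extending the extended ancestor adds nothing", {
  ext <- extend_by_self_priming(unname(oli_ancestor()))
  st <- find_self_priming_stem(ext)
  expect_equal(st$partner_span[1L], 1L)
  expect_equal(extend_by_self_priming(ext), ext)
})

test_that("a sequence whose partner span starts at position 1 is unchanged", {
  # suffix CCCC pairs with GGGG at the very 5' terminus: nothing to copy
  s <- "GGGGACGTACCCC"
  expect_equal(extend_by_self_priming(s, min_stem = 4L), s)
})
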