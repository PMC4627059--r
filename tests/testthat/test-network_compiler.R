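test_that("binding decision is a thresholded XOR popcount", {
  a <- bits("1111111111"); z <- bits("0000000000")
  expect_true(binds(a, z, 10))
  expect_false(binds(a, a, 1))
  b8 <- a; b8[9:10] <- 1L - b8[9:10]   # differs from z in 8 positions
  expect_false(binds(b8, z, 9))
  expect_true(binds(b8, z, 8))
  expect_identical(binds(a, z, 10), binds(z, a, 10))
  expect_error(binds(a, bits("111"), 5), "length")
})

test_that("pairwise rate scaling is loglinear in Hamming distance", {
  spec <- scaling_spec("loglinear", 1e-3, 1e3)
  p <- bits(strrep("01", 10))
  expect_identical(rate_from_profiles(p, p, spec), 1e-3)
  expect_identical(rate_from_profiles(p, 1L - p, spec), 1e3)
  q <- p; q[1:10] <- 1L - q[1:10]
  expect_equal(rate_from_profiles(p, q, spec), 1, tolerance = 1e-12)
  expect_identical(rate_from_profiles(p, q, spec), rate_from_profiles(q, p, spec))
})

test_that("masks modulate effective profiles by XOR", {
  p <- bits("1010")
  expect_identical(effective_profile(p, bits("1111"), NULL, "R", 0L), p)
  expect_identical(effective_profile(p, bits("0000"), NULL, "T", 0L), p)
  expect_identical(effective_profile(p, bits("1111"), NULL, "T", 0L), bits("0101"))
  expect_identical(effective_profile(p, bits("0000"), bits("1100"), "R", 1L),
                   bits("0110"))
})

test_that("allosteric rate shifts follow the MWC Gamma/Phi split", {
  expect_equal(allosteric_rates(2, 3, 0.7), c(k_RT = 2, k_TR = 3))
  kk <- allosteric_rates(1, 1, 0.5, 100)
  expect_equal(kk, c(k_RT = 10, k_TR = 0.1))
  expect_equal(kk[["k_RT"]] / (kk[["k_RT"]] + kk[["k_TR"]]), 10 / 10.1)
  expect_equal(allosteric_rates(1, 1, 1, 100), c(k_RT = 100, k_TR = 1))
  expect_equal(allosteric_rates(1, 1, 0, 100), c(k_RT = 1, k_TR = 0.01))
  # equilibrium ratio shifts by exactly G for any phi
  for (phi in c(0, 0.3, 1)) {
    kk <- allosteric_rates(2, 5, phi, c(3, 7))
    expect_equal((kk[["k_RT"]] / kk[["k_TR"]]) / (2 / 5), 21)
  }
  expect_error(allosteric_rates(0, 1, 0.5), "positive")
})

test_that("non-interacting proteins compile to monomers with no reactions", {
  ps <- protein_set(
    make_protein("A", 1, list(make_domain(list(
      make_site("bsite", binding_profile = bits("0000000000")))))),
    make_protein("B", 1, list(make_domain(list(
      make_site("bsite", binding_profile = bits("0000011111"))))))
  )
  net <- compile_network(ps)
  expect_length(net$species, 2)
  expect_identical(nrow(net$reactions), 0L)
  expect_identical(nrow(net$rules), 0L)
})

test_that("a kinase/substrate pair gives the textbook 4-species 3-reaction cycle", {
  net <- compile_network(fixture_kinase_substrate())
  expect_length(net$species, 4)  # E, S, S*, E.S
  expect_identical(nrow(net$reactions), 3L)
  expect_setequal(net$reactions$kind, c("bind", "unbind", "catalysis"))
  # kinase binds only the unmodified substrate: no E.S* complex
  expect_identical(sum(vapply(net$complexes, function(cx)
    length(cx$insts) == 2, TRUE)), 1L)
  kf <- net$reactions$rate[net$reactions$kind == "bind"]
  kb <- net$reactions$rate[net$reactions$kind == "unbind"]
  expect_equal(kf, 1, tolerance = 1e-12)   # Hamming distance 10 of 20
  expect_equal(kb, 1, tolerance = 1e-12)   # Hamming distance 10 of 20
})

test_that("an isolated allosteric domain compiles to a two-state flip pair", {
  net <- compile_network(fixture_allosteric_monomer(rt_rate = 2, phi = 0.3))
  expect_length(net$species, 2)
  expect_identical(nrow(net$reactions), 2L)
  expect_setequal(net$reactions$kind, c("flip_RT", "flip_TR"))
  expect_equal(net$reactions$rate, c(2, 2))  # basal: G = 1
})

test_that("compilation is a pure function: identical outputs across runs", {
  ps <- fixture_gk()
  a <- compile_network(ps)
  b <- compile_network(ps)
  expect_identical(a$species, b$species)
  expect_identical(a$reactions, b$reactions)
  expect_identical(a$x0, b$x0)
})

test_that("every reaction conserves every protein type (stoichiometry check)", {
  for (ps in list(fixture_kinase_substrate(), fixture_gk(),
                  fixture_reversible_dimer())) {
    net <- compile_network(ps)
    odes <- build_odes(net)
    resid <- net$conservation %*% odes$S
    expect_lt(max(abs(as.matrix(resid))), 1e-12)
    expect_true(all(net$reactions$rate > 0))
  }
})

test_that("species and reactions match the brute-force enumerator", {
  cases <- list(
    fixture_kinase_substrate(),
    fixture_reversible_dimer(),
    fixture_gk(),
    # allosteric receptor with a Gamma-shifting bsite + ligand
    protein_set(
      make_protein("L", 1, list(make_domain(list(
        make_site("bsite", binding_profile = bits("1111111111"),
                  kf_profile = dist_profile(rep(0L, 20), 12)))))),
      make_protein("R", 1, list(make_domain(
        list(make_site("bsite", binding_profile = bits("0000000000"),
                       gamma = 25,
                       kb_conf_mask = c(rep(1L, 5), rep(0L, 15)))),
        allosteric = TRUE, rt_rate = 0.5, phi = 0.4))))
  )
  for (ps in cases) {
    net <- compile_network(ps)
    sig <- network_signature(net)
    orc <- oracle_network(ps)
    expect_identical(sig$species, orc$species)
    expect_identical(sig$reactions, orc$reactions)
  }
})

test_that("state-space caps raise an explicit blow-up error", {
  ps <- fixture_kinase_substrate()
  cfg <- default_config(list(compiler = list(max_species = 3L)))
  expect_error(compile_network(ps, cfg), "network blow-up.*max_species = 3",
               class = "evosig_blowup")
})

test_that("modification masks change rates without changing partners", {
  base <- rep(0L, 20)
  ps <- protein_set(
    make_protein("E", 1, list(make_domain(list(
      make_site("csite", "modify", binding_profile = bits("1111111111"),
                kp_profile = encode_scaled(1, 10, scaling_spec("loglinear", 1e-3, 1e3))))))),
    make_protein("Sb", 1, list(make_domain(list(
      make_site("msite", binding_profile = bits("0000000000"),
                kb_profile = base,
                kb_polarity_mask = c(rep(1L, 10), rep(0L, 10))))))),
    make_protein("Ph", 1, list(make_domain(list(
      make_site("csite", "unmodify", binding_profile = bits("1111111111"),
                kp_profile = encode_scaled(1, 10, scaling_spec("loglinear", 1e-3, 1e3))))))
  ))
  net <- compile_network(ps)
  # kinase sees the unmodified msite (kb distance 0 -> 1e-3), the
  # phosphatase sees the modified msite whose kb profile is mask-flipped
  # (distance 10 -> 1)
  kb <- net$reactions[net$reactions$kind == "unbind", ]
  expect_setequal(signif(kb$rate, 6), signif(c(1e-3, 1), 6))
})
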