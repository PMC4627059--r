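# Shared hand-built fixtures (decoded protein sets; exact kinetics).

comp10 <- function(p) 1L - p   # complementary binding profile

# profiles with a chosen Hamming distance d (of L) -> rate lo*(hi/lo)^(d/L)
dist_profile <- function(base, d) {
  out <- base
  if (d > 0) out[seq_len(d)] <- 1L - out[seq_len(d)]
  out
}

# kinase/phosphatase pair acting on one substrate msite; enzyme 1 (kinase)
# modifies, enzyme 2 (phosphatase) unmodifies. d_* set rates on the
# loglinear [1e-3, 1e3] grids: rate = 1e-3 * 10^(6 d / L).
fixture_gk <- function(S_tot = 100, E_tot = 0.01, P_tot = 0.01,
                       d_kf = 16, d_kb = 10, kp = 4) {
  bp <- bits("1111100000")   # shared by both enzymes: one substrate msite
  base <- rep(0L, 20)
  kp_bits <- encode_scaled(kp, 10, scaling_spec("loglinear", 1e-3, 1e3))
  protein_set(
    make_protein("E", E_tot, list(make_domain(list(
      make_site("csite", "modify", binding_profile = bp,
                kf_profile = base, kb_profile = base, kp_profile = kp_bits))))),
    make_protein("S", S_tot, list(make_domain(list(
      make_site("msite", binding_profile = comp10(bp),
                kf_profile = dist_profile(base, d_kf),
                kb_profile = dist_profile(base, d_kb)))))),
    make_protein("P", P_tot, list(make_domain(list(
      make_site("csite", "unmodify", binding_profile = bp,
                kf_profile = base, kb_profile = base, kp_profile = kp_bits)))))
  )
}

# one kinase csite + one substrate msite, fully complementary
fixture_kinase_substrate <- function(kp = 1) {
  bp <- bits("1010101010")
  kp_bits <- encode_scaled(kp, 10, scaling_spec("loglinear", 1e-3, 1e3))
  protein_set(
    make_protein("E", 1, list(make_domain(list(
      make_site("csite", "modify", binding_profile = bp,
                kf_profile = dist_profile(rep(0L, 20), 10),
                kb_profile = dist_profile(rep(0L, 20), 10),
                kp_profile = kp_bits))))),
    make_protein("S", 2, list(make_domain(list(
      make_site("msite", binding_profile = comp10(bp))))))
  )
}

# single allosteric protein, no partners
fixture_allosteric_monomer <- function(rt_rate = 1, phi = 0.5) {
  protein_set(
    make_protein("A", 1, list(make_domain(
      list(make_site("bsite", binding_profile = rep(0L, 10))),
      allosteric = TRUE, rt_rate = rt_rate, phi = phi)))
  )
}

# reversible A + B <-> C (two bsites, kf = kb = 1)
fixture_reversible_dimer <- function(A = 2, B = 2) {
  bp <- bits("1111111111")
  base <- rep(0L, 20)
  protein_set(
    make_protein("A", A, list(make_domain(list(
      make_site("bsite", binding_profile = bp,
                kf_profile = dist_profile(base, 10),
                kb_profile = dist_profile(base, 10)))))),
    make_protein("B", B, list(make_domain(list(
      make_site("bsite", binding_profile = comp10(bp),
                kf_profile = base, kb_profile = base)))))
  )
}

# Goldbeter-Koshland closed form: modified fraction of substrate for a
# covalent modification cycle with maximal rates v1 (modifying) and v2
# (demodifying) and scaled Michaelis constants J1, J2. Standard two-branch
# solution of the quadratic in the modified fraction.
gk_fraction <- function(v1, v2, J1, J2) {
  B <- v2 - v1 + J1 * v2 + J2 * v1
  2 * v1 * J2 / (B + sqrt(B^2 - 4 * (v2 - v1) * v1 * J2))
}

# two-protein genome with junk flanks, built from hand-assembled sections
two_protein_genome <- function(seed = 1) {
  set.seed(seed)
  p1 <- raw_protein(list(raw_domain(list(
    raw_site(type = "11", binding = "1111100000"),
    raw_site(type = "00", binding = "0000011111")))),
    conc = "1010101010")
  p2 <- raw_protein(list(
    raw_domain(list(raw_site(type = "01", binding = "0000011111")),
               allosteric = "1"),
    raw_domain(list(raw_site(type = "00", binding = "1100110011")))),
    conc = "0101010101")
  genome(c(sample(0:1, 23, TRUE), p1, sample(0:1, 17, TRUE), p2,
           sample(0:1, 9, TRUE)))
}
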