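test_that("point mutation flips unprotected bits at the configured rate", {
  g <- random_genome(500, seed = 4)
  set.seed(1)
  expect_identical(point_mutate(g, 0)$genome$bits, g$bits)
  set.seed(1)
  expect_identical(point_mutate(g, 1)$genome$bits, 1L - g$bits)

  g <- random_genome(10000, seed = 5)
  set.seed(2)
  child <- point_mutate(g, 0.01)$genome
  flips <- sum(child$bits != g$bits)
  expect_gte(flips, 60)   # binomial(1e4, 0.01), 99.99% interval
  expect_lte(flips, 140)
})

test_that("point mutation honours protected bit spans", {
  g <- two_protein_genome()
  parsed <- parse_genome(g)
  span1 <- genome_proteins(parsed)[[1]]$span
  mask <- protection_mask(bit_spans = list(
    list(protein = 1L, from = 0L, to = span1[2] - span1[1])))
  set.seed(3)
  child <- point_mutate(g, 1, mask)$genome
  idx <- (span1[1] + 1):span1[2]
  expect_identical(child$bits[idx], g$bits[idx])
  expect_identical(child$bits[-idx], 1L - g$bits[-idx])
})

test_that("protein duplication appends an identical copy at the end", {
  g <- genome(one_site_protein_bits(binding = "1011001010"))
  set.seed(1)
  res <- duplicate_protein(g, rate = 1)
  ps <- genome_proteins(parse_genome(res$genome))
  expect_length(ps, 2)
  dec <- decode_proteins(parse_genome(res$genome))
  expect_equal(dec[[1]]$domains, dec[[2]]$domains)
  expect_equal(dec[[1]]$concentration, dec[[2]]$concentration)
  # copy sits at the end of the string
  expect_identical(res$genome$bits[seq_along(g$bits)], g$bits)

  set.seed(1)
  expect_identical(duplicate_protein(g, 0)$genome$bits, g$bits)
})

test_that("protein deletion removes the section; protected proteins survive", {
  g <- two_protein_genome()
  set.seed(1)
  res <- delete_protein(g, rate = 1, mask = protection_mask(proteins = 2L))
  ps <- genome_proteins(parse_genome(res$genome))
  expect_length(ps, 1)
  expect_length(ps[[1]]$domains, 2)   # the protected two-domain protein
  expect_lt(length(res$genome$bits), length(g$bits))
  set.seed(1)
  expect_identical(delete_protein(g, 0)$genome$bits, g$bits)
})

test_that("domain duplication and deletion restructure whole site blocks", {
  # duplicating a whole-domain fragment gives an extra identical domain
  g <- genome(one_site_protein_bits(binding = "1011001010"))
  res <- evosig:::apply_domain_dup(parse_genome(g), 1, 1, 1)
  dec <- decode_proteins(res)
  expect_length(dec[[1]]$domains, 2)
  expect_equal(dec[[1]]$domains[[1]], dec[[1]]$domains[[2]])

  # deleting all sites of one domain removes that domain
  g2 <- two_protein_genome()
  ps <- decode_proteins(parse_genome(g2))
  expect_length(ps[[2]]$domains, 2)
  res2 <- evosig:::apply_domain_del(parse_genome(g2), 2, 1, 1)
  dec2 <- decode_proteins(res2)
  expect_length(dec2[[2]]$domains, 1)
  expect_equal(dec2[[2]]$domains[[1]], ps[[2]]$domains[[2]])

  # deleting every site deletes the protein
  res3 <- evosig:::apply_domain_del(parse_genome(g2), 2, 1, 2)
  expect_length(decode_proteins(res3), 1)

  set.seed(1)
  expect_identical(domain_dup_del(g2, 0, 0)$genome$bits, g2$bits)
})

test_that("domain shuffling fuses a copied fragment via a hard linker", {
  g <- two_protein_genome()
  before <- decode_proteins(parse_genome(g))
  # fuse a copy of protein 2's msite (flat site 1) after protein 1's site 2
  res <- evosig:::apply_shuffle(parse_genome(g), 1, 2, 2, 1, 1)
  dec <- decode_proteins(res)
  expect_length(dec[[1]]$domains, 1)             # hard link: same domain
  expect_length(dec[[1]]$domains[[1]]$sites, 3)  # 2 own + 1 copied
  expect_equal(dec[[1]]$domains[[1]]$sites[[3]],
               before[[2]]$domains[[1]]$sites[[1]])
  expect_equal(dec[[2]], before[[2]])            # donor untouched
  set.seed(1)
  expect_identical(domain_shuffle(g, 0)$genome$bits, g$bits)
})

test_that("genome rearrangement duplicates or deletes site-aligned segments", {
  g <- two_protein_genome()
  set.seed(1)
  expect_identical(genome_rearrange(g, 0)$genome$bits, g$bits)
  n_dup <- 0; n_del <- 0
  set.seed(7)
  for (i in 1:40) {
    res <- genome_rearrange(g, 1)
    expect_s3_class(parse_genome(res$genome), "parsed_genome")  # total
    if (length(res$events)) {
      ev <- res$events[[1]]
      seg_len <- ev$end0 - ev$start0
      if (ev$op == "rearrange_dup") {
        n_dup <- n_dup + 1
        expect_identical(length(res$genome$bits), length(g$bits) + seg_len)
      } else {
        n_del <- n_del + 1
        expect_identical(length(res$genome$bits), length(g$bits) - seg_len)
      }
    }
  }
  expect_gt(n_dup, 0); expect_gt(n_del, 0)
})

test_that("horizontal transfer copies donor sites without altering the donor", {
  donor <- two_protein_genome(seed = 11)
  recipient <- two_protein_genome(seed = 12)
  donor_before <- donor$bits
  set.seed(5)
  expect_identical(horizontal_transfer(donor, recipient, 0)$genome$bits,
                   recipient$bits)
  set.seed(6)
  res <- horizontal_transfer(donor, recipient, 1)
  expect_identical(donor$bits, donor_before)
  ev <- res$events[[1]]
  expect_identical(length(res$genome$bits),
                   length(recipient$bits) + length(ev$bits))
  expect_s3_class(parse_genome(res$genome), "parsed_genome")
})

test_that("composite mutation is deterministic and replayable", {
  g <- two_protein_genome()
  rates <- mutation_rates(point_rate = 0.01, protein_dup_rate = 0.3,
                          protein_del_rate = 0.2, domain_dup_rate = 0.3,
                          domain_del_rate = 0.2, shuffle_rate = 0.3,
                          rearrange_rate = 0.5)
  zero <- mutation_rates(0, 0, 0, 0, 0, 0, 0, 0)
  expect_identical(mutate_genome(g, zero, seed = 1)$genome$bits, g$bits)

  a <- mutate_genome(g, rates, seed = 42)
  b <- mutate_genome(g, rates, seed = 42)
  expect_identical(a$genome$bits, b$genome$bits)
  expect_identical(a$events, b$events)

  # the event log alone reproduces the child
  expect_identical(replay_mutations(g, a$events)$bits, a$genome$bits)
})

test_that("protected proteins survive any mutation pressure bit-identically", {
  g <- two_protein_genome()
  prot_bits <- function(gn, idx) {
    ps <- genome_proteins(parse_genome(gn))
    gn$bits[(ps[[idx]]$span[1] + 1):ps[[idx]]$span[2]]
  }
  ref <- prot_bits(g, 2)
  span2 <- genome_proteins(parse_genome(g))[[2]]$span
  mask <- protection_mask(
    proteins = 2L,
    bit_spans = list(list(protein = 2L, from = 0L,
                          to = span2[2] - span2[1])))
  rates <- mutation_rates(point_rate = 0.05, protein_dup_rate = 0.5,
                          protein_del_rate = 0.5, domain_dup_rate = 0.5,
                          domain_del_rate = 0.5, shuffle_rate = 0.5,
                          rearrange_rate = 0.8)
  ref_str <- bitstr(ref)
  tracked <- 0
  for (seed in 1:40) {
    res <- mutate_genome(g, rates, mask, seed = seed)
    # the protected coding section survives verbatim somewhere in the child
    expect_true(grepl(ref_str, bitstr(res$genome$bits), fixed = TRUE))
    # and in most children it is still parsed as a protein (an upstream
    # junk-born start code can occasionally capture its frame)
    if (length(res$mask$proteins) == 1) {
      tracked <- tracked + 1
      expect_identical(prot_bits(res$genome, res$mask$proteins), ref)
    }
  }
  expect_gt(tracked, 30)
})

test_that("mutation operators are total: children always parse (fuzz)", {
  rates <- mutation_rates(point_rate = 0.02, protein_dup_rate = 0.2,
                          protein_del_rate = 0.2, domain_dup_rate = 0.2,
                          domain_del_rate = 0.2, shuffle_rate = 0.2,
                          rearrange_rate = 0.3)
  set.seed(99)
  g_struct <- two_protein_genome()
  for (round in 1:1000) {
    g <- if (round %% 2 == 0) {
      genome(sample(0:1, sample(0:400, 1), replace = TRUE))
    } else {
      g_struct
    }
    res <- mutate_genome(g, rates)
    p <- parse_genome(res$genome)                       # never errors
    expect_identical(serialize_genome(p)$bits, res$genome$bits)
    if (round %% 4 == 0) g_struct <- res$genome         # drift the fixture
  }
})
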