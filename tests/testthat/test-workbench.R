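# seed spec for a working covalent-modification cycle plus one idle protein
gk_seed_spec <- function() {
  seed_spec(
    proteins = list(
      list(name = "E", concentration = 0.01, domains = list(
        list(sites = list(list(type = "csite", polarity = "modify"))))),
      list(name = "S", concentration = 100, domains = list(
        list(sites = list(list(type = "msite"))))),
      list(name = "Pp", concentration = 0.01, domains = list(
        list(sites = list(list(type = "csite", polarity = "unmodify"))))),
      list(name = "X", concentration = 1, domains = list(
        list(sites = list(list(type = "bsite")))))
    ),
    pairs = list(
      list(a = c(1, 1, 1), b = c(2, 1, 1), kf = 1, kb = 1, kp = 4),
      list(a = c(3, 1, 1), b = c(2, 1, 1), kf = 1, kb = 1, kp = 4)
    ))
}

test_that("the five-protein seed compiles to exactly the requested rules", {
  g <- build_seed_genome(signaling_seed_spec(), seed = 1)
  parsed <- parse_genome(g)
  expect_length(genome_proteins(parsed), 5)
  proteins <- decode_proteins(parsed)
  expect_equal(vapply(proteins, function(p) p$concentration, 1.0),
               c(1, 1, 1, 10, 10), tolerance = 0.01)

  net <- compile_network(proteins)
  rules <- net$rules
  expect_identical(nrow(rules), 3L)
  key <- function(i) paste(sort(c(rules$p1[i], rules$p2[i])), collapse = "-")
  keys <- vapply(seq_len(3), key, "")
  expect_setequal(keys, c("1-3", "2-4", "2-5"))  # L-A, K-T, P-T
  expect_identical(sort(rules$kind), c("binding", "catalytic", "catalytic"))
  # requested kinetics decode back (exact: distances encode the rates)
  kf <- net$reactions$rate[net$reactions$kind == "bind"]
  expect_true(all(abs(kf - 1) < 1e-9))
  # the adaptor domain is allosteric with the configured Gamma
  expect_true(proteins[[3]]$domains[[1]]$allosteric)
  expect_equal(proteins[[3]]$domains[[1]]$sites[[1]]$gamma, 10,
               tolerance = 0.02)
})

test_that("seed construction is deterministic, and degenerate specs work", {
  a <- build_seed_genome(signaling_seed_spec(), seed = 7)
  b <- build_seed_genome(signaling_seed_spec(), seed = 7)
  expect_identical(a$bits, b$bits)

  expect_length(build_seed_genome(seed_spec(list()), seed = 1)$bits, 0)

  lone <- seed_spec(list(list(name = "A", concentration = 1, domains = list(
    list(sites = list(list(type = "bsite")))))))
  g <- build_seed_genome(lone, seed = 1)
  net <- compile_network(decode_proteins(parse_genome(g)))
  expect_length(net$species, 1)
  expect_identical(nrow(net$reactions), 0L)
})

test_that("an odd complementarity cycle is rejected as unrealizable", {
  three <- seed_spec(
    proteins = lapply(c("A", "B", "C"), function(nm)
      list(name = nm, concentration = 1, domains = list(
        list(sites = list(list(type = "bsite")))))),
    pairs = list(
      list(a = c(1, 1, 1), b = c(2, 1, 1)),
      list(a = c(2, 1, 1), b = c(3, 1, 1)),
      list(a = c(1, 1, 1), b = c(3, 1, 1))))
  expect_error(build_seed_genome(three, seed = 1), "unrealizable")
})

test_that("the seed scores as viable with zero initial responsiveness", {
  g <- build_seed_genome(signaling_seed_spec(), seed = 1)
  rep <- score_genome(g)
  expect_true(rep$viable)
  # input is disconnected from the modification cycle at the start: only
  # solver-level noise shows up in the response
  expect_lt(rep$S_amp, 1e-9)
  expect_lt(rep$fitness, 1e-4)
  expect_gt(rep$S_com, 0)
})

test_that("pruning removes idle proteins and never the protected ones", {
  # pruning judges the functional response, so the complexity weight is 0
  # (otherwise every deletion moves S_com by construction)
  cfg <- default_config(list(
    protocol = list(levels = c(0.005, 0.008, 0.0125, 0.02)),
    scoring = list(w_com = 0)))
  g <- build_seed_genome(gk_seed_spec(), cfg, seed = 3)
  fit <- function(gn) score_genome(gn, cfg)
  f0 <- fit(g)$fitness
  expect_gt(f0, 0)   # the cycle responds to the clamped kinase input

  res <- prune_network(g, fit, cfg, protect = c(1L, 2L))
  expect_identical(res$removed$protein, 4L)         # only the idle protein
  expect_identical(res$removed$reason, "isolated")
  expect_equal(res$fitness_after, f0, tolerance = 1e-9)
  expect_length(genome_proteins(parse_genome(res$genome)), 3)

  # a fully connected, essential network is left unchanged
  res2 <- prune_network(res$genome, fit, cfg, protect = c(1L, 2L))
  expect_identical(nrow(res2$removed), 0L)
})

test_that("saturation parameters recover hand-computed Michaelis constants", {
  bp <- bits("1111100000")
  base <- rep(0L, 20)
  kp1 <- encode_scaled(1, 10, scaling_spec("loglinear", 1e-3, 1e3))
  mk_kinase <- function(nm) make_protein(nm, 1, list(make_domain(list(
    make_site("csite", "modify", binding_profile = bp,
              kf_profile = base, kb_profile = base, kp_profile = kp1)))))
  sub <- function(conc) make_protein("S", conc, list(make_domain(list(
    make_site("msite", binding_profile = comp10(bp),
              kf_profile = dist_profile(base, 10),
              kb_profile = dist_profile(base, 10))))))

  net <- compile_network(protein_set(mk_kinase("E"), sub(2)))
  sp <- saturation_params(net, output_protein = 2)
  expect_equal(sp$K1, 1, tolerance = 0.01)   # ((1 + 1) / 1) / 2
  expect_true(is.na(sp$K2))                  # no phosphatase

  # two identical kinases: geometric mean unchanged
  net2 <- compile_network(protein_set(mk_kinase("E1"), sub(2),
                                      mk_kinase("E2")))
  expect_equal(saturation_params(net2, 2)$K1, sp$K1)

  # doubling the substrate halves K1
  net3 <- compile_network(protein_set(mk_kinase("E"), sub(4)))
  expect_equal(saturation_params(net3, 2)$K1, sp$K1 / 2, tolerance = 0.02)
})

test_that("network exports are deterministic and readable", {
  net <- compile_network(fixture_gk())
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_reaction_list(net, p1)
  write_reaction_list(net, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(any(grepl("-> .* ; k = ", readLines(p1))))
  skip_if_not_installed("igraph")
  p3 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, p3)
  expect_true(any(grepl("graphml", readLines(p3, n = 3))))
})

test_that("the command-line interface round-trips init/translate/score", {
  out <- withr::local_tempdir()
  expect_identical(run_cli(c("init", "--out", out, "--seed", "5")), 0L)
  gfile <- file.path(out, "genome.txt")
  expect_true(file.exists(gfile))
  expect_true(file.exists(file.path(out, "resolved_config.ini")))

  expect_identical(run_cli(c("translate", "--genome", gfile, "--out", out)),
                   0L)
  expect_true(file.exists(file.path(out, "reactions.txt")))

  expect_output(
    expect_identical(run_cli(c("score", "--genome", gfile, "--out", out)), 0L),
    "fitness")
  expect_true(file.exists(file.path(out, "fitness.json")))

  expect_identical(run_cli(c("evolve", "--genome", gfile, "--out", out,
                             "--attempts", "0")), 0L)
  traj <- utils::read.csv(file.path(out, "trajectory.csv"))
  expect_identical(nrow(traj), 0L)   # budget 0: only the seed, no attempts

  suppressMessages({
    expect_identical(run_cli(character(0)), 1L)
    expect_identical(run_cli(c("score", "--nonsense", "x")), 1L)
    expect_identical(run_cli(c("frobnicate")), 1L)
  })
})
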