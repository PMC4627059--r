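#' Declarative seed-network specification
#'
#' Describes a hand-designed starting network: proteins (with domain/site
#' skeletons, concentrations and allosteric parameters), the site pairs that
#' must interact, and the kinetics each interaction should decode to.
#' [build_seed_genome()] realizes the specification as a genome whose
#' compiled network contains exactly the requested interaction rules.
#'
#' @param proteins List of protein descriptions: `list(name, concentration,
#'   domains = list(list(allosteric, rt_rate, phi, sites = list(list(type,
#'   polarity = "modify", gamma = 1)))))`.
#' @param pairs List of requested interactions: `list(a = c(p, d, s),
#'   b = c(p, d, s), kf = 1, kb = 1, kp = NULL)` with `a`/`b` indexing
#'   (protein, domain, site); `kp` only for catalytic pairs (the csite must
#'   be on side `a` or `b`, found automatically).
#' @return A `seed_spec` object.
#' @export
seed_spec <- function(proteins, pairs = list()) {
  structure(list(proteins = proteins, pairs = pairs), class = "seed_spec")
}

#' Minimal five-protein signaling seed
#'
#' The canonical starting point for evolving ultrasensitive (and adaptive)
#' responses: a ligand L that binds an adaptor/receptor A on an allosteric
#' domain, a kinase K whose catalytic site phosphorylates the output protein
#' T, and a phosphatase P that dephosphorylates it. L is the clamped input
#' (protein 1), T the scored output (protein 2). The enzymes start abundant
#' (10 uM) and the target low (1 uM), so the covalent modification cycle
#' starts far from saturation. No other interactions exist at the start:
#' the input is initially disconnected from the output and any
#' responsiveness must evolve.
#'
#' @param conc_L,conc_T,conc_A,conc_K,conc_P Initial concentrations (uM).
#' @return A `seed_spec`.
#' @export
signaling_seed_spec <- function(conc_L = 1, conc_T = 1, conc_A = 1,
                                conc_K = 10, conc_P = 10) {
  proteins <- list(
    list(name = "L", concentration = conc_L, domains = list(
      list(allosteric = FALSE, rt_rate = 1, phi = 0.5, sites = list(
        list(type = "bsite"))))),
    list(name = "T", concentration = conc_T, domains = list(
      list(allosteric = FALSE, rt_rate = 1, phi = 0.5, sites = list(
        list(type = "msite", gamma = 1))))),
    list(name = "A", concentration = conc_A, domains = list(
      list(allosteric = TRUE, rt_rate = 1, phi = 0.5, sites = list(
        list(type = "bsite", gamma = 10))))),
    list(name = "K", concentration = conc_K, domains = list(
      list(allosteric = FALSE, rt_rate = 1, phi = 0.5, sites = list(
        list(type = "csite", polarity = "modify"))))),
    list(name = "P", concentration = conc_P, domains = list(
      list(allosteric = FALSE, rt_rate = 1, phi = 0.5, sites = list(
        list(type = "csite", polarity = "unmodify")))))
  )
  pairs <- list(
    list(a = c(1, 1, 1), b = c(3, 1, 1), kf = 1, kb = 1),           # L - A
    list(a = c(4, 1, 1), b = c(2, 1, 1), kf = 1, kb = 1, kp = 1),   # K -> T
    list(a = c(5, 1, 1), b = c(2, 1, 1), kf = 1, kb = 1, kp = 0.5)  # P -> T
  )
  seed_spec(proteins, pairs)
}

# site key helpers for the seed builder
.sk <- function(idx) paste(idx, collapse = ".")

#' Build a genome realizing a seed specification
#'
#' Chooses binding profiles so that exactly the requested site pairs are
#' complementary above the binding threshold (partners get complementary
#' profiles, everything else stays below threshold), writes kf/kb profiles
#' whose pairwise Hamming distances decode to the requested rates, encodes
#' concentrations, catalytic rates and allosteric parameters onto the bit
#' fields, and serializes the result. Profile assignment is randomized and
#' re-drawn until the no-extra-rules condition holds; an inconsistent
#' specification (e.g. a site required to be complementary to two mutually
#' complementary partners) raises an error.
#'
#' @param spec A [seed_spec()].
#' @param config An `evosig_config` (layout, scaling ranges, threshold).
#' @param seed Optional RNG seed for the profile draw.
#' @param max_tries Redraw budget for the profile assignment.
#' @return A [genome()].
#' @export
build_seed_genome <- function(spec, config = default_config(), seed = NULL,
                              max_tries = 200) {
  stopifnot(inherits(spec, "seed_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (length(spec$proteins) == 0) return(genome(layout = config_layout(config)))
  sc <- config_scalings(config)
  layout <- config_layout(config)
  w <- layout$widths
  threshold <- config$compiler$binding_threshold
  Lb <- w$binding_profile

  # enumerate sites
  sites <- list()
  for (p in seq_along(spec$proteins)) {
    for (d in seq_along(spec$proteins[[p]]$domains)) {
      ss <- spec$proteins[[p]]$domains[[d]]$sites
      for (s in seq_along(ss)) {
        site <- ss[[s]]
        sites[[.sk(c(p, d, s))]] <- list(
          p = p, d = d, s = s, type = site$type,
          polarity = site$polarity %||% "modify",
          gamma = site$gamma %||% 1)
      }
    }
  }
  if (length(spec$pairs)) {
    for (pr in spec$pairs) {
      if (is.null(sites[[.sk(pr$a)]]) || is.null(sites[[.sk(pr$b)]])) {
        stop("pair references a site outside the specification")
      }
    }
  }

  # 2-colour the complementarity constraint graph
  colour <- stats::setNames(rep(NA_integer_, length(sites)), names(sites))
  comp <- stats::setNames(rep(NA_integer_, length(sites)), names(sites))
  ncomp <- 0
  adj <- lapply(stats::setNames(names(sites), names(sites)),
                function(k) character(0))
  for (pr in spec$pairs) {
    a <- .sk(pr$a); b <- .sk(pr$b)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (root in names(sites)) {
    if (!is.na(colour[root])) next
    ncomp <- ncomp + 1
    queue <- root
    colour[root] <- 0L
    comp[root] <- ncomp
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.na(colour[v])) {
          colour[v] <- 1L - colour[u]
          comp[v] <- ncomp
          queue <- c(queue, v)
        } else if (colour[v] == colour[u]) {
          stop("unrealizable specification: a site would need to be ",
               "complementary to two mutually complementary partners")
        }
      }
    }
  }

  requested <- vapply(spec$pairs, function(pr)
    paste(sort(c(.sk(pr$a), .sk(pr$b))), collapse = "~"), "")

  could_bind <- function(ta, tb) {
    (ta == "bsite" && tb == "bsite") ||
      (ta == "csite" && tb == "msite") || (ta == "msite" && tb == "csite")
  }

  # draw component base profiles until no unrequested pair reaches threshold
  profiles <- NULL
  for (try in seq_len(max_tries)) {
    bases <- replicate(ncomp, sample(0:1, Lb, replace = TRUE),
                       simplify = FALSE)
    prof <- lapply(names(sites), function(k) {
      base <- bases[[comp[k]]]
      if (colour[k] == 0L) base else 1L - base
    })
    names(prof) <- names(sites)
    ok <- TRUE
    keys <- names(sites)
    for (i in seq_along(keys)) {
      for (j in i:length(keys)) {
        a <- keys[i]; b <- keys[j]
        if (!could_bind(sites[[a]]$type, sites[[b]]$type)) next
        pairkey <- paste(sort(c(a, b)), collapse = "~")
        d <- popcount(bit_xor(prof[[a]], prof[[b]]))
        if (pairkey %in% requested) {
          if (d < threshold) { ok <- FALSE; break }
        } else if (d >= threshold) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) { profiles <- prof; break }
  }
  if (is.null(profiles)) {
    stop("unrealizable specification: could not find binding profiles with ",
         "exactly the requested rules in ", max_tries, " draws")
  }

  # kf/kb profiles: breadth-first assignment along the pair graph so each
  # pair's Hamming distance encodes its requested rate
  rate_dist <- function(rate, spec_sc, L) {
    d <- round(L * log(rate / spec_sc$lo) / log(spec_sc$hi / spec_sc$lo))
    min(max(d, 0L), L)
  }
  flip_first <- function(base, d) {
    out <- base
    if (d > 0) out[seq_len(d)] <- 1L - out[seq_len(d)]
    out
  }
  assign_rate_profiles <- function(which_rate, spec_field, L) {
    prof <- stats::setNames(vector("list", length(sites)), names(sites))
    for (pr in spec$pairs) {
      a <- .sk(pr$a); b <- .sk(pr$b)
      rate <- pr[[which_rate]] %||% 1
      d <- rate_dist(rate, spec_field, L)
      if (is.null(prof[[a]]) && is.null(prof[[b]])) {
        prof[[a]] <- sample(0:1, L, replace = TRUE)
        prof[[b]] <- flip_first(prof[[a]], d)
      } else if (is.null(prof[[b]])) {
        prof[[b]] <- flip_first(prof[[a]], d)
      } else if (is.null(prof[[a]])) {
        prof[[a]] <- flip_first(prof[[b]], d)
      } else if (popcount(bit_xor(prof[[a]], prof[[b]])) != d) {
        stop("unrealizable kinetics: conflicting ", which_rate,
             " rates for shared sites")
      }
    }
    for (k in names(prof)) {
      if (is.null(prof[[k]])) prof[[k]] <- sample(0:1, L, replace = TRUE)
    }
    prof
  }
  kf_prof <- assign_rate_profiles("kf", sc$kf, w$kf_profile)
  kb_prof <- assign_rate_profiles("kb", sc$kb, w$kb_profile)

  # per-csite catalytic rates from the pair list
  kp_for <- stats::setNames(rep(NA_real_, length(sites)), names(sites))
  for (pr in spec$pairs) {
    if (is.null(pr$kp)) next
    cs <- if (sites[[.sk(pr$a)]]$type == "csite") .sk(pr$a) else .sk(pr$b)
    kp_for[cs] <- pr$kp
  }

  # assemble bit-level protein structures
  zero <- function(n) rep(0L, n)
  prots <- lapply(seq_along(spec$proteins), function(p) {
    sp <- spec$proteins[[p]]
    domains <- lapply(seq_along(sp$domains), function(d) {
      dd <- sp$domains[[d]]
      sl <- lapply(seq_along(dd$sites), function(s) {
        k <- .sk(c(p, d, s))
        info <- sites[[k]]
        type_bits <- switch(info$type, bsite = bits("00"), msite = bits("01"),
                            csite = bits("11"))
        kp <- if (!is.na(kp_for[k])) kp_for[k] else 1
        list(site_type = type_bits,
             polarity = if (identical(info$polarity, "unmodify")) 1L else 0L,
             binding_profile = profiles[[k]],
             kf_profile = kf_prof[[k]], kb_profile = kb_prof[[k]],
             kp_profile = encode_scaled(kp, w$kp_profile, sc$kp),
             keq_ratio = encode_scaled(info$gamma, w$keq_ratio, sc$gamma),
             kf_polarity_mask = zero(w$kf_polarity_mask),
             kb_polarity_mask = zero(w$kb_polarity_mask),
             kf_conf_mask = zero(w$kf_conf_mask),
             kb_conf_mask = zero(w$kb_conf_mask),
             kp_conf_mask = zero(w$kp_conf_mask),
             site_unused = zero(w$site_unused))
      })
      list(allosteric = as.integer(isTRUE(dd$allosteric)),
           rt_rate_bits = encode_scaled(dd$rt_rate %||% 1, w$rt_rate, sc$rt),
           phi_bits = encode_scaled(dd$phi %||% 0.5, w$phi, sc$phi),
           unused = zero(w$domain_unused),
           sites = sl)
    })
    list(concentration_bits = encode_scaled(sp$concentration,
                                            w$concentration,
                                            sc$concentration),
         unused = zero(w$protein_unused),
         domains = domains)
  })
  segments <- lapply(prots, function(pp) list(kind = "protein", protein = pp))
  parsed <- structure(list(segments = segments, layout = layout,
                           n_bits = NA_integer_), class = "parsed_genome")
  serialize_genome(parsed)
}

#' Prune an evolved network genome
#'
#' Removes proteins that do not contribute to the selected function: first
#' every protein that participates in no interaction rule (the isolated
#' nodes of an evolved network), then -- greedily, one protein at a time --
#' any remaining protein whose deletion changes fitness by less than
#' `tol` (absolute). Proteins listed in `protect` (by index in the original
#' parse, e.g. the input and output proteins) are never removed.
#'
#' @param g A [genome()].
#' @param fitness_fn Function `genome -> fitness_report`.
#' @param config An `evosig_config`.
#' @param protect Protein indices never to remove.
#' @param tol Maximum |fitness change| a kept deletion may cause.
#' @return List: pruned `genome`, `removed` (data.frame of protein index,
#'   reason, fitness after removal), `fitness_before`, `fitness_after`.
#' @export
prune_network <- function(g, fitness_fn, config = default_config(),
                          protect = integer(0), tol = 1e-6) {
  f0 <- fitness_fn(g)$fitness
  removed <- list()
  # current protein identity = index in the current parse; keep a map back
  # to original indices so `protect` stays meaningful
  orig_idx <- seq_along(genome_proteins(parse_genome(g)))
  repeat {
    parsed <- parse_genome(g)
    proteins <- decode_proteins(parsed, config)
    if (length(proteins) == 0) break
    net <- try(compile_network(proteins, config), silent = TRUE)
    in_rule <- if (inherits(net, "try-error")) {
      rep(TRUE, length(proteins))      # blow-up: keep everything structural
    } else {
      vapply(seq_along(proteins), function(p)
        any(net$rules$p1 == p | net$rules$p2 == p), TRUE)
    }
    cand <- which(!in_rule & !(orig_idx %in% protect))
    if (length(cand) == 0) break
    p <- cand[1]
    g2 <- serialize_genome(apply_protein_del(parsed, p))
    f2 <- fitness_fn(g2)$fitness
    if (abs(f2 - f0) < tol) {
      removed[[length(removed) + 1L]] <- data.frame(
        protein = orig_idx[p], reason = "isolated", fitness_after = f2)
      g <- g2
      orig_idx <- orig_idx[-p]
    } else break
  }
  # greedy pass over connected proteins
  repeat {
    parsed <- parse_genome(g)
    np <- length(genome_proteins(parsed))
    dropped <- FALSE
    for (p in seq_len(np)) {
      if (orig_idx[p] %in% protect) next
      g2 <- serialize_genome(apply_protein_del(parsed, p))
      f2 <- fitness_fn(g2)$fitness
      if (abs(f2 - f0) < tol) {
        removed[[length(removed) + 1L]] <- data.frame(
          protein = orig_idx[p], reason = "dispensable", fitness_after = f2)
        g <- g2
        orig_idx <- orig_idx[-p]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(genome = g,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(protein = integer(0), reason = character(0),
                    fitness_after = numeric(0)),
       fitness_before = f0, fitness_after = fitness_fn(g)$fitness)
}

#' Composite enzyme-saturation parameters of a modification cycle
#'
#' For every catalytic rule acting on the output protein's first
#' modification site, computes the Michaelis constant of the enzyme in each
#' of its conformational states, scaled by the total substrate
#' concentration: `K = ((kb + kp) / kf) / S_tot`. `K1` is the geometric mean
#' over all kinase-like (modifying) enzyme-state pairs, `K2` over all
#' phosphatase-like (demodifying) ones. Decreasing K1 and K2 mean the
#' enzymes are increasingly saturated -- the regime of zero-order
#' ultrasensitivity.
#'
#' @param net A `reaction_network`.
#' @param output_protein Output protein index.
#' @return List with `K1`, `K2` (NA when no qualifying enzyme exists) and
#'   the per-enzyme-state table.
#' @export
saturation_params <- function(net,
                              output_protein = net$config$protocol$output_protein) {
  sc <- config_scalings(net$config)
  ms <- first_msite(net, output_protein)
  if (is.na(ms)) stop("output protein has no modification site")
  S_tot <- protein_total(net, output_protein)
  rr <- net$rules[net$rules$kind == "catalytic" &
                    net$rules$p2 == output_protein & net$rules$s2 == ms, ,
                  drop = FALSE]
  if (nrow(rr) == 0) {
    return(list(K1 = NA_real_, K2 = NA_real_, table = NULL))
  }
  sub_site <- site_info(net$proteins, output_protein, ms, net$site_map)
  rows <- list()
  for (i in seq_len(nrow(rr))) {
    p <- rr$p1[i]; s <- rr$s1[i]
    enz <- site_info(net$proteins, p, s, net$site_map)
    d <- site_domain(net$site_map, p, s)
    allo <- net$proteins[[p]]$domains[[d]]$allosteric
    sub_mod <- if (enz$polarity == "modify") 0L else 1L
    for (conf in if (allo) c("R", "T") else "R") {
      kf <- rate_from_profiles(
        effective_profile(enz$kf_profile, enz$kf_conf_mask, NULL, conf, 0L),
        effective_profile(sub_site$kf_profile, sub_site$kf_conf_mask,
                          sub_site$kf_polarity_mask, "R", sub_mod),
        sc$kf)
      kb <- rate_from_profiles(
        effective_profile(enz$kb_profile, enz$kb_conf_mask, NULL, conf, 0L),
        effective_profile(sub_site$kb_profile, sub_site$kb_conf_mask,
                          sub_site$kb_polarity_mask, "R", sub_mod),
        sc$kb)
      kp <- decode_scaled(
        effective_profile(enz$kp_profile, enz$kp_conf_mask, NULL, conf, 0L),
        sc$kp)
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = net$proteins[[p]]$name, site = s, conformation = conf,
        polarity = enz$polarity, kf = kf, kb = kb, kp = kp,
        K = ((kb + kp) / kf) / S_tot)
    }
  }
  tab <- do.call(rbind, rows)
  gmean <- function(x) if (length(x)) exp(mean(log(x))) else NA_real_
  list(K1 = gmean(tab$K[tab$polarity == "modify"]),
       K2 = gmean(tab$K[tab$polarity == "unmodify"]),
       table = tab)
}
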