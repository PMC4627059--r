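#' Binding decision between two reactive sites
#'
#' Two sites interact when their binding profiles are sufficiently
#' complementary: the XOR of the two profiles is taken and binding occurs
#' iff the number of 1s (complementary positions) reaches the threshold.
#' The threshold is the user-facing control of protein promiscuity.
#'
#' @param profile_a,profile_b Equal-length bit vectors.
#' @param threshold Minimum number of complementary bits.
#' @return Logical scalar; symmetric in the two profiles.
#' @export
binds <- function(profile_a, profile_b, threshold) {
  popcount(bit_xor(profile_a, profile_b)) >= threshold
}

#' Kinetic rate from a pair of rate profiles
#'
#' Binding kinetics are encoded pairwise: the Hamming distance d between the
#' two partners' rate profiles (length L) is scaled log-linearly onto the
#' configured range, `rate = lo * (hi/lo)^(d/L)`. Identical profiles give
#' `lo`, fully complementary profiles give `hi`.
#'
#' @param pa,pb Equal-length bit vectors (the two sites' kf or kb profiles,
#'   after any conformation/modification masks).
#' @param spec A [scaling_spec()] (must be loglinear-compatible; the linear
#'   branch is also supported for completeness).
#' @return A positive rate.
#' @export
rate_from_profiles <- function(pa, pb, spec) {
  if (length(pa) != length(pb)) stop("rate profiles differ in length")
  d <- popcount(bit_xor(pa, pb))
  L <- length(pa)
  if (spec$mode == "linear") {
    spec$lo + (spec$hi - spec$lo) * d / L
  } else {
    spec$lo * (spec$hi / spec$lo)^(d / L)
  }
}

#' Context-dependent effective rate profile
#'
#' A site's rate profiles are modulated by the conformation of its domain
#' and, for modification sites, by its own modification state. The masks are
#' XOR-applied: in the T conformation the conformational mask flips selected
#' profile bits, and on a modified msite the polarity (modification) mask
#' does the same. An all-zero mask leaves the kinetics untouched, so masks
#' can evolve to have no effect. Masks never touch the 10-bit binding
#' profile: interaction partners are state-independent, kinetics are not.
#'
#' @param profile Rate profile bits.
#' @param conf_mask Conformational mask (same length; extra mask bits beyond
#'   the profile length are ignored).
#' @param mod_mask Modification mask or `NULL`.
#' @param conformation `"R"` or `"T"`.
#' @param modified 0 or 1.
#' @return Bit vector of the profile's length.
#' @export
effective_profile <- function(profile, conf_mask, mod_mask = NULL,
                              conformation = "R", modified = 0L) {
  out <- profile
  L <- length(profile)
  if (conformation == "T") out <- bit_xor(out, conf_mask[seq_len(L)])
  if (modified == 1L && !is.null(mod_mask)) {
    out <- bit_xor(out, mod_mask[seq_len(L)])
  }
  out
}

#' Allosterically shifted R-T transition rates
#'
#' Each bound or covalently modified site on an allosteric domain multiplies
#' the domain's R-T equilibrium constant by its factor Gamma_i. The combined
#' shift `G = prod(Gamma_i)` is split between the forward and backward
#' transition rates by the partition exponent Phi (MWC convention):
#' `k_RT' = k_RT * G^Phi`, `k_TR' = k_TR * G^(Phi - 1)`, so the equilibrium
#' ratio shifts by exactly G.
#'
#' @param k_RT,k_TR Basal transition rates (> 0).
#' @param phi Partition exponent in \[0, 1\].
#' @param gammas Numeric vector of active modifiers' Gamma factors (> 0).
#' @return Named numeric vector `c(k_RT, k_TR)`.
#' @export
allosteric_rates <- function(k_RT, k_TR, phi, gammas = numeric(0)) {
  if (k_RT <= 0 || k_TR <= 0 || any(gammas <= 0)) {
    stop("transition rates and Gamma factors must be positive")
  }
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  G <- prod(gammas)
  c(k_RT = k_RT * G^phi, k_TR = k_TR * G^(phi - 1))
}

# --- internal complex machinery ---------------------------------------------

# Flatten a protein's sites: data.frame(domain, site_in_domain) per site id.
flatten_sites <- function(protein) {
  doms <- protein$domains
  do.call(rbind, lapply(seq_along(doms), function(d) {
    data.frame(domain = d, site_in_domain = seq_along(doms[[d]]$sites))
  }))
}

site_info <- function(proteins, p, s, site_map) {
  m <- site_map[[p]][s, ]
  proteins[[p]]$domains[[m$domain]]$sites[[m$site_in_domain]]
}

site_domain <- function(site_map, p, s) site_map[[p]][s, "domain"]

inst_key <- function(inst) {
  paste0("p", inst$p, "(", paste(c("R", "T")[inst$conf + 1L], collapse = ""),
         "|", paste(inst$mod, collapse = ""), ")")
}

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (q in perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[q])
    }
  }
  out
}

complex_string <- function(cx, ord) {
  ikeys <- vapply(cx$insts[ord], inst_key, "")
  pos <- match(seq_along(ord), ord)   # pos[i] = new index of old instance i
  bstr <- if (length(cx$bonds)) {
    bs <- vapply(cx$bonds, function(b) {
      a <- c(pos[b[1]], b[2]); z <- c(pos[b[3]], b[4])
      if (a[1] > z[1] || (a[1] == z[1] && a[2] > z[2])) { tmp <- a; a <- z; z <- tmp }
      sprintf("%d.%d-%d.%d", a[1], a[2], z[1], z[2])
    }, "")
    paste(sort(bs), collapse = ",")
  } else ""
  paste0(paste(ikeys, collapse = "+"), "@", bstr)
}

# Canonical form: minimal serialization over instance orderings.
canon_complex <- function(cx) {
  n <- length(cx$insts)
  if (n == 1) return(list(key = complex_string(cx, 1L), cx = cx))
  best <- NULL; best_ord <- NULL
  for (ord in perms(n)) {
    s <- complex_string(cx, ord)
    if (is.null(best) || s < best) { best <- s; best_ord <- ord }
  }
  pos <- match(seq_len(n), best_ord)
  bonds <- lapply(cx$bonds, function(b) {
    a <- c(pos[b[1]], b[2]); z <- c(pos[b[3]], b[4])
    if (a[1] > z[1] || (a[1] == z[1] && a[2] > z[2])) { tmp <- a; a <- z; z <- tmp }
    c(a[1], a[2], z[1], z[2])
  })
  list(key = best, cx = list(insts = cx$insts[best_ord], bonds = bonds))
}

# Split a complex into its connected components after removing bond `drop`.
split_complex <- function(cx, drop) {
  keep <- cx$bonds[setdiff(seq_along(cx$bonds), drop)]
  n <- length(cx$insts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in keep) {
      m <- min(comp[b[1]], comp[b[3]])
      if (comp[b[1]] != m || comp[b[3]] != m) {
        comp[comp == comp[b[1]] | comp == comp[b[3]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    remap <- match(seq_len(n), idx)
    list(insts = cx$insts[idx],
         bonds = lapply(Filter(function(b) b[1] %in% idx, keep),
                        function(b) c(remap[b[1]], b[2], remap[b[3]], b[4])))
  })
}

bound_sites <- function(cx, i) {
  out <- integer(0)
  for (b in cx$bonds) {
    if (b[1] == i) out <- c(out, b[2])
    if (b[3] == i) out <- c(out, b[4])
  }
  out
}

#' Compile a protein set into an explicit mass-action reaction network
#'
#' Enumerates the interaction rules implied by the binding profiles, then
#' performs a breadth-first closure over complexes reachable from the
#' initial monomer pool (every protein in its all-R, unmodified state) under
#' three reaction classes:
#'
#' 1. conformational flips of allosteric domains, with rates shifted by the
#'    Gamma factors of the domain's currently bound or modified sites
#'    ([allosteric_rates()]);
#' 2. binding and unbinding between complementary sites, with mass-action
#'    constants derived from the context-dependent effective kf/kb profiles
#'    ([rate_from_profiles()], [effective_profile()]);
#' 3. catalysis through explicit enzyme-substrate complexes: a catalytic
#'    site binds only the substrate state it can act on (a kinase-like
#'    csite of polarity "modify" binds an unmodified msite, a
#'    phosphatase-like one a modified msite) and converts it on release,
#'    `E.S -> E + S*`, at the rate decoded from its (conformation-masked)
#'    kp profile.
#'
#' Interaction rules are formed between bsite pairs (plain binding) and
#' csite-msite pairs (catalytic); other type combinations are inert.
#' Intramolecular bond closure is not modeled. Enumeration is a pure
#' function of the protein set and configuration: species and reactions are
#' returned in canonical lexicographic order.
#'
#' @param proteins A `protein_set` from [decode_proteins()] or
#'   [seed_protein_set()].
#' @param config An `evosig_config`; uses `compiler$binding_threshold`,
#'   `compiler$max_complex_size` and `compiler$max_species`.
#' @return A `reaction_network`: species keys and structures, a reaction
#'   table (reactant/product indices, rate constant, kind), initial
#'   concentrations, per-protein conservation matrix, the rule table and
#'   complexity counts.
#' @export
compile_network <- function(proteins, config = default_config()) {
  sc <- config_scalings(config)
  threshold <- config$compiler$binding_threshold
  max_size <- config$compiler$max_complex_size
  max_species <- config$compiler$max_species
  np <- length(proteins)
  site_map <- lapply(proteins, flatten_sites)
  nsites <- vapply(site_map, nrow, 1L)

  # ---- interaction rules ----
  slots <- do.call(rbind, lapply(seq_len(np), function(p) {
    if (nsites[p] == 0) NULL else data.frame(p = p, s = seq_len(nsites[p]))
  }))
  rules <- list()
  if (!is.null(slots) && nrow(slots) > 0) {
    for (a in seq_len(nrow(slots))) {
      for (z in a:nrow(slots)) {
        sa <- site_info(proteins, slots$p[a], slots$s[a], site_map)
        sz <- site_info(proteins, slots$p[z], slots$s[z], site_map)
        pair_kind <- if (sa$type == "bsite" && sz$type == "bsite") {
          "binding"
        } else if (sa$type == "csite" && sz$type == "msite") {
          "catalytic"
        } else if (sa$type == "msite" && sz$type == "csite") {
          "catalytic_rev"
        } else NA_character_
        if (is.na(pair_kind)) next
        if (!binds(sa$binding_profile, sz$binding_profile, threshold)) next
        if (pair_kind == "catalytic_rev") {
          rules[[length(rules) + 1L]] <- data.frame(
            p1 = slots$p[z], s1 = slots$s[z], p2 = slots$p[a], s2 = slots$s[a],
            kind = "catalytic")
        } else {
          rules[[length(rules) + 1L]] <- data.frame(
            p1 = slots$p[a], s1 = slots$s[a], p2 = slots$p[z], s2 = slots$s[z],
            kind = pair_kind)
        }
      }
    }
  }
  rules <- if (length(rules)) do.call(rbind, rules) else
    data.frame(p1 = integer(0), s1 = integer(0), p2 = integer(0),
               s2 = integer(0), kind = character(0))
  # for catalytic rules, (p1, s1) is the catalytic side

  rules_for <- function(p, s) {
    which((rules$p1 == p & rules$s1 == s) | (rules$p2 == p & rules$s2 == s))
  }

  eff_rate_profile <- function(site, which, conformation, modified) {
    prof <- site[[paste0(which, "_profile")]]
    mod_mask <- if (site$type == "msite") site[[paste0(which, "_polarity_mask")]]
    effective_profile(prof, site[[paste0(which, "_conf_mask")]], mod_mask,
                      conformation, modified)
  }
  site_context <- function(cx, i, s) {
    inst <- cx$insts[[i]]
    d <- site_domain(site_map, inst$p, s)
    list(conformation = c("R", "T")[inst$conf[d] + 1L],
         modified = inst$mod[s],
         site = site_info(proteins, inst$p, s, site_map))
  }
  pair_rate <- function(cxa, ia, sa, cxb, ib, sb, which, spec) {
    ca <- site_context(cxa, ia, sa)
    cb <- site_context(cxb, ib, sb)
    rate_from_profiles(
      eff_rate_profile(ca$site, which, ca$conformation, ca$modified),
      eff_rate_profile(cb$site, which, cb$conformation, cb$modified), spec)
  }

  # ---- breadth-first closure over species ----
  index <- new.env(hash = TRUE, parent = emptyenv())
  species <- list()       # canonical complex objects
  keys <- character(0)
  queue <- integer(0)
  add_species <- function(cx) {
    cc <- canon_complex(cx)
    id <- index[[cc$key]]
    if (!is.null(id)) return(id)
    if (length(keys) + 1L > max_species) {
      stop(errorCondition(sprintf(
        "network blow-up: more than max_species = %d species (complex size cap %d)",
        max_species, max_size), class = "evosig_blowup"))
    }
    keys[[length(keys) + 1L]] <<- cc$key
    species[[length(species) + 1L]] <<- cc$cx
    id <- length(keys)
    index[[cc$key]] <- id
    queue[[length(queue) + 1L]] <<- id
    id
  }

  monomer_ids <- integer(np)
  for (p in seq_len(np)) {
    inst <- list(p = p, conf = integer(length(proteins[[p]]$domains)),
                 mod = integer(nsites[p]))
    monomer_ids[p] <- add_species(list(insts = list(inst), bonds = list()))
  }

  reactions <- list()
  seen_rxn <- new.env(hash = TRUE, parent = emptyenv())
  add_reaction <- function(reactants, products, rate, kind) {
    key <- paste0(paste(sort(reactants), collapse = "+"), ">",
                  paste(sort(products), collapse = "+"), "|", kind)
    if (!is.null(seen_rxn[[key]])) return(invisible(NULL))
    seen_rxn[[key]] <- TRUE
    reactions[[length(reactions) + 1L]] <<- list(
      reactants = reactants, products = products, rate = rate, kind = kind)
  }

  catalytic_ok <- function(rule_row, mod_state) {
    # enzyme polarity "modify" acts on (and binds) unmodified substrate
    enz <- site_info(proteins, rules$p1[rule_row], rules$s1[rule_row], site_map)
    (enz$polarity == "modify" && mod_state == 0L) ||
      (enz$polarity == "unmodify" && mod_state == 1L)
  }

  qpos <- 0L
  while (qpos < length(queue)) {
    qpos <- qpos + 1L
    xid <- queue[qpos]
    X <- species[[xid]]
    nx <- length(X$insts)

    # (1) conformational flips
    for (i in seq_len(nx)) {
      inst <- X$insts[[i]]
      prot <- proteins[[inst$p]]
      bnd <- bound_sites(X, i)
      for (d in seq_along(prot$domains)) {
        dom <- prot$domains[[d]]
        if (!dom$allosteric) next
        dsites <- which(site_map[[inst$p]]$domain == d)
        active <- dsites[dsites %in% bnd | inst$mod[dsites] == 1L]
        gammas <- vapply(active, function(s)
          site_info(proteins, inst$p, s, site_map)$gamma, 1.0)
        kk <- allosteric_rates(dom$rt_rate, dom$rt_rate, dom$phi, gammas)
        Y <- X
        Y$insts[[i]]$conf[d] <- 1L - inst$conf[d]
        yid <- add_species(Y)
        add_reaction(xid, yid,
                     if (inst$conf[d] == 0L) kk[["k_RT"]] else kk[["k_TR"]],
                     if (inst$conf[d] == 0L) "flip_RT" else "flip_TR")
      }
    }

    # (2) unbinding and catalysis on each bond
    for (bi in seq_along(X$bonds)) {
      b <- X$bonds[[bi]]
      kb <- pair_rate(X, b[1], b[2], X, b[3], b[4], "kb", sc$kb)
      parts <- split_complex(X, bi)
      pids <- vapply(parts, add_species, 1L)
      add_reaction(xid, pids, kb, "unbind")

      # catalytic bond? find rule, enzyme side
      i1 <- X$insts[[b[1]]]; i2 <- X$insts[[b[3]]]
      rr <- intersect(rules_for(i1$p, b[2]), rules_for(i2$p, b[4]))
      rr <- rr[rules$kind[rr] == "catalytic"]
      for (r in rr) {
        # orient: enzyme instance / substrate instance within this bond
        if (rules$p1[r] == i1$p && rules$s1[r] == b[2] &&
            rules$p2[r] == i2$p && rules$s2[r] == b[4]) {
          ei <- b[1]; si <- b[3]; ss <- b[4]; es <- b[2]
        } else if (rules$p1[r] == i2$p && rules$s1[r] == b[4] &&
                   rules$p2[r] == i1$p && rules$s2[r] == b[2]) {
          ei <- b[3]; si <- b[1]; ss <- b[2]; es <- b[4]
        } else next
        sub_mod <- X$insts[[si]]$mod[ss]
        if (!catalytic_ok(r, sub_mod)) next
        ectx <- site_context(X, ei, es)
        kp_prof <- effective_profile(
          ectx$site$kp_profile, ectx$site$kp_conf_mask, NULL,
          ectx$conformation, 0L)
        kp <- decode_scaled(kp_prof, sc$kp)
        Y <- X
        Y$insts[[si]]$mod[ss] <- 1L - sub_mod
        parts2 <- split_complex(Y, bi)
        pids2 <- vapply(parts2, add_species, 1L)
        add_reaction(xid, pids2, kp, "catalysis")
      }
    }

    # (3) binding with every currently known species
    n_known <- length(species)
    for (yid in seq_len(n_known)) {
      Y <- species[[yid]]
      if (nx + length(Y$insts) > max_size) next
      for (i in seq_len(nx)) {
        free_x <- setdiff(seq_len(nsites[X$insts[[i]]$p]), bound_sites(X, i))
        for (s in free_x) {
          for (j in seq_along(Y$insts)) {
            free_y <- setdiff(seq_len(nsites[Y$insts[[j]]$p]),
                              bound_sites(Y, j))
            for (t in free_y) {
              rr <- intersect(rules_for(X$insts[[i]]$p, s),
                              rules_for(Y$insts[[j]]$p, t))
              # drop rules not matching this orientation (e.g. same protein
              # type but rule pairs site s with t only one way around)
              rr <- rr[(rules$p1[rr] == X$insts[[i]]$p & rules$s1[rr] == s &
                        rules$p2[rr] == Y$insts[[j]]$p & rules$s2[rr] == t) |
                       (rules$p1[rr] == Y$insts[[j]]$p & rules$s1[rr] == t &
                        rules$p2[rr] == X$insts[[i]]$p & rules$s2[rr] == s)]
              if (!length(rr)) next
              r <- rr[1]
              if (rules$kind[r] == "catalytic") {
                # which side is the substrate msite?
                sub_is_x <- rules$p2[r] == X$insts[[i]]$p && rules$s2[r] == s &&
                  rules$p1[r] == Y$insts[[j]]$p && rules$s1[r] == t
                sub_mod <- if (sub_is_x) X$insts[[i]]$mod[s] else
                  Y$insts[[j]]$mod[t]
                if (!catalytic_ok(r, sub_mod)) next
              }
              kf <- pair_rate(X, i, s, Y, j, t, "kf", sc$kf)
              merged <- list(
                insts = c(X$insts, Y$insts),
                bonds = c(X$bonds,
                          lapply(Y$bonds, function(bb)
                            c(bb[1] + nx, bb[2], bb[3] + nx, bb[4])),
                          list(c(i, s, j + nx, t))))
              zid <- add_species(merged)
              add_reaction(c(xid, yid), zid, kf, "bind")
            }
          }
        }
      }
    }
  }

  # ---- canonical ordering ----
  ord <- order(keys)
  remap <- match(seq_along(keys), ord)
  species <- species[ord]
  keys <- keys[ord]
  rx <- lapply(reactions, function(r) {
    r$reactants <- sort(remap[r$reactants])
    r$products <- sort(remap[r$products])
    r
  })
  rxkey <- vapply(rx, function(r)
    paste0(paste(r$reactants, collapse = "+"), ">",
           paste(r$products, collapse = "+"), "|", r$kind), "")
  rx <- rx[order(rxkey)]

  reactions_df <- data.frame(
    r1 = vapply(rx, function(r) r$reactants[1], 1L),
    r2 = vapply(rx, function(r)
      if (length(r$reactants) > 1) r$reactants[2] else NA_integer_, 1L),
    p1 = vapply(rx, function(r) r$products[1], 1L),
    p2 = vapply(rx, function(r)
      if (length(r$products) > 1) r$products[2] else NA_integer_, 1L),
    rate = vapply(rx, function(r) r$rate, 1.0),
    kind = vapply(rx, function(r) r$kind, "")
  )

  x0 <- numeric(length(keys))
  for (p in seq_len(np)) {
    x0[remap[monomer_ids[p]]] <- proteins[[p]]$concentration
  }
  names(x0) <- keys

  conservation <- matrix(0, nrow = np, ncol = length(keys),
                         dimnames = list(
                           vapply(proteins, function(x) x$name, ""), keys))
  for (k in seq_along(species)) {
    for (inst in species[[k]]$insts) {
      conservation[inst$p, k] <- conservation[inst$p, k] + 1
    }
  }

  structure(list(
    species = keys, complexes = species, reactions = reactions_df,
    x0 = x0, conservation = conservation, rules = rules,
    proteins = proteins, site_map = site_map, config = config,
    counts = list(
      n_proteins = np,
      n_domains = sum(vapply(proteins, function(p) length(p$domains), 1L)),
      n_sites = sum(nsites),
      n_rules = nrow(rules))
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      nrow(x$reactions), " reactions, ", nrow(x$rules), " rule(s)\n", sep = "")
  invisible(x)
}

#' Count instances of a protein in each species
#'
#' @param net A `reaction_network`.
#' @param protein Protein index.
#' @return Integer vector over species.
#' @export
species_protein_count <- function(net, protein) {
  as.integer(net$conservation[protein, ])
}

# Index of the first msite of a protein (site id), or NA if none.
first_msite <- function(net, protein) {
  sm <- net$site_map[[protein]]
  for (s in seq_len(nrow(sm))) {
    if (site_info(net$proteins, protein, s, net$site_map)$type == "msite") {
      return(s)
    }
  }
  NA_integer_
}

#' Output-observable weights: modified copies of a protein per species
#'
#' The output readout of a network is the total concentration of the
#' designated output protein whose first modification site is modified
#' (e.g. total phosphorylated output), counting every instance inside
#' complexes. This returns the per-species weight vector of that sum.
#'
#' @inheritParams species_protein_count
#' @export
output_weights <- function(net, protein) {
  ms <- first_msite(net, protein)
  if (is.na(ms)) return(numeric(length(net$species)))
  vapply(net$complexes, function(cx) {
    sum(vapply(cx$insts, function(inst)
      inst$p == protein && inst$mod[ms] == 1L, TRUE))
  }, 1.0)
}
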