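# Independent brute-force network enumerator for small protein sets
# (<= 3 proteins, pairwise complexes). Instead of the package's incremental
# breadth-first closure, this generates EVERY candidate species up front
# (all conformation/modification state combinations of every monomer, and
# every dimer allowed by an interaction rule), generates every reaction by
# exhaustive application of the rules to those candidates, and then filters
# to the part reachable from the initial monomer pool by fixpoint iteration.
# Rates are recomputed from first principles. Only the canonical species-key
# serializer is shared with the package, so that the two species sets can be
# compared as strings.

oracle_network <- function(proteins, config = evosig::default_config()) {
  th <- config$compiler$binding_threshold
  sc <- evosig::config_scalings(config)
  np <- length(proteins)

  # flat site table
  tab <- list()
  for (p in seq_len(np)) {
    sid <- 0
    for (d in seq_along(proteins[[p]]$domains)) {
      for (s in seq_along(proteins[[p]]$domains[[d]]$sites)) {
        sid <- sid + 1
        tab[[length(tab) + 1]] <- list(
          p = p, s = sid, d = d,
          site = proteins[[p]]$domains[[d]]$sites[[s]])
      }
    }
  }
  nsites <- vapply(seq_len(np), function(p)
    sum(vapply(tab, function(e) e$p == p, TRUE)), 1L)
  get_site <- function(p, s) {
    for (e in tab) if (e$p == p && e$s == s) return(e)
    stop("no such site")
  }

  # interaction rules, from scratch
  rules <- list()
  for (a in seq_along(tab)) {
    for (z in a:length(tab)) {
      ta <- tab[[a]]$site$type; tz <- tab[[z]]$site$type
      match_bits <- sum(tab[[a]]$site$binding_profile !=
                          tab[[z]]$site$binding_profile)
      if (match_bits < th) next
      if (ta == "bsite" && tz == "bsite") {
        rules[[length(rules) + 1]] <- list(kind = "binding",
                                           e = tab[[a]], m = tab[[z]])
      } else if (ta == "csite" && tz == "msite") {
        rules[[length(rules) + 1]] <- list(kind = "catalytic",
                                           e = tab[[a]], m = tab[[z]])
      } else if (ta == "msite" && tz == "csite") {
        rules[[length(rules) + 1]] <- list(kind = "catalytic",
                                           e = tab[[z]], m = tab[[a]])
      }
    }
  }

  # all instance states of protein p
  inst_states <- function(p) {
    doms <- proteins[[p]]$domains
    conf_opts <- lapply(doms, function(d) if (d$allosteric) 0:1 else 0L)
    confs <- expand.grid(conf_opts)
    msites <- vapply(seq_len(nsites[p]), function(s)
      get_site(p, s)$site$type == "msite", TRUE)
    mod_opts <- lapply(seq_len(nsites[p]), function(s) if (msites[s]) 0:1 else 0L)
    mods <- if (nsites[p]) expand.grid(mod_opts) else data.frame(x = 0)[, 0]
    out <- list()
    for (i in seq_len(nrow(confs))) {
      for (j in seq_len(max(nrow(mods), 1))) {
        out[[length(out) + 1]] <- list(
          p = p, conf = as.integer(confs[i, ]),
          mod = if (nsites[p]) as.integer(mods[j, ]) else integer(0))
      }
    }
    out
  }

  key_of <- function(cx) evosig:::canon_complex(cx)$key

  eff <- function(site, which, conformation, modified) {
    prof <- site[[paste0(which, "_profile")]]
    if (conformation == 1L) {
      prof <- as.integer(xor(prof == 1, site[[paste0(which, "_conf_mask")]][
        seq_along(prof)] == 1))
    }
    if (modified == 1L && site$type == "msite") {
      prof <- as.integer(xor(prof == 1, site[[paste0(which, "_polarity_mask")]][
        seq_along(prof)] == 1))
    }
    prof
  }
  pair_rate <- function(ea, ia, eb, ib, which, spec) {
    pa <- eff(ea$site, which, ia$conf[ea$d], ia$mod[ea$s])
    pb <- eff(eb$site, which, ib$conf[eb$d], ib$mod[eb$s])
    d <- sum(pa != pb)
    spec$lo * (spec$hi / spec$lo)^(d / length(pa))
  }
  kp_rate <- function(e, inst) {
    prof <- eff(e$site, "kp", inst$conf[e$d], 0L)
    v <- sum(prof * 2^((length(prof) - 1):0))
    sc$kp$lo * (sc$kp$hi / sc$kp$lo)^(v / (2^length(prof) - 1))
  }
  cat_ok <- function(rule, sub_mod) {
    (rule$e$site$polarity == "modify" && sub_mod == 0L) ||
      (rule$e$site$polarity == "unmodify" && sub_mod == 1L)
  }

  # candidate species
  monomers <- list()
  for (p in seq_len(np)) monomers <- c(monomers, inst_states(p))
  mono_cx <- lapply(monomers, function(i) list(insts = list(i), bonds = list()))
  dimers <- list()
  for (r in rules) {
    a <- if (r$kind == "binding") r$e else r$e
    for (ia in inst_states(r$e$p)) {
      for (ib in inst_states(r$m$p)) {
        if (r$kind == "catalytic" && !cat_ok(r, ib$mod[r$m$s])) next
        dimers[[length(dimers) + 1]] <- list(
          insts = list(ia, ib),
          bonds = list(c(1L, r$e$s, 2L, r$m$s)), rule = r)
      }
    }
  }
  cands <- c(mono_cx, dimers)
  ckeys <- vapply(cands, key_of, "")
  keep <- !duplicated(ckeys)
  cands <- cands[keep]; ckeys <- ckeys[keep]

  # all reactions over the candidates
  rxs <- list()
  add <- function(reactants, products, rate, kind) {
    rxs[[length(rxs) + 1]] <<- list(
      reactants = sort(reactants), products = sort(products),
      rate = rate, kind = kind)
  }
  for (ci in seq_along(cands)) {
    cx <- cands[[ci]]
    # flips
    for (ii in seq_along(cx$insts)) {
      inst <- cx$insts[[ii]]
      for (d in seq_along(proteins[[inst$p]]$domains)) {
        dom <- proteins[[inst$p]]$domains[[d]]
        if (!dom$allosteric) next
        bound <- unlist(lapply(cx$bonds, function(b) {
          out <- c(); if (b[1] == ii) out <- c(out, b[2])
          if (b[3] == ii) out <- c(out, b[4]); out
        }))
        act <- c()
        for (s in seq_len(nsites[inst$p])) {
          e <- get_site(inst$p, s)
          if (e$d == d && (s %in% bound || inst$mod[s] == 1L)) {
            act <- c(act, e$site$gamma)
          }
        }
        G <- prod(c(1, act))
        k <- if (inst$conf[d] == 0L) dom$rt_rate * G^dom$phi else
          dom$rt_rate * G^(dom$phi - 1)
        y <- cx; y$insts[[ii]]$conf[d] <- 1L - inst$conf[d]
        add(ckeys[ci], key_of(y), k, if (inst$conf[d] == 0L) "flip_RT" else "flip_TR")
      }
    }
    if (length(cx$insts) == 2) {
      b <- cx$bonds[[1]]
      ea <- get_site(cx$insts[[1]]$p, b[2])
      eb <- get_site(cx$insts[[2]]$p, b[4])
      m1 <- list(insts = cx$insts[1], bonds = list())
      m2 <- list(insts = cx$insts[2], bonds = list())
      kb <- pair_rate(ea, cx$insts[[1]], eb, cx$insts[[2]], "kb", sc$kb)
      add(ckeys[ci], c(key_of(m1), key_of(m2)), kb, "unbind")
      r <- cx$rule
      if (!is.null(r) && r$kind == "catalytic" &&
          cat_ok(r, cx$insts[[2]]$mod[r$m$s])) {
        y2 <- m2; y2$insts[[1]]$mod[r$m$s] <- 1L - y2$insts[[1]]$mod[r$m$s]
        add(ckeys[ci], c(key_of(m1), key_of(y2)),
            kp_rate(r$e, cx$insts[[1]]), "catalysis")
      }
      # formation of this dimer from its two monomer states
      kf <- pair_rate(ea, cx$insts[[1]], eb, cx$insts[[2]], "kf", sc$kf)
      add(c(key_of(m1), key_of(m2)), ckeys[ci], kf, "bind")
    }
  }
  # dedupe
  rkeys <- vapply(rxs, function(r) paste(
    paste(r$reactants, collapse = "+"), paste(r$products, collapse = "+"),
    r$kind, sep = ">"), "")
  rxs <- rxs[!duplicated(rkeys)]

  # reachability fixpoint from the initial all-R unmodified monomers
  reach <- vapply(seq_len(np), function(p) key_of(list(
    insts = list(list(p = p, conf = integer(length(proteins[[p]]$domains)),
                      mod = integer(nsites[p]))), bonds = list())), "")
  repeat {
    new_rx <- Filter(function(r) all(r$reactants %in% reach), rxs)
    prods <- unique(unlist(lapply(new_rx, function(r) r$products)))
    add_keys <- setdiff(prods, reach)
    if (!length(add_keys)) break
    reach <- c(reach, add_keys)
  }
  live <- Filter(function(r) all(r$reactants %in% reach), rxs)
  list(
    species = sort(reach),
    reactions = sort(vapply(live, function(r) paste(
      paste(r$reactants, collapse = "+"), ">",
      paste(r$products, collapse = "+"), "|", r$kind, "|",
      signif(r$rate, 10)), ""))
  )
}

# package network rendered in the oracle's comparison format
network_signature <- function(net) {
  rx <- net$reactions
  strs <- vapply(seq_len(nrow(rx)), function(i) {
    re <- sort(net$species[stats::na.omit(c(rx$r1[i], rx$r2[i]))])
    pr <- sort(net$species[stats::na.omit(c(rx$p1[i], rx$p2[i]))])
    paste(paste(re, collapse = "+"), ">", paste(pr, collapse = "+"),
          "|", rx$kind[i], "|", signif(rx$rate[i], 10))
  }, "")
  list(species = sort(net$species), reactions = sort(strs))
}
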