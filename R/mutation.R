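#' Mutation rates
#'
#' Per-operator probabilities. `point_rate` is per bit; duplication,
#' deletion, domain duplication/deletion and shuffling are per protein;
#' rearrangement is per genome; horizontal gene transfer is per individual
#' (population mode only).
#'
#' @param point_rate,protein_dup_rate,protein_del_rate,domain_dup_rate,domain_del_rate,shuffle_rate,rearrange_rate,hgt_rate
#'   Probabilities in \[0, 1\].
#' @export
mutation_rates <- function(point_rate = 0.002, protein_dup_rate = 0.005,
                           protein_del_rate = 0.005, domain_dup_rate = 0.01,
                           domain_del_rate = 0.01, shuffle_rate = 0.01,
                           rearrange_rate = 0.01, hgt_rate = 0) {
  r <- list(point_rate = point_rate, protein_dup_rate = protein_dup_rate,
            protein_del_rate = protein_del_rate,
            domain_dup_rate = domain_dup_rate,
            domain_del_rate = domain_del_rate, shuffle_rate = shuffle_rate,
            rearrange_rate = rearrange_rate, hgt_rate = hgt_rate)
  if (any(unlist(r) < 0 | unlist(r) > 1)) stop("rates must lie in [0, 1]")
  structure(r, class = "mutation_rates")
}

config_rates <- function(config) do.call(mutation_rates, config$mutation)

#' Protection mask
#'
#' Restricts what mutation can touch. `proteins` lists protein indices (in
#' parse order) exempt from duplication, deletion, domain operations,
#' shuffling, rearrangement overlap and HGT insertion -- e.g. the frozen
#' input and output proteins of an evolution run. `bit_spans` lists bit
#' ranges exempt from point mutation, each
#' `list(protein = idx, from = a, to = b)` with a 0-based half-open range
#' relative to that protein's coding span (use `protein = NA` for an
#' absolute genome span). Protected proteins are re-identified by their bit
#' content after operators that restructure the string.
#'
#' @param proteins Integer vector of protein indices.
#' @param bit_spans List of relative bit spans (see above).
#' @export
protection_mask <- function(proteins = integer(0), bit_spans = list()) {
  structure(list(proteins = as.integer(proteins), bit_spans = bit_spans),
            class = "protection_mask")
}

# absolute 0-based half-open bit spans protected from point mutation
protected_bit_spans <- function(parsed, mask) {
  ps <- genome_proteins(parsed)
  out <- list()
  for (sp in mask$bit_spans) {
    if (is.null(sp$protein) || is.na(sp$protein)) {
      out[[length(out) + 1L]] <- c(sp$from, sp$to)
    } else if (sp$protein <= length(ps)) {
      base <- ps[[sp$protein]]$span[1]
      out[[length(out) + 1L]] <- c(base + sp$from,
                                   min(base + sp$to, ps[[sp$protein]]$span[2]))
    }
  }
  out
}

# --- flat site representation for structural edits ---------------------------

# protein -> flat element list; each element one site, carrying its domain's
# header metadata on the domain's first site
protein_to_flat <- function(protein) {
  out <- list()
  for (d in protein$domains) {
    meta <- d[c("allosteric", "rt_rate_bits", "phi_bits", "unused")]
    for (i in seq_along(d$sites)) {
      out[[length(out) + 1L]] <- list(meta = if (i == 1L) meta,
                                      site = d$sites[[i]])
    }
  }
  out
}

# flat element list -> protein (NULL if no sites remain); elements without a
# leading domain header fuse into the previous domain, and a headless first
# element reuses `fallback` (the original first domain's header)
flat_to_protein <- function(flat, concentration_bits, unused, fallback) {
  if (length(flat) == 0) return(NULL)
  domains <- list()
  cur <- NULL
  for (el in flat) {
    if (!is.null(el$meta) || is.null(cur)) {
      if (!is.null(cur)) domains[[length(domains) + 1L]] <- cur
      meta <- el$meta %||% fallback
      cur <- list(allosteric = meta$allosteric,
                  rt_rate_bits = meta$rt_rate_bits, phi_bits = meta$phi_bits,
                  unused = meta$unused, sites = list(el$site))
    } else {
      cur$sites[[length(cur$sites) + 1L]] <- el$site
    }
  }
  domains[[length(domains) + 1L]] <- cur
  list(concentration_bits = concentration_bits, unused = unused,
       domains = domains)
}

# replace protein `pidx` in a parsed genome with an edited structure (or
# remove it if NULL), returning the reparsed genome
update_protein <- function(parsed, pidx, new_protein) {
  seg_idx <- which(vapply(parsed$segments, function(s) s$kind == "protein", TRUE))
  si <- seg_idx[pidx]
  if (is.null(new_protein)) {
    parsed$segments[[si]] <- NULL
  } else {
    parsed$segments[[si]]$protein <- new_protein
  }
  parsed
}

# bit offsets (0-based half-open) of every site block in the genome
site_spans <- function(parsed) {
  w <- parsed$layout$widths
  sw <- site_block_width(parsed$layout)
  sepw <- parsed$layout$sep_width
  startw <- length(parsed$layout$codes$start)
  out <- list()
  off <- 0L
  p <- 0L
  for (seg in parsed$segments) {
    if (seg$kind == "junk") { off <- off + length(seg$bits); next }
    p <- p + 1L
    pos <- off + startw + w$concentration + w$protein_unused
    flat <- 0L
    for (d in seq_along(seg$protein$domains)) {
      if (d > 1L) pos <- pos + sepw                      # soft linker
      pos <- pos + w$allosteric + w$rt_rate + w$phi + w$domain_unused
      for (s in seq_along(seg$protein$domains[[d]]$sites)) {
        if (s > 1L) pos <- pos + sepw                    # hard linker
        flat <- flat + 1L
        out[[length(out) + 1L]] <- data.frame(
          protein = p, flat_site = flat, start0 = pos, end0 = pos + sw)
        pos <- pos + sw
      }
    }
    off <- off + (seg$protein$span[2] - seg$protein$span[1])
  }
  if (length(out) == 0) {
    return(data.frame(protein = integer(0), flat_site = integer(0),
                      start0 = integer(0), end0 = integer(0)))
  }
  do.call(rbind, out)
}

# re-identify proteins after a restructuring operator by matching the exact
# coding-section bit content (earliest unclaimed match wins); returns a map
# from old index to new index (NA when lost)
track_proteins <- function(old_parsed, protected, new_parsed) {
  if (length(protected) == 0) return(integer(0))
  old_keys <- vapply(genome_proteins(old_parsed), function(p)
    bitstr(protein_bits(p, old_parsed$layout)), "")
  new_keys <- vapply(genome_proteins(new_parsed), function(p)
    bitstr(protein_bits(p, new_parsed$layout)), "")
  claimed <- logical(length(new_keys))
  out <- integer(0)
  names_out <- character(0)
  for (pi in unique(protected)) {
    if (pi > length(old_keys)) next
    hit <- which(new_keys == old_keys[pi] & !claimed)
    if (length(hit)) {
      claimed[hit[1]] <- TRUE
      out <- c(out, hit[1])
      names_out <- c(names_out, as.character(pi))
    }
  }
  names(out) <- names_out
  out
}

# remap every protein reference in a protection mask (indices and the
# protein-relative bit spans) across a restructuring step
track_mask <- function(old_parsed, mask, new_parsed) {
  refs <- c(mask$proteins,
            unlist(lapply(mask$bit_spans, function(sp)
              if (!is.null(sp$protein) && !is.na(sp$protein)) sp$protein)))
  map <- track_proteins(old_parsed, refs, new_parsed)
  mask$proteins <- unname(map[as.character(mask$proteins)])
  mask$proteins <- mask$proteins[!is.na(mask$proteins)]
  mask$bit_spans <- Filter(Negate(is.null), lapply(mask$bit_spans, function(sp) {
    if (is.null(sp$protein) || is.na(sp$protein)) return(sp)
    new_idx <- map[as.character(sp$protein)]
    if (is.na(new_idx) || is.null(new_idx) || length(new_idx) == 0) return(NULL)
    sp$protein <- unname(new_idx)
    sp
  }))
  mask
}

# --- deterministic appliers (used both by the operators and by replay) ------

apply_point <- function(g, positions0) {
  if (length(positions0)) g$bits[positions0 + 1L] <- 1L - g$bits[positions0 + 1L]
  g
}

apply_protein_dup <- function(parsed, pidx) {
  prot <- genome_proteins(parsed)[[pidx]]
  parsed$segments[[length(parsed$segments) + 1L]] <-
    list(kind = "protein", protein = prot)
  parsed
}

apply_protein_del <- function(parsed, pidx) update_protein(parsed, pidx, NULL)

apply_domain_dup <- function(parsed, pidx, from, to) {
  prot <- genome_proteins(parsed)[[pidx]]
  flat <- protein_to_flat(prot)
  copy <- flat[from:to]
  # a fragment starting at a domain head keeps its header (the copy starts
  # a new identical domain); a mid-domain fragment fuses by a hard linker
  flat <- append(flat, copy, after = to)
  update_protein(parsed, pidx, flat_to_protein(
    flat, prot$concentration_bits, prot$unused,
    prot$domains[[1]][c("allosteric", "rt_rate_bits", "phi_bits", "unused")]))
}

apply_domain_del <- function(parsed, pidx, from, to) {
  prot <- genome_proteins(parsed)[[pidx]]
  flat <- protein_to_flat(prot)
  flat <- flat[-(from:to)]
  update_protein(parsed, pidx, flat_to_protein(
    flat, prot$concentration_bits, prot$unused,
    prot$domains[[1]][c("allosteric", "rt_rate_bits", "phi_bits", "unused")]))
}

apply_shuffle <- function(parsed, pidx, to, donor, dfrom, dto) {
  prots <- genome_proteins(parsed)
  copy <- protein_to_flat(prots[[donor]])[dfrom:dto]
  copy[[1]]$meta <- NULL   # fused by a hard linker
  prot <- prots[[pidx]]
  flat <- append(protein_to_flat(prot), copy, after = to)
  update_protein(parsed, pidx, flat_to_protein(
    flat, prot$concentration_bits, prot$unused,
    prot$domains[[1]][c("allosteric", "rt_rate_bits", "phi_bits", "unused")]))
}

apply_segment_del <- function(g, start0, end0) {
  keep <- setdiff(seq_along(g$bits), (start0 + 1L):end0)
  g$bits <- g$bits[keep]
  g
}

apply_segment_dup <- function(g, start0, end0) {
  seg <- g$bits[(start0 + 1L):end0]
  g$bits <- append(g$bits, seg, after = end0)
  g
}

apply_insert <- function(g, pos0, insert_bits) {
  g$bits <- append(g$bits, insert_bits, after = pos0)
  g
}

# --- operators ---------------------------------------------------------------

#' Mutation operators
#'
#' Each operator draws from the current RNG stream, honours the
#' [protection_mask()], and returns `list(genome, events)` where `events`
#' records the operator parameters needed to replay the change with
#' [replay_mutations()].
#'
#' * `point_mutate()`: flips each unprotected bit independently with
#'   probability `rate`.
#' * `duplicate_protein()` / `delete_protein()`: per unprotected protein,
#'   with probability `rate`, appends a copy of its full coding section to
#'   the end of the genome / removes the section and closes the gap.
#' * `domain_dup_del()`: per unprotected protein, picks a fragment of whole
#'   reactive-site blocks and duplicates it in place (fused by a hard
#'   linker) or deletes it; a domain whose sites are all deleted disappears,
#'   and a protein losing all sites is deleted.
#' * `domain_shuffle()`: per unprotected protein, copies a site-block
#'   fragment from a random protein and fuses it after a fragment of the
#'   target protein.
#' * `genome_rearrange()`: with probability `rate` per genome, deletes or
#'   duplicates in place a contiguous segment snapped to site-block
#'   boundaries, possibly crossing protein boundaries.
#' * `horizontal_transfer()`: population mode only; copies a multi-site
#'   segment from a donor genome into the recipient at a boundary between
#'   two reactive sites (the donor is untouched).
#'
#' @param g,donor,recipient [genome()] objects.
#' @param rate,dup_rate,del_rate Operator probabilities in \[0, 1\].
#' @param mask A [protection_mask()].
#' @return `list(genome, events)`.
#' @name mutation_operators
NULL

#' @rdname mutation_operators
#' @export
point_mutate <- function(g, rate, mask = protection_mask()) {
  n <- length(g$bits)
  if (n == 0 || rate == 0) return(list(genome = g, events = list()))
  hits <- which(stats::runif(n) < rate) - 1L
  if (length(hits)) {
    spans <- protected_bit_spans(parse_genome(g), mask)
    for (sp in spans) hits <- hits[hits < sp[1] | hits >= sp[2]]
  }
  ev <- if (length(hits)) list(list(op = "point", positions = hits)) else list()
  list(genome = apply_point(g, hits), events = ev)
}

#' @rdname mutation_operators
#' @export
duplicate_protein <- function(g, rate, mask = protection_mask()) {
  parsed <- parse_genome(g)
  np <- length(genome_proteins(parsed))
  events <- list()
  for (p in seq_len(np)) {
    if (p %in% mask$proteins) next
    if (stats::runif(1) < rate) {
      parsed <- apply_protein_dup(parsed, p)
      events[[length(events) + 1L]] <- list(op = "protein_dup", protein = p)
    }
  }
  list(genome = serialize_genome(parsed), events = events)
}

#' @rdname mutation_operators
#' @export
delete_protein <- function(g, rate, mask = protection_mask()) {
  parsed <- parse_genome(g)
  np <- length(genome_proteins(parsed))
  events <- list()
  doomed <- integer(0)
  for (p in seq_len(np)) {
    if (p %in% mask$proteins) next
    if (stats::runif(1) < rate) doomed <- c(doomed, p)
  }
  for (p in rev(doomed)) {   # descending: indices stay valid
    parsed <- apply_protein_del(parsed, p)
    events[[length(events) + 1L]] <- list(op = "protein_del", protein = p)
  }
  list(genome = serialize_genome(parsed), events = events)
}

# pick a whole-site fragment (>= 1 site) of a protein with S sites
pick_fragment <- function(S) {
  from <- sample.int(S, 1)
  to <- if (from == S) S else sample(from:S, 1)
  c(from, to)
}

#' @rdname mutation_operators
#' @export
domain_dup_del <- function(g, dup_rate, del_rate, mask = protection_mask()) {
  events <- list()
  for (action in c("dup", "del")) {
    rate <- if (action == "dup") dup_rate else del_rate
    parsed <- parse_genome(g)
    prots <- genome_proteins(parsed)
    picks <- list()
    for (p in seq_along(prots)) {      # decisions in ascending protein order
      if (p %in% mask$proteins) next
      if (stats::runif(1) >= rate) next
      fr <- pick_fragment(length(protein_to_flat(prots[[p]])))
      picks[[length(picks) + 1L]] <- list(p = p, fr = fr)
    }
    # apply deletions in descending protein order: an emptied (hence
    # removed) protein must not shift the indices of pending edits
    if (action == "del") picks <- rev(picks)
    for (pk in picks) {
      parsed <- if (action == "dup") {
        apply_domain_dup(parsed, pk$p, pk$fr[1], pk$fr[2])
      } else {
        apply_domain_del(parsed, pk$p, pk$fr[1], pk$fr[2])
      }
      events[[length(events) + 1L]] <- list(op = paste0("domain_", action),
                                            protein = pk$p, from = pk$fr[1],
                                            to = pk$fr[2])
    }
    g <- serialize_genome(parsed)
  }
  list(genome = g, events = events)
}

#' @rdname mutation_operators
#' @export
domain_shuffle <- function(g, rate, mask = protection_mask()) {
  parsed <- parse_genome(g)
  prots <- genome_proteins(parsed)
  events <- list()
  for (p in seq_along(prots)) {
    if (p %in% mask$proteins) next
    if (stats::runif(1) >= rate) next
    prots_now <- genome_proteins(parsed)
    S <- length(protein_to_flat(prots_now[[p]]))
    fr <- pick_fragment(S)
    donor <- sample.int(length(prots_now), 1)
    Sd <- length(protein_to_flat(prots_now[[donor]]))
    dfr <- pick_fragment(Sd)
    parsed <- apply_shuffle(parsed, p, fr[2], donor, dfr[1], dfr[2])
    events[[length(events) + 1L]] <- list(op = "shuffle", protein = p,
                                          to = fr[2], donor = donor,
                                          dfrom = dfr[1], dto = dfr[2])
  }
  list(genome = serialize_genome(parsed), events = events)
}

#' @rdname mutation_operators
#' @export
genome_rearrange <- function(g, rate, mask = protection_mask()) {
  if (stats::runif(1) >= rate) return(list(genome = g, events = list()))
  parsed <- parse_genome(g)
  spans <- site_spans(parsed)
  if (nrow(spans) == 0) return(list(genome = g, events = list()))
  prots <- genome_proteins(parsed)
  prot_spans <- lapply(mask$proteins[mask$proteins <= length(prots)],
                       function(p) prots[[p]]$span)
  for (try in 1:20) {
    a <- sample.int(nrow(spans), 1)
    b <- if (a == nrow(spans)) a else sample(a:nrow(spans), 1)
    start0 <- spans$start0[a]; end0 <- spans$end0[b]
    clash <- any(vapply(prot_spans, function(sp)
      start0 < sp[2] && end0 > sp[1], TRUE))
    if (!clash) {
      action <- if (stats::runif(1) < 0.5) "del" else "dup"
      gg <- if (action == "del") apply_segment_del(g, start0, end0) else
        apply_segment_dup(g, start0, end0)
      return(list(genome = gg,
                  events = list(list(op = paste0("rearrange_", action),
                                     start0 = start0, end0 = end0))))
    }
  }
  list(genome = g, events = list())
}

#' @rdname mutation_operators
#' @export
horizontal_transfer <- function(donor, recipient, rate,
                                mask = protection_mask()) {
  if (stats::runif(1) >= rate) return(list(genome = recipient, events = list()))
  dparsed <- parse_genome(donor)
  dspans <- site_spans(dparsed)
  if (nrow(dspans) == 0) return(list(genome = recipient, events = list()))
  # donor fragment: whole site blocks within one protein, including the
  # 3-bit separator that follows the last block (every site block has one)
  p <- sample(unique(dspans$protein), 1)
  rows <- which(dspans$protein == p)
  a <- if (length(rows) == 1) rows else sample(rows, 1)
  b <- if (a == max(rows)) a else sample(a:max(rows), 1)
  seg <- donor$bits[(dspans$start0[a] + 1L):(dspans$end0[b] + 3L)]

  rparsed <- parse_genome(recipient)
  rspans <- site_spans(rparsed)
  ok <- if (nrow(rspans)) !(rspans$protein %in% mask$proteins) else logical(0)
  pos0 <- if (any(ok)) {
    k <- which(ok); k <- if (length(k) == 1) k else sample(k, 1)
    rspans$start0[k]          # boundary just before an existing site block
  } else {
    length(recipient$bits)
  }
  list(genome = apply_insert(recipient, pos0, seg),
       events = list(list(op = "hgt", pos0 = pos0, bits = seg)))
}

#' Composite mutation step
#'
#' Applies the operators in a fixed order -- rearrangement, protein
#' duplication/deletion, domain duplication/deletion, domain shuffling,
#' point mutation -- so that a (parent, rates, seed) triple always produces
#' the same child. Protected proteins are re-identified by bit content
#' after the bit-level rearrangement stage.
#'
#' @param g Parent [genome()].
#' @param rates A [mutation_rates()].
#' @param mask A [protection_mask()].
#' @param seed Optional integer seed.
#' @return `list(genome, events, mask)`: the child, the replayable event
#'   log, and the mask with protein indices updated to the child's parse
#'   order.
#' @export
mutate_genome <- function(g, rates = mutation_rates(),
                          mask = protection_mask(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  events <- list()
  grab <- function(res) { events <<- c(events, res$events); res$genome }

  before <- parse_genome(g)
  g <- grab(genome_rearrange(g, rates$rearrange_rate, mask))
  mask <- track_mask(before, mask, parse_genome(g))

  g <- grab(duplicate_protein(g, rates$protein_dup_rate, mask))
  before <- parse_genome(g)
  g <- grab(delete_protein(g, rates$protein_del_rate, mask))
  mask <- track_mask(before, mask, parse_genome(g))

  before <- parse_genome(g)
  g <- grab(domain_dup_del(g, rates$domain_dup_rate, rates$domain_del_rate,
                           mask))
  # a domain deletion can empty (and thereby delete) another protein,
  # shifting indices
  mask <- track_mask(before, mask, parse_genome(g))
  g <- grab(domain_shuffle(g, rates$shuffle_rate, mask))
  before <- parse_genome(g)
  g <- grab(point_mutate(g, rates$point_rate, mask))
  # point mutations can silence genes (or spawn new ones upstream), so the
  # returned mask is re-anchored to the child's parse; a protein whose
  # reading frame was lost drops out of the mask
  mask <- track_mask(before, mask, parse_genome(g))
  list(genome = g, events = events, mask = mask)
}

#' Replay a mutation event log
#'
#' Applies the logged events of [mutate_genome()] (or any single operator)
#' to the parent genome, reproducing the child bit-exactly without touching
#' the RNG.
#'
#' @param g Parent [genome()].
#' @param events Event list as returned in `$events`.
#' @return The child [genome()].
#' @export
replay_mutations <- function(g, events) {
  for (ev in events) {
    g <- switch(ev$op,
      point = apply_point(g, ev$positions),
      protein_dup = serialize_genome(apply_protein_dup(parse_genome(g),
                                                       ev$protein)),
      protein_del = serialize_genome(apply_protein_del(parse_genome(g),
                                                       ev$protein)),
      domain_dup = serialize_genome(apply_domain_dup(parse_genome(g),
                                                     ev$protein, ev$from,
                                                     ev$to)),
      domain_del = serialize_genome(apply_domain_del(parse_genome(g),
                                                     ev$protein, ev$from,
                                                     ev$to)),
      shuffle = serialize_genome(apply_shuffle(parse_genome(g), ev$protein,
                                               ev$to, ev$donor, ev$dfrom,
                                               ev$dto)),
      rearrange_del = apply_segment_del(g, ev$start0, ev$end0),
      rearrange_dup = apply_segment_dup(g, ev$start0, ev$end0),
      hgt = apply_insert(g, ev$pos0, ev$bits),
      stop("unknown mutation event: ", ev$op)
    )
  }
  g
}

#' Write a mutation event log as JSON lines
#' @param events Event list.
#' @param path Output path.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(events, function(ev)
    jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path)
  invisible(path)
}
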