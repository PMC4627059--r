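#' Genome objects
#'
#' A genome is a finite binary string together with the [genome_layout()]
#' that governs its interpretation. Any bit content is a legal genome:
#' regions that do not parse as protein-coding sections are untranslated
#' ("junk") sequence.
#'
#' @param bits Integer vector over {0, 1} or a character string of `0`/`1`.
#' @param layout A [genome_layout()].
#' @return An object of class `genome`.
#' @export
genome <- function(bits = integer(0), layout = genome_layout()) {
  b <- if (is.character(bits)) bits(bits) else {
    b <- as.integer(bits)
    if (anyNA(b) || any(b < 0L | b > 1L)) stop("bits must be 0 or 1")
    b
  }
  structure(list(bits = b, layout = layout), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x$bits), " bits\n", sep = "")
  invisible(x)
}

#' @export
length.genome <- function(x) length(x$bits)

#' Uniform random genome
#'
#' Draws `n_bits` i.i.d. fair bits. Used to start evolutionary runs from
#' entirely random initial points.
#'
#' @param n_bits Number of bits (>= 0).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @inheritParams genome
#' @return A [genome()].
#' @export
random_genome <- function(n_bits, seed = NULL, layout = genome_layout()) {
  stopifnot(n_bits >= 0)
  if (!is.null(seed)) set.seed(seed)
  genome(if (n_bits == 0) integer(0) else sample(0:1, n_bits, replace = TRUE),
         layout)
}

# --- parsing ---------------------------------------------------------------

# Attempt to parse one protein starting right AFTER its start code.
# Returns NULL on any malformed structure (unknown separator, truncation),
# else list(protein = <struct>, end = first position after the stop code).
parse_protein_at <- function(b, pos, layout) {
  n <- length(b)
  w <- layout$widths
  take <- function(width) {
    if (pos + width - 1L > n) return(NULL)
    out <- b[pos:(pos + width - 1L)]
    pos <<- pos + width
    out
  }
  conc <- take(w$concentration); if (is.null(conc)) return(NULL)
  punused <- take(w$protein_unused); if (is.null(punused)) return(NULL)
  domains <- list()
  repeat {
    flag <- take(w$allosteric); if (is.null(flag)) return(NULL)
    rt <- take(w$rt_rate); if (is.null(rt)) return(NULL)
    phi <- take(w$phi); if (is.null(phi)) return(NULL)
    dunused <- take(w$domain_unused); if (is.null(dunused)) return(NULL)
    sites <- list()
    new_domain <- FALSE
    done <- FALSE
    repeat {
      site <- vector("list", length(site_fields()))
      names(site) <- site_fields()
      for (f in site_fields()) {
        site[[f]] <- take(w[[f]])
        if (is.null(site[[f]])) return(NULL)
      }
      sites[[length(sites) + 1L]] <- site
      sep <- take(layout$sep_width)
      if (is.null(sep)) return(NULL)
      if (identical(sep, layout$codes$hard)) next
      if (identical(sep, layout$codes$soft)) { new_domain <- TRUE; break }
      if (identical(sep, layout$codes$stop)) { done <- TRUE; break }
      return(NULL)  # undefined separator pattern: abort this protein
    }
    domains[[length(domains) + 1L]] <- list(
      allosteric = flag, rt_rate_bits = rt, phi_bits = phi,
      unused = dunused, sites = sites
    )
    if (done) break
    stopifnot(new_domain)
  }
  list(protein = list(concentration_bits = conc, unused = punused,
                      domains = domains),
       end = pos)
}

#' Parse a genome into proteins and junk spans
#'
#' Scans the string left to right for the start code; after a start code,
#' fixed-width fields are consumed, with a 3-bit separator after every
#' reactive-site block selecting the next element (hard linker: another site,
#' soft linker: a new domain, stop code: end of protein). An undefined
#' separator or running off the end of the genome aborts the candidate
#' protein: its region stays untranslated and scanning resumes immediately
#' after the aborted start code. The parser is total -- it never fails on
#' any bitstring -- so point mutations can silence a gene by corrupting its
#' start code and the result is simply more junk.
#'
#' @param g A [genome()].
#' @return A `parsed_genome`: ordered segments (`junk` spans kept verbatim,
#'   `protein` structures holding every field bit-exactly), plus the layout.
#'   Spans are reported 0-based, half-open.
#' @export
parse_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  b <- g$bits
  layout <- g$layout
  n <- length(b)
  start <- layout$codes$start
  sw <- length(start)
  segments <- list()
  junk_from <- 1L
  flush_junk <- function(upto) {           # junk span [junk_from, upto]
    if (upto >= junk_from) {
      segments[[length(segments) + 1L]] <<- list(
        kind = "junk", bits = b[junk_from:upto])
    }
  }
  # candidate start-code positions (overlapping matches allowed)
  cand <- if (n >= sw) {
    ok <- rep(TRUE, n - sw + 1L)
    for (k in seq_len(sw)) ok <- ok & (b[k:(n - sw + k)] == start[k])
    which(ok)
  } else integer(0)
  i <- 1L
  for (p in cand) {
    if (p < i) next
    res <- parse_protein_at(b, p + sw, layout)
    if (is.null(res)) {
      i <- p + sw            # abort: rescan after the start code
    } else {
      flush_junk(p - 1L)
      prot <- res$protein
      prot$span <- c(p - 1L, res$end - 1L)   # 0-based half-open
      segments[[length(segments) + 1L]] <- list(kind = "protein",
                                                protein = prot)
      i <- res$end
      junk_from <- i
    }
  }
  flush_junk(n)
  structure(list(segments = segments, layout = layout, n_bits = n),
            class = "parsed_genome")
}

#' Extract the protein list from a parsed genome
#' @param parsed A `parsed_genome`.
#' @return List of protein structures in genome order.
#' @export
genome_proteins <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_genome"))
  lapply(Filter(function(s) s$kind == "protein", parsed$segments),
         function(s) s$protein)
}

#' @export
print.parsed_genome <- function(x, ...) {
  ps <- genome_proteins(x)
  cat("<parsed_genome> ", x$n_bits, " bits, ", length(ps), " protein(s)\n",
      sep = "")
  for (i in seq_along(ps)) {
    nd <- length(ps[[i]]$domains)
    ns <- sum(vapply(ps[[i]]$domains, function(d) length(d$sites), 1L))
    cat(sprintf("  P%d: span [%d,%d), %d domain(s), %d site(s)\n",
                i, ps[[i]]$span[1], ps[[i]]$span[2], nd, ns))
  }
  invisible(x)
}

# --- serialization ---------------------------------------------------------

site_bits <- function(site) unlist(site[site_fields()], use.names = FALSE)

domain_bits <- function(domain, layout) {
  c(domain$allosteric, domain$rt_rate_bits, domain$phi_bits, domain$unused,
    unlist(lapply(seq_along(domain$sites), function(i) {
      if (i == 1L) site_bits(domain$sites[[i]])
      else c(layout$codes$hard, site_bits(domain$sites[[i]]))
    }), use.names = FALSE))
}

protein_bits <- function(protein, layout) {
  c(layout$codes$start, protein$concentration_bits, protein$unused,
    unlist(lapply(seq_along(protein$domains), function(i) {
      if (i == 1L) domain_bits(protein$domains[[i]], layout)
      else c(layout$codes$soft, domain_bits(protein$domains[[i]], layout))
    }), use.names = FALSE),
    layout$codes$stop)
}

#' Serialize a parsed genome back to bits
#'
#' Junk spans are emitted verbatim and protein structures are re-encoded
#' field by field, so `serialize_genome(parse_genome(g))` reproduces `g`
#' bit-exactly.
#'
#' @param parsed A `parsed_genome` (possibly with edited protein structures).
#' @return A [genome()].
#' @export
serialize_genome <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_genome"))
  pieces <- lapply(parsed$segments, function(s) {
    if (s$kind == "junk") s$bits else protein_bits(s$protein, parsed$layout)
  })
  genome(unlist(pieces, use.names = FALSE) %||% integer(0), parsed$layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- decoding to a protein set --------------------------------------------

SITE_TYPES <- c("00" = "bsite", "01" = "msite", "11" = "csite",
                "10" = "bsite")  # undefined pattern decodes to an inert bsite

#' Decode parsed proteins into a typed protein set
#'
#' Turns raw bit fields into real-valued kinetic and allosteric parameters
#' using the configured scaling ranges: concentration (loglinear),
#' basal R-T transition rate (loglinear; a single encoded rate r sets
#' k_RT = k_TR = r, a neutral basal equilibrium that Gamma factors can
#' bias), Phi (linear on \[0,1\]) and Gamma (loglinear). Rate profiles stay
#' as bit vectors: binding decisions and binding kinetics are pairwise
#' properties resolved by the network compiler.
#'
#' @param parsed A `parsed_genome`.
#' @param config An `evosig_config`.
#' @return A `protein_set`: list of proteins with decoded parameters.
#' @export
decode_proteins <- function(parsed, config = default_config()) {
  sc <- config_scalings(config)
  ps <- genome_proteins(parsed)
  proteins <- lapply(seq_along(ps), function(i) {
    p <- ps[[i]]
    domains <- lapply(p$domains, function(d) {
      sites <- lapply(d$sites, function(s) {
        list(
          type = SITE_TYPES[[bitstr(s$site_type)]],
          polarity = if (s$polarity == 1L) "unmodify" else "modify",
          binding_profile = s$binding_profile,
          kf_profile = s$kf_profile, kb_profile = s$kb_profile,
          kp_profile = s$kp_profile,
          gamma = decode_scaled(s$keq_ratio, sc$gamma),
          kf_polarity_mask = s$kf_polarity_mask,
          kb_polarity_mask = s$kb_polarity_mask,
          kf_conf_mask = s$kf_conf_mask, kb_conf_mask = s$kb_conf_mask,
          kp_conf_mask = s$kp_conf_mask
        )
      })
      list(allosteric = d$allosteric == 1L,
           rt_rate = decode_scaled(d$rt_rate_bits, sc$rt),
           phi = decode_scaled(d$phi_bits, sc$phi),
           sites = sites)
    })
    list(name = paste0("P", i),
         concentration = decode_scaled(p$concentration_bits, sc$concentration),
         domains = domains)
  })
  structure(proteins, class = "protein_set")
}

# --- text I/O --------------------------------------------------------------

#' Read and write genome text files
#'
#' FASTA-like plain-text format: a header line `>name length=N` followed by
#' the bit characters wrapped at 80 columns.
#'
#' @param g A [genome()].
#' @param path File path.
#' @param name Sequence name for the header.
#' @export
write_genome <- function(g, path, name = "genome") {
  stopifnot(inherits(g, "genome"))
  s <- bitstr(g$bits)
  rows <- if (nzchar(s)) {
    starts <- seq(1L, nchar(s), by = 80L)
    substring(s, starts, pmin(starts + 79L, nchar(s)))
  } else character(0)
  writeLines(c(sprintf(">%s length=%d", name, length(g$bits)), rows), path)
  invisible(path)
}

#' @rdname write_genome
#' @inheritParams genome
#' @export
read_genome <- function(path, layout = genome_layout()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    stop("genome file must begin with a '>name length=N' header")
  }
  body <- paste(lines[-1], collapse = "")
  g <- genome(gsub("\\s", "", body), layout)
  n <- suppressWarnings(as.integer(sub(".*length=(\\d+).*", "\\1", lines[1])))
  if (!is.na(n) && n != length(g$bits)) {
    stop("genome length mismatch: header says ", n, ", body has ",
         length(g$bits))
  }
  g
}
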