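#' Construct protein sets programmatically
#'
#' [decode_proteins()] produces a `protein_set` from a genome; these
#' constructors build the same structure directly from decoded values,
#' which is convenient for hand-built fixtures and for tests that need a
#' network with exact kinetics.
#'
#' @param type Site type: `"bsite"` (binding), `"msite"` (modifiable) or
#'   `"csite"` (catalytic).
#' @param polarity For csites, `"modify"` (kinase-like) or `"unmodify"`
#'   (phosphatase-like).
#' @param binding_profile 10-bit binding profile (vector or string).
#' @param kf_profile,kb_profile 20-bit rate profiles.
#' @param kp_profile 10-bit catalytic rate profile (csites).
#' @param gamma Equilibrium-shift factor Gamma (> 0).
#' @param kf_polarity_mask,kb_polarity_mask,kf_conf_mask,kb_conf_mask,kp_conf_mask
#'   Optional 20-bit masks (all zeros by default: state-independent rates).
#' @return A site structure.
#' @export
make_site <- function(type = "bsite", polarity = "modify",
                      binding_profile = rep(0L, 10),
                      kf_profile = rep(0L, 20), kb_profile = rep(0L, 20),
                      kp_profile = rep(0L, 10), gamma = 1,
                      kf_polarity_mask = rep(0L, 20),
                      kb_polarity_mask = rep(0L, 20),
                      kf_conf_mask = rep(0L, 20),
                      kb_conf_mask = rep(0L, 20),
                      kp_conf_mask = rep(0L, 20)) {
  stopifnot(type %in% c("bsite", "msite", "csite"),
            polarity %in% c("modify", "unmodify"), gamma > 0)
  as_bits <- function(x) if (is.character(x)) bits(x) else as.integer(x)
  list(type = type, polarity = polarity,
       binding_profile = as_bits(binding_profile),
       kf_profile = as_bits(kf_profile), kb_profile = as_bits(kb_profile),
       kp_profile = as_bits(kp_profile), gamma = gamma,
       kf_polarity_mask = as_bits(kf_polarity_mask),
       kb_polarity_mask = as_bits(kb_polarity_mask),
       kf_conf_mask = as_bits(kf_conf_mask),
       kb_conf_mask = as_bits(kb_conf_mask),
       kp_conf_mask = as_bits(kp_conf_mask))
}

#' @rdname make_site
#' @param sites List of [make_site()] structures (>= 1).
#' @param allosteric Whether the domain switches R/T conformations.
#' @param rt_rate Basal R-T transition rate (s^-1); sets both k_RT and k_TR.
#' @param phi Partition exponent in \[0, 1\].
#' @export
make_domain <- function(sites, allosteric = FALSE, rt_rate = 1, phi = 0.5) {
  stopifnot(length(sites) >= 1, rt_rate > 0, phi >= 0, phi <= 1)
  list(allosteric = allosteric, rt_rate = rt_rate, phi = phi, sites = sites)
}

#' @rdname make_site
#' @param name Protein name.
#' @param concentration Initial concentration (uM).
#' @param domains List of [make_domain()] structures (>= 1).
#' @export
make_protein <- function(name, concentration, domains) {
  stopifnot(length(domains) >= 1, concentration >= 0)
  list(name = name, concentration = concentration, domains = domains)
}

#' @rdname make_site
#' @param ... [make_protein()] structures.
#' @export
protein_set <- function(...) {
  structure(list(...), class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("<protein_set> ", length(x), " protein(s)\n", sep = "")
  for (p in x) {
    cat(sprintf("  %s: %.4g uM, %d domain(s), %d site(s)\n", p$name,
                p$concentration, length(p$domains),
                sum(vapply(p$domains, function(d) length(d$sites), 1L))))
  }
  invisible(x)
}
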