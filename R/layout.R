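#' Genome layout
#'
#' The genome is a binary string with a hierarchical, gene-like structure:
#' proteins are delimited by a fixed start code and stop code, domains within
#' a protein are separated by a soft linker, and reactive sites within a
#' domain by a hard linker. Every parameter field has a fixed width. This
#' object collects the codes and widths; all parsing and serialization is
#' driven by it so alternative layouts can be configured.
#'
#' Field widths (bits), in the order they appear on the string:
#' * protein: start code (8), concentration (10), unused (4), domains, stop
#'   code (3);
#' * domain: allosteric flag (1), R-T transition rate (10), phi (10),
#'   unused (4), reactive sites;
#' * reactive site: type (2), substrate polarity (1), binding profile (10),
#'   kf profile (20), kb profile (20), kp profile (10), keq ratio (10),
#'   kf polarity mask (20), kb polarity mask (20), kf conformation mask (20),
#'   kb conformation mask (20), kp conformation mask (20), unused (4).
#'
#' @param start_code,stop_code,soft_linker,hard_linker Bit patterns given as
#'   character strings.
#' @param widths Named list of field widths; see Details for the defaults.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(start_code = "01111110", stop_code = "111",
                          soft_linker = "001", hard_linker = "000",
                          widths = list()) {
  w <- list(
    concentration = 10L, protein_unused = 4L,
    allosteric = 1L, rt_rate = 10L, phi = 10L, domain_unused = 4L,
    site_type = 2L, polarity = 1L, binding_profile = 10L,
    kf_profile = 20L, kb_profile = 20L, kp_profile = 10L, keq_ratio = 10L,
    kf_polarity_mask = 20L, kb_polarity_mask = 20L,
    kf_conf_mask = 20L, kb_conf_mask = 20L, kp_conf_mask = 20L,
    site_unused = 4L
  )
  w[names(widths)] <- lapply(widths, as.integer)
  if (any(unlist(w) < 1L)) stop("all field widths must be >= 1")
  codes <- list(start = bits(start_code), stop = bits(stop_code),
                soft = bits(soft_linker), hard = bits(hard_linker))
  if (identical(codes$soft, codes$hard) || identical(codes$soft, codes$stop) ||
      identical(codes$hard, codes$stop)) {
    stop("stop code and linkers must be pairwise distinct")
  }
  if (length(codes$soft) != length(codes$hard) ||
      length(codes$soft) != length(codes$stop)) {
    stop("stop code and linkers must share one separator width")
  }
  structure(list(codes = codes, widths = w,
                 sep_width = length(codes$stop)),
            class = "genome_layout")
}

# Field names of one reactive-site block, in string order.
site_fields <- function() {
  c("site_type", "polarity", "binding_profile", "kf_profile", "kb_profile",
    "kp_profile", "keq_ratio", "kf_polarity_mask", "kb_polarity_mask",
    "kf_conf_mask", "kb_conf_mask", "kp_conf_mask", "site_unused")
}

site_block_width <- function(layout) {
  sum(unlist(layout$widths[site_fields()]))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> start=", bitstr(x$codes$start),
      " stop=", bitstr(x$codes$stop),
      " soft=", bitstr(x$codes$soft),
      " hard=", bitstr(x$codes$hard), "\n", sep = "")
  cat("  site block:", site_block_width(x), "bits\n")
  invisible(x)
}

#' Scaling of bit fields to real parameter values
#'
#' A bit field of width L is read as a big-endian unsigned integer v and
#' mapped onto a configured range. With `m = 2^L - 1`:
#' * linear: `lo + (hi - lo) * v / m`;
#' * loglinear: `lo * (hi / lo)^(v / m)`.
#'
#' Both scalings are strictly increasing in v and hit the endpoints exactly
#' (`v = 0 -> lo`, `v = m -> hi`). Concentrations and kinetic rate constants
#' use the loglinear scaling over ranges spanning several decades; the
#' allosteric partition exponent phi uses the linear scaling on \[0, 1\].
#'
#' @param mode `"linear"` or `"loglinear"`.
#' @param lo,hi Range endpoints (`lo < hi`; `loglinear` requires `lo > 0`).
#' @return A `scaling_spec` object.
#' @export
scaling_spec <- function(mode = c("linear", "loglinear"), lo, hi) {
  mode <- match.arg(mode)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) stop("need lo < hi")
  if (mode == "loglinear" && lo <= 0) {
    stop("loglinear scaling requires lo > 0")
  }
  structure(list(mode = mode, lo = lo, hi = hi), class = "scaling_spec")
}

#' Decode a bit field into a real value
#'
#' @param field Integer bit vector (big-endian, first bit most significant).
#' @param spec A [scaling_spec()].
#' @return A real number in `[spec$lo, spec$hi]`.
#' @examples
#' decode_scaled(rep(0L, 10), scaling_spec("linear", 0, 1))
#' decode_scaled(rep(1L, 10), scaling_spec("loglinear", 1e-3, 1e3))
#' @export
decode_scaled <- function(field, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  v <- bits_to_uint(field)
  m <- 2^length(field) - 1
  if (spec$mode == "linear") {
    spec$lo + (spec$hi - spec$lo) * v / m
  } else {
    spec$lo * (spec$hi / spec$lo)^(v / m)
  }
}

#' Encode a real value as the nearest representable bit field
#'
#' Inverse of [decode_scaled()] up to quantization: returns the bit field of
#' the requested width whose decoded value is closest to `value` (in log
#' space for the loglinear scaling). Used by the seed-network builder to
#' write target concentrations and rate constants onto a genome.
#'
#' @param value Target value, clamped to `[spec$lo, spec$hi]`.
#' @param width Field width in bits.
#' @inheritParams decode_scaled
#' @export
encode_scaled <- function(value, width, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  value <- min(max(value, spec$lo), spec$hi)
  m <- 2^width - 1
  frac <- if (spec$mode == "linear") {
    (value - spec$lo) / (spec$hi - spec$lo)
  } else {
    log(value / spec$lo) / log(spec$hi / spec$lo)
  }
  uint_to_bits(round(frac * m), width)
}
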