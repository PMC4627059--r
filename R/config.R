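#' Default configuration
#'
#' One flat configuration object controls the whole pipeline: genome layout,
#' parameter scaling ranges, compiler caps, solver tolerances, stimulus
#' protocol, fitness weights, mutation rates and the evolutionary engines.
#' Values can be overridden programmatically (`default_config(list(...))`)
#' or loaded from an INI-style file with [read_config()].
#'
#' Scaling ranges follow measured biochemical ranges for signaling proteins:
#' concentrations and binding/catalytic rate constants span
#' \[1e-3, 1e3\] (in uM, uM^-1 s^-1 or s^-1 as appropriate), conformational
#' transition rates and the equilibrium-shift factor Gamma span
#' \[1e-2, 1e2\], and the partition exponent Phi is linear on \[0, 1\].
#'
#' @param override Named list (possibly nested by section) of values to
#'   replace in the defaults.
#' @return A nested list of class `evosig_config`.
#' @export
default_config <- function(override = list()) {
  cfg <- list(
    encoding = list(
      start_code = "01111110", stop_code = "111",
      soft_linker = "001", hard_linker = "000"
    ),
    scaling = list(
      concentration_lo = 1e-3, concentration_hi = 1e3,   # uM
      kf_lo = 1e-3, kf_hi = 1e3,                         # uM^-1 s^-1
      kb_lo = 1e-3, kb_hi = 1e3,                         # s^-1
      kp_lo = 1e-3, kp_hi = 1e3,                         # s^-1
      rt_lo = 1e-2, rt_hi = 1e2,                         # s^-1
      gamma_lo = 1e-2, gamma_hi = 1e2,                   # dimensionless
      phi_lo = 0, phi_hi = 1                             # dimensionless
    ),
    compiler = list(
      binding_threshold = 9L,      # complementary bits (of 10) needed to bind
      max_complex_size = 2L,       # monomers per complex
      max_species = 2000L
    ),
    simulation = list(
      rtol = 1e-6, atol = 1e-9,    # solver tolerances (atol in uM)
      ss_tol = 1e-6,               # steady-state criterion
      t_max = 1e5,                 # max integration time per phase (s)
      max_steps = 5000             # solver effort cap per output interval
    ),
    protocol = list(
      input_protein = 1L, output_protein = 2L,
      # staircase levels (uM): middle decades of the concentration range
      levels = c(1e-2, 1e-1, 1, 10),
      # adaptation step (uM): a 5-fold step around mid-range
      step_levels = c(1, 5)
    ),
    scoring = list(
      w_amp = 1, w_ult = 1, w_com = 0.1,
      complexity_scale = 100,      # C0 in S_com = exp(-C / C0)
      y_max = NA_real_             # default: total output-protein conc
    ),
    mutation = list(
      point_rate = 0.002,          # per bit
      protein_dup_rate = 0.005, protein_del_rate = 0.005,  # per protein
      domain_dup_rate = 0.01, domain_del_rate = 0.01,      # per protein
      shuffle_rate = 0.01,                                 # per protein
      rearrange_rate = 0.01,                               # per genome
      hgt_rate = 0                 # per individual (population mode)
    ),
    evolution = list(
      Ne = 1e5,                    # effective population size
      alpha = 1e4,                 # acceptance speed-up, alpha * Pfix < 1
      target_fitness = 0.8,
      max_attempts = 1000L,
      population_size = 50L, generations = 20L,
      mutation_prob = 0.5          # per-individual, population mode
    )
  )
  for (sec in names(override)) {
    if (is.list(override[[sec]])) {
      cfg[[sec]][names(override[[sec]])] <- override[[sec]]
    } else {
      cfg[[sec]] <- override[[sec]]
    }
  }
  class(cfg) <- "evosig_config"
  cfg
}

#' Configuration scaling specs
#'
#' Builds the [scaling_spec()] objects for each encoded parameter from a
#' configuration.
#' @param config An `evosig_config` list.
#' @return Named list of `scaling_spec`s.
#' @export
config_scalings <- function(config) {
  s <- config$scaling
  list(
    concentration = scaling_spec("loglinear", s$concentration_lo, s$concentration_hi),
    kf = scaling_spec("loglinear", s$kf_lo, s$kf_hi),
    kb = scaling_spec("loglinear", s$kb_lo, s$kb_hi),
    kp = scaling_spec("loglinear", s$kp_lo, s$kp_hi),
    rt = scaling_spec("loglinear", s$rt_lo, s$rt_hi),
    gamma = scaling_spec("loglinear", s$gamma_lo, s$gamma_hi),
    phi = scaling_spec("linear", s$phi_lo, s$phi_hi)
  )
}

config_layout <- function(config) {
  e <- config$encoding
  genome_layout(e$start_code, e$stop_code, e$soft_linker, e$hard_linker)
}

#' Read / write INI-style configuration files
#'
#' The file format is flat `key = value` pairs grouped under `[section]`
#' headers; blank lines and lines starting with `#` or `;` are ignored.
#' Values are parsed as numeric where possible, otherwise kept as strings;
#' comma-separated values become vectors.
#'
#' @param path File path.
#' @return [read_config()] returns an `evosig_config`; [write_config()] is
#'   called for its side effect and returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  override <- list()
  section <- "misc"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!anyNA(num)) num else parts
    override[[section]][[key]] <- val
  }
  default_config(override)
}

#' @rdname read_config
#' @param config Configuration to write.
#' @export
write_config <- function(config, path) {
  out <- character(0)
  for (sec in names(config)) {
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(config[[sec]])) {
      v <- config[[sec]][[key]]
      out <- c(out, sprintf("%s = %s", key, paste(format(v, digits = 15), collapse = ", ")))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
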