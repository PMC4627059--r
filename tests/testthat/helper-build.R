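# Hand assembly of coding sections by direct concatenation of the layout's
# field widths. Kept independent of the package serializer so parse tests
# check against an explicitly constructed bit sequence.

raw_site <- function(type = "00", polarity = "0",
                     binding = strrep("0", 10),
                     kf = strrep("0", 20), kb = strrep("0", 20),
                     kp = strrep("0", 10), keq = strrep("0", 10),
                     kf_pol = strrep("0", 20), kb_pol = strrep("0", 20),
                     kf_conf = strrep("0", 20), kb_conf = strrep("0", 20),
                     kp_conf = strrep("0", 20), unused = "0000") {
  bits(paste0(type, polarity, binding, kf, kb, kp, keq,
              kf_pol, kb_pol, kf_conf, kb_conf, kp_conf, unused))
}

raw_domain <- function(sites, allosteric = "0", rt = strrep("0", 10),
                       phi = strrep("0", 10), unused = "0000") {
  body <- sites[[1]]
  for (s in sites[-1]) body <- c(body, bits("000"), s)
  c(bits(allosteric), bits(rt), bits(phi), bits(unused), body)
}

raw_protein <- function(domains, conc = strrep("0", 10), unused = "0000") {
  body <- domains[[1]]
  for (d in domains[-1]) body <- c(body, bits("001"), d)
  c(bits("01111110"), bits(conc), bits(unused), body, bits("111"))
}

one_site_protein_bits <- function(...) {
  raw_protein(list(raw_domain(list(raw_site(...)))))
}
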