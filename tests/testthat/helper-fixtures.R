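# Small fixtures built in code at test time.

peak_tbl <- function(residues, h, n, type = "A", intensity = NA_real_,
                     flags = "") {
  tibble::tibble(residue_number = as.integer(residues),
                 residue_type = type,
                 shift_h = h, shift_n = n,
                 intensity = intensity, flags = flags)
}

# A minimal two-point series with a known shift change.
tiny_series <- function(dh = 0.1, dn = 0.5, ratios = c(0, 1)) {
  apo <- peak_tbl(1:3, c(8.0, 8.5, 9.0), c(110, 115, 120))
  holo <- peak_tbl(1:3, c(8.0, 8.5, 9.0) + dh, c(110, 115, 120) + dn)
  assemble_series(list(apo, holo), ratios, c_pro = 100, c_lig = 5000)
}

write_tsv_fixture <- function(path) {
  writeLines(c(
    "residue_number\tresidue_type\tshift_h_ppm\tshift_n_ppm\tintensity\tflags",
    "5\tG\t8.310\t109.100\t500000\t",
    "6\tK\t8.050\t121.300\t\t",
    "7\tP\t\t\t\tproline"
  ), path)
  path
}
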