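#' Toy backbone template for ensemble simulations
#'
#' A single-conformer backbone (N, CA, C per residue) laid out along a
#' gentle helix-like curve with ~3.8 Angstrom CA-CA spacing. Optionally
#' adds named side-chain atoms at fixed offsets from their residue's CA.
#' Geometric realism is irrelevant for the ensemble metrics; what matters
#' is a well-defined, non-degenerate reference conformation.
#'
#' @param n_residues Number of residues.
#' @param side_chain_atoms Optional tibble with columns `residue_number`,
#'   `atom_name`, `residue_name`, `dx`, `dy`, `dz` (offsets from the CA).
#' @param chain Chain identifier.
#' @return A one-conformer atom tibble usable as an
#'   [ensemble_sim_spec()] template.
#' @export
toy_backbone_template <- function(n_residues, side_chain_atoms = NULL,
                                  chain = "A") {
  i <- seq_len(n_residues)
  t <- i * 0.55
  ca <- cbind(9.5 * cos(t), 9.5 * sin(t), 1.45 * i)
  mk <- function(atom, off) {
    tibble::tibble(atom_name = atom, residue_name = "ALA",
                   residue_number = i, chain = chain,
                   x = ca[, 1] + off[1], y = ca[, 2] + off[2],
                   z = ca[, 3] + off[3])
  }
  tmpl <- dplyr::bind_rows(
    mk("N", c(-1.20, 0.25, -0.45)),
    mk("CA", c(0, 0, 0)),
    mk("C", c(1.20, 0.30, 0.45))
  )
  if (!is.null(side_chain_atoms)) {
    sc <- tibble::as_tibble(side_chain_atoms)
    sc_rows <- tibble::tibble(
      atom_name = sc$atom_name, residue_name = sc$residue_name,
      residue_number = as.integer(sc$residue_number), chain = chain,
      x = ca[sc$residue_number, 1] + sc$dx,
      y = ca[sc$residue_number, 2] + sc$dy,
      z = ca[sc$residue_number, 3] + sc$dz)
    tmpl <- dplyr::bind_rows(tmpl, sc_rows)
    tmpl$residue_name[tmpl$residue_number %in% sc$residue_number] <-
      sc$residue_name[match(
        tmpl$residue_number[tmpl$residue_number %in% sc$residue_number],
        sc$residue_number)]
  }
  dplyr::arrange(tmpl, .data$residue_number,
                 match(.data$atom_name, c("N", "CA", "C")))
}

#' Synthetic stand-in for a double-Tudor NMR ensemble
#'
#' A fully synthetic 20-conformer ensemble of a 151-residue construct,
#' generated by [make_toy_ensemble()] and labelled as such: it is NOT a
#' deposited structure, but its generator defaults emulate the precision
#' pattern of a determined double-Tudor solution ensemble -- two
#' internally well-ordered subdomains (small atomic scatter, HTD-1
#' slightly looser than HTD-2) that are mobile relative to each other
#' (per-model rigid displacement of HTD-2), flanked by disordered N- and
#' C-terminal segments with large scatter -- plus two constructed
#' Glu50-Lys37/Lys39 salt bridges (carboxylate-O to ammonium-N target
#' distances 3.4 and 3.5 Angstrom with per-model jitter of 1.0 and 1.8).
#'
#' @param n_models Number of conformers (default 20).
#' @param seed Integer seed.
#' @param rigid_sd_htd2 SD (Angstrom) of the per-model rigid translation
#'   of HTD-2 relative to HTD-1 (default 2.5, emulating inter-domain
#'   mobility of an interdigitated double Tudor fold).
#' @return An `atom_ensemble` with backbone atoms for residues 1-151 and
#'   the four salt-bridge side-chain atoms.
#' @seealso [htd_regions()] for the matching region definitions.
#' @export
synthetic_td151_ensemble <- function(n_models = 20, seed = 1L,
                                     rigid_sd_htd2 = 2.5) {
  sc <- tibble::tribble(
    ~residue_number, ~atom_name, ~residue_name, ~dx, ~dy, ~dz,
    37L, "NZ", "LYS", 3.2, 0.6, 0.8,
    39L, "NZ", "LYS", 3.0, -0.8, 1.2,
    50L, "OE1", "GLU", 2.0, 0.1, 0.2,
    50L, "OE2", "GLU", 2.6, 1.1, 0.4
  )
  tmpl <- toy_backbone_template(151, side_chain_atoms = sc)
  spec <- ensemble_sim_spec(
    template = tmpl, n_models = n_models, regions = htd_regions(),
    displacement_sd = c(htd1 = 0.30, htd2 = 0.21, nterm = 2.5, tail = 3.5),
    rigid_sd = c(htd2 = rigid_sd_htd2),
    salt_bridges = list(
      list(donor_residue = 50L, donor_atoms = c("OE1", "OE2"),
           acceptor_residue = 37L, acceptor_atoms = "NZ",
           target = 3.4, jitter_sd = 1.0),
      list(donor_residue = 50L, donor_atoms = c("OE1", "OE2"),
           acceptor_residue = 39L, acceptor_atoms = "NZ",
           target = 3.5, jitter_sd = 1.8)
    ),
    seed = seed)
  make_toy_ensemble(spec)
}
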