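#' Specification of a simulated titration
#'
#' Holds the ground truth for a forward simulation of a fast-exchange CSP
#' titration under the n-equivalent-sites isotherm ([predict_csp()]).
#'
#' Each residue's combined CSP trajectory is decomposed onto the two
#' nuclei through a per-residue direction angle theta:
#' `delta_h = CSP * cos(theta)` and `delta_n = 5 * CSP * sin(theta)`, so
#' that the weighted recombination returns exactly the model CSP. When
#' `direction_angle` is `NULL`, angles are drawn uniformly in (0, pi/2)
#' (both nuclei move, as in real spectra), deterministically from `seed`.
#'
#' @param true_kd Dissociation constant (uM).
#' @param n_sites Equivalent independent sites per ligand.
#' @param c_pro Initial protein concentration (uM); default 100.
#' @param c_lig Ligand stock concentration (uM); default 5000 (a 5 mM
#'   DNA-duplex stock).
#' @param ratios Molar ratios, strictly increasing from 0.
#' @param residues Integer residue numbers.
#' @param cspmax Saturation CSP per residue (ppm, recycled).
#' @param direction_angle Per-residue angle in radians, or `NULL` to draw.
#' @param noise_sd_h,noise_sd_n Gaussian noise SD (ppm) added to each
#'   non-apo peak position in the 1H and 15N dimensions.
#' @param seed Integer seed; same seed, same spec gives identical output.
#' @return A `titration_sim_spec` list.
#' @export
titration_sim_spec <- function(true_kd, n_sites, c_pro = 100, c_lig = 5000,
                               ratios, residues, cspmax,
                               direction_angle = NULL,
                               noise_sd_h = 0, noise_sd_n = 0, seed = 1L) {
  check_number(true_kd, "true_kd", lower = 0)
  check_number(n_sites, "n_sites", lower = 0, allow_zero = FALSE)
  check_number(c_pro, "c_pro", lower = 0, allow_zero = FALSE)
  check_number(c_lig, "c_lig", lower = 0, allow_zero = FALSE)
  check_number(noise_sd_h, "noise_sd_h", lower = 0)
  check_number(noise_sd_n, "noise_sd_n", lower = 0)
  if (length(ratios) < 2L || ratios[1] != 0 || any(diff(ratios) <= 0)) {
    abort("`ratios` must be strictly increasing with first element 0.")
  }
  residues <- as.integer(residues)
  cspmax <- rep_len(as.numeric(cspmax), length(residues))
  if (any(cspmax < 0)) abort("`cspmax` must be >= 0.")
  if (is.null(direction_angle)) {
    direction_angle <- with_seed(seed + 1000L,
                                 runif(length(residues), 1e-3, pi / 2 - 1e-3))
  }
  direction_angle <- rep_len(direction_angle, length(residues))
  structure(list(true_kd = true_kd, n_sites = n_sites, c_pro = c_pro,
                 c_lig = c_lig, ratios = as.numeric(ratios),
                 residues = residues, cspmax = cspmax,
                 direction_angle = direction_angle,
                 noise_sd_h = noise_sd_h, noise_sd_n = noise_sd_n,
                 seed = as.integer(seed)),
            class = "titration_sim_spec")
}

#' Simulate a fast-exchange CSP titration series
#'
#' Forward model of the n-equivalent-sites isotherm: apo peak positions
#' are drawn from plausible amide ranges (1H 6-10 ppm, 15N 105-130 ppm;
#' the values are irrelevant downstream because CSPs are referenced to the
#' apo point), each non-apo point moves every residue's peak along its
#' direction angle by the model CSP, and Gaussian noise is added per
#' nucleus to the non-apo points (the apo reference itself is exact, so a
#' zero-noise run reproduces [predict_csp()] exactly).
#'
#' @param spec A [titration_sim_spec()].
#' @return An `nmr_titration` (see [assemble_series()]).
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  nres <- length(spec$residues)
  with_seed(spec$seed, {
    apo_h <- runif(nres, 6, 10)
    apo_n <- runif(nres, 105, 130)
    tables <- lapply(spec$ratios, function(r) {
      csp <- predict_csp(r, kd = spec$true_kd, cspmax = 1,
                         n_sites = spec$n_sites,
                         c_pro = spec$c_pro, c_lig = spec$c_lig) * spec$cspmax
      dh <- csp * cos(spec$direction_angle)
      dn <- 5 * csp * sin(spec$direction_angle)
      if (r > 0) {
        dh <- dh + rnorm(nres, sd = spec$noise_sd_h)
        dn <- dn + rnorm(nres, sd = spec$noise_sd_n)
      }
      new_peak_table(spec$residues, "A", apo_h + dh, apo_n + dn)
    })
    suppressWarnings(
      assemble_series(tables, spec$ratios, c_pro = spec$c_pro,
                      c_lig = spec$c_lig, protein_id = "simulated",
                      ligand_id = "simulated")
    )
  })
}

#' Specification and simulation of apo/holo intensity profiles
#'
#' Emulates the exchange-broadening signature of a disordered segment that
#' rigidifies on ligand binding: the bound-state peak height is the apo
#' height times a per-residue enhancement factor. Noise is multiplicative
#' mean-one lognormal (peak heights are positive and scale-dependent),
#' applied independently to the apo and holo measurements.
#'
#' @param residues Integer residue numbers.
#' @param base_intensity Apo peak heights (> 0, recycled).
#' @param enhancement_factor Per-residue holo/apo factor (>= 0, recycled).
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param seed Integer seed.
#' @return `intensity_sim_spec()`: a spec list. `simulate_intensities()`:
#'   a tibble with `residue_number`, `intensity_apo`, `intensity_holo` and
#'   the designed `factor_true`.
#' @export
intensity_sim_spec <- function(residues, base_intensity = 1e6,
                               enhancement_factor = 1, noise_cv = 0,
                               seed = 1L) {
  residues <- as.integer(residues)
  base_intensity <- rep_len(as.numeric(base_intensity), length(residues))
  enhancement_factor <- rep_len(as.numeric(enhancement_factor),
                                length(residues))
  if (any(base_intensity <= 0)) abort("`base_intensity` must be > 0.")
  if (any(enhancement_factor < 0)) abort("`enhancement_factor` must be >= 0.")
  check_number(noise_cv, "noise_cv", lower = 0)
  structure(list(residues = residues, base_intensity = base_intensity,
                 enhancement_factor = enhancement_factor,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "intensity_sim_spec")
}

#' @rdname intensity_sim_spec
#' @param spec An `intensity_sim_spec`.
#' @export
simulate_intensities <- function(spec) {
  stopifnot(inherits(spec, "intensity_sim_spec"))
  nres <- length(spec$residues)
  sdlog <- sqrt(log1p(spec$noise_cv^2))
  with_seed(spec$seed, {
    noise <- function() exp(rnorm(nres, mean = -sdlog^2 / 2, sd = sdlog))
    tibble::tibble(
      residue_number = spec$residues,
      intensity_apo = spec$base_intensity * noise(),
      intensity_holo = spec$base_intensity * spec$enhancement_factor * noise(),
      factor_true = spec$enhancement_factor
    )
  })
}

#' Specification of a toy multi-model coordinate ensemble
#'
#' Ground-truth generator for the ensemble metrics: starting from a single
#' template conformer, each model adds (i) i.i.d. isotropic Gaussian
#' displacement per atom, with a region-dependent SD (disordered regions
#' get large SDs), (ii) optionally a per-model rigid translation of a
#' whole region (emulating inter-domain mobility of internally
#' well-ordered domains), and (iii) optionally constructed salt-bridge
#' contacts: for each bridge the acceptor atom is repositioned along the
#' axis to its nearest donor atom so the pair distance equals
#' `target + N(0, jitter_sd)`, truncated below at 1.5 Angstrom (a physical
#' contact limit).
#'
#' @param template Atom table (one conformer) with columns
#'   `atom_name`, `residue_name`, `residue_number`, `chain`, `x`, `y`, `z`.
#' @param n_models Number of conformers (>= 2).
#' @param regions A [region_set()] giving labelled residue ranges.
#' @param displacement_sd Named numeric: per-region atomic displacement SD
#'   (Angstrom); regions not named get 0.
#' @param rigid_sd Optional named numeric: per-region rigid-translation SD.
#' @param salt_bridges Optional list of bridges, each a list with
#'   `donor_residue`, `donor_atoms`, `acceptor_residue`, `acceptor_atoms`,
#'   `target` (Angstrom), `jitter_sd` (Angstrom).
#' @param seed Integer seed.
#' @return An `ensemble_sim_spec` list.
#' @export
ensemble_sim_spec <- function(template, n_models, regions,
                              displacement_sd = numeric(),
                              rigid_sd = numeric(),
                              salt_bridges = list(), seed = 1L) {
  template <- tibble::as_tibble(template)
  if (nrow(template) == 0L) abort("`template` must be non-empty.")
  if (n_models < 2L) abort("`n_models` must be >= 2.")
  if (any(displacement_sd < 0) || any(rigid_sd < 0)) {
    abort("Displacement SDs must be >= 0.")
  }
  known <- unique(regions$region)
  missing <- setdiff(c(names(displacement_sd), names(rigid_sd)), known)
  if (length(missing) > 0L) {
    abort(sprintf("Region label(s) not in `regions`: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(list(template = template, n_models = as.integer(n_models),
                 regions = regions, displacement_sd = displacement_sd,
                 rigid_sd = rigid_sd, salt_bridges = salt_bridges,
                 seed = as.integer(seed)),
            class = "ensemble_sim_spec")
}

region_rows <- function(template, regions, label) {
  rr <- regions[regions$region == label, , drop = FALSE]
  keep <- rep(FALSE, nrow(template))
  for (i in seq_len(nrow(rr))) {
    keep <- keep | (template$residue_number >= rr$start[i] &
                      template$residue_number <= rr$end[i])
  }
  which(keep)
}

#' @rdname ensemble_sim_spec
#' @param spec An `ensemble_sim_spec`.
#' @export
make_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_sim_spec"))
  tmpl <- spec$template
  nat <- nrow(tmpl)
  with_seed(spec$seed, {
    models <- lapply(seq_len(spec$n_models), function(m) {
      xyz <- cbind(tmpl$x, tmpl$y, tmpl$z)
      for (lab in names(spec$displacement_sd)) {
        sdv <- spec$displacement_sd[[lab]]
        idx <- region_rows(tmpl, spec$regions, lab)
        if (sdv > 0 && length(idx) > 0) {
          xyz[idx, ] <- xyz[idx, ] + matrix(rnorm(3 * length(idx), sd = sdv),
                                            ncol = 3)
        }
      }
      for (lab in names(spec$rigid_sd)) {
        sdv <- spec$rigid_sd[[lab]]
        idx <- region_rows(tmpl, spec$regions, lab)
        if (sdv > 0 && length(idx) > 0) {
          shift <- rnorm(3, sd = sdv)
          xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, `+`)
        }
      }
      for (sb in spec$salt_bridges) {
        don <- which(tmpl$residue_number == sb$donor_residue &
                       tmpl$atom_name %in% sb$donor_atoms)
        acc <- which(tmpl$residue_number == sb$acceptor_residue &
                       tmpl$atom_name %in% sb$acceptor_atoms)
        if (length(don) == 0L || length(acc) == 0L) {
          abort("Salt-bridge atoms absent from template.")
        }
        d <- as.matrix(stats::dist(rbind(xyz[don, , drop = FALSE],
                                         xyz[acc, , drop = FALSE])))
        dd <- d[seq_along(don), length(don) + seq_along(acc), drop = FALSE]
        hit <- which(dd == min(dd), arr.ind = TRUE)[1, ]
        di <- don[hit[1]]; ai <- acc[hit[2]]
        target <- max(1.5, sb$target + rnorm(1, sd = sb$jitter_sd))
        u <- xyz[ai, ] - xyz[di, ]
        u <- u / sqrt(sum(u^2))
        xyz[ai, ] <- xyz[di, ] + target * u
      }
      dplyr::mutate(tmpl, model = m, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    .before = 1)
    })
    ens <- dplyr::bind_rows(models)
    ens <- dplyr::relocate(ens, "model")
    new_atom_ensemble(ens)
  })
}

#' Specification and simulation of a protein alignment on a known tree
#'
#' Sequences evolve site-independently down a rooted binary tree under a
#' Jukes-Cantor-style uniform replacement model over the 20 amino acids:
#' along a branch of length `t` substitutions/site, a site changes with
#' probability `(19/20) * (1 - exp(-20/19 * t))`, to a uniformly chosen
#' different residue. No indels, so the result is already aligned.
#'
#' @param tree An `ape::phylo` tree with branch lengths (substitutions per
#'   site, >= 0). An unrooted tree is accepted and midpoint-handled by
#'   rooting at its first internal node.
#' @param seq_length Number of sites (> 0).
#' @param seed Integer seed.
#' @return `alignment_sim_spec()`: a spec list. `simulate_alignment()`: a
#'   named character vector of aligned sequences (one per tip).
#' @export
alignment_sim_spec <- function(tree, seq_length, seed = 1L) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo tree.")
  if (length(tree$tip.label) < 2L) abort("Tree must have >= 2 tips.")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    abort("Tree must have finite non-negative branch lengths.")
  }
  check_number(seq_length, "seq_length", lower = 1)
  structure(list(tree = tree, seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "alignment_sim_spec")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","S","T","W","Y","V","P")

#' @rdname alignment_sim_spec
#' @param spec An `alignment_sim_spec`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_sim_spec"))
  tree <- spec$tree
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, node = length(tree$tip.label) + 1L,
                      resolve.root = TRUE)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- spec$seq_length
  with_seed(spec$seed, {
    seqs <- vector("list", ntip + nnode)
    root <- ntip + 1L
    seqs[[root]] <- sample(AA20, L, replace = TRUE)
    # pre-order: parents before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t <- ord$edge.length[e]
      p_sub <- (19 / 20) * (1 - exp(-20 / 19 * t))
      s <- seqs[[par]]
      hit <- runif(L) < p_sub
      if (any(hit)) {
        # uniform among the 19 other residues
        cur <- s[hit]
        new <- vapply(cur, function(a) sample(setdiff(AA20, a), 1L),
                      character(1))
        s[hit] <- new
      }
      seqs[[child]] <- s
    }
    out <- vapply(seqs[seq_len(ntip)], paste, character(1), collapse = "")
    names(out) <- tree$tip.label
    out
  })
}

#' DNA duplexes used as titration ligands
#'
#' Metadata table for the five double-stranded DNA ligands referenced by
#' the packaged fixtures: an 18-bp and a 12-bp mixed-sequence duplex
#' (dsDNA1, dsDNA2), an A-tract duplex, an AT-rich duplex and a GC-rich
#' duplex. `forward` is the 5'->3' top strand; `backward` is the bottom
#' strand written 3'->5' (i.e. aligned under the top strand).
#'
#' @return A tibble with columns `id`, `length_bp`, `forward`, `backward`.
#' @export
dna_duplexes <- function() {
  tibble::tribble(
    ~id, ~length_bp, ~forward, ~backward,
    "dsDNA1", 18L, "CTCAGGTCAAAGGTCACG", "AGTCCAGTTTCCAGTGCT",
    "dsDNA2", 12L, "CTGTCAAAGGTG", "ACAGTTTCCACT",
    "dsA-tract", 18L, "CGCTTTAAAAAATTTCGG", "GCGAAATTTTTTAAAGCC",
    "dsAT18", 18L, "CGCAATTATATATTACGG", "GCGTTAATATATAATGCC",
    "dsGC18", 18L, "CGCACCGATCCGTGACGG", "GCGTGGCTAGGCACTGCC"
  )
}

#' Packaged synthetic fixture: a 151-residue DNA-binding titration
#'
#' A fully synthetic but realistically structured test case emulating an
#' extended double-Tudor construct of 151 residues titrated with an 18-bp
#' DNA duplex: true K_D 22 uM with n = 3 equivalent sites, protein 100 uM,
#' ligand stock 5000 uM, ratios up to 1.6. A designed binding hotspot
#' (residues 18-22, 88-91 and 99-105) carries large saturation CSPs, the
#' rest of the folded core small ones, and the disordered C-terminal tail
#' almost none. Peak intensities are attached to the apo and final points
#' with designed enhancement factors: > 3 for the RGR-motif residues
#' 138-146, between 1.5 and 3 for the disordered linker 110-136, ~1
#' elsewhere. Prolines (residues 13, 46, 62, 120) are flagged and carry no
#' amide data.
#'
#' @param seed Integer seed (default 1).
#' @param noise_sd_h,noise_sd_n Shift noise SDs (ppm); defaults 0.002 and
#'   0.01 (small spectral noise).
#' @param noise_cv Intensity noise CV; default 0.05.
#' @return A list with `series` (an `nmr_titration` with intensities at
#'   r = 0 and r = 1.6) and `truth` (list of the designed parameters:
#'   `kd`, `n_sites`, `hotspot`, `rgr_residues`, `linker_residues`,
#'   `prolines`, `cspmax`, `enhancement_factor`).
#' @export
td151_fixture <- function(seed = 1L, noise_sd_h = 0.002, noise_sd_n = 0.01,
                          noise_cv = 0.05) {
  residues <- 1:151
  prolines <- c(13L, 46L, 62L, 120L)
  hotspot <- c(18:22, 88:91, 99:105)
  rgr <- 138:146
  linker <- 110:136
  cspmax <- rep(0.03, 151)
  cspmax[hotspot] <- 0.25
  cspmax[c(linker, rgr, 147:151)] <- 0.005
  factor <- rep(1, 151)
  factor[linker] <- 2.2
  factor[rgr] <- 4
  ratios <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.6)

  tspec <- titration_sim_spec(true_kd = 22, n_sites = 3, c_pro = 100,
                              c_lig = 5000, ratios = ratios,
                              residues = residues, cspmax = cspmax,
                              noise_sd_h = noise_sd_h,
                              noise_sd_n = noise_sd_n, seed = seed)
  series <- simulate_titration(tspec)
  series$protein_id <- "TD151-like synthetic construct"
  series$ligand_id <- sprintf("dsDNA1 (%s)",
                              dna_duplexes()$forward[1])
  # flag prolines (no backbone amide)
  pk <- series$peaks
  is_pro <- pk$residue_number %in% prolines
  pk$residue_type[is_pro] <- "P"
  pk$flags[is_pro] <- "proline"
  pk$shift_h[is_pro] <- NA_real_
  pk$shift_n[is_pro] <- NA_real_
  # attach intensities at apo and final point
  ispec <- intensity_sim_spec(residues, base_intensity = 1e6,
                              enhancement_factor = factor,
                              noise_cv = noise_cv, seed = seed + 7L)
  ints <- simulate_intensities(ispec)
  pk$intensity[pk$ratio == 0] <-
    ints$intensity_apo[match(pk$residue_number[pk$ratio == 0],
                             ints$residue_number)]
  pk$intensity[pk$ratio == 1.6] <-
    ints$intensity_holo[match(pk$residue_number[pk$ratio == 1.6],
                              ints$residue_number)]
  pk$intensity[is_pro] <- NA_real_
  series$peaks <- pk
  list(series = series,
       truth = list(kd = 22, n_sites = 3, hotspot = hotspot,
                    rgr_residues = rgr, linker_residues = linker,
                    prolines = prolines, cspmax = cspmax,
                    enhancement_factor = factor))
}
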