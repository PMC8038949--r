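test_that("titration generators are seed-deterministic", {
  spec <- titration_sim_spec(true_kd = 22, n_sites = 3,
                             ratios = c(0, 0.5, 1, 1.6), residues = 1:5,
                             cspmax = 0.2, noise_sd_h = 0.005,
                             noise_sd_n = 0.025, seed = 7)
  s1 <- simulate_titration(spec)
  s2 <- simulate_titration(spec)
  expect_identical(s1$peaks, s2$peaks)
  spec2 <- titration_sim_spec(true_kd = 22, n_sites = 3,
                              ratios = c(0, 0.5, 1, 1.6), residues = 1:5,
                              cspmax = 0.2, noise_sd_h = 0.005,
                              noise_sd_n = 0.025, seed = 8)
  s3 <- simulate_titration(spec2)
  expect_false(identical(s1$peaks$shift_h, s3$peaks$shift_h))
})

test_that("spec validation rejects malformed titration designs", {
  expect_error(titration_sim_spec(22, 3, ratios = c(0.1, 0.5),
                                  residues = 1:2, cspmax = 0.1),
               "first element 0")
  expect_error(titration_sim_spec(22, 3, ratios = c(0, 0.5, 0.5),
                                  residues = 1:2, cspmax = 0.1),
               "strictly increasing")
  expect_error(titration_sim_spec(22, 3, c_pro = -1, ratios = c(0, 1),
                                  residues = 1:2, cspmax = 0.1),
               "range")
})

test_that("shift noise is calibrated to the stated normal model", {
  # 1000 i.i.d. draws of the same titration point
  spec <- titration_sim_spec(true_kd = 22, n_sites = 3, ratios = c(0, 1),
                             residues = 1:1000, cspmax = 0,
                             noise_sd_h = 0.005, noise_sd_n = 0.025,
                             seed = 99)
  prof <- csp_profile(simulate_titration(spec))
  dh <- prof$delta_h[prof$ratio == 1]
  dn <- prof$delta_n[prof$ratio == 1]
  expect_lt(abs(sd(dh) - 0.005) / 0.005, 0.10)
  expect_lt(abs(sd(dn) - 0.025) / 0.025, 0.10)
  expect_lt(abs(mean(dh)), 3 * 0.005 / sqrt(1000))
})

test_that("intensity simulation reproduces designed enhancement exactly when noiseless", {
  spec <- intensity_sim_spec(1:4, base_intensity = 1e6,
                             enhancement_factor = c(4, 1, 1, 2),
                             noise_cv = 0, seed = 1)
  sim <- simulate_intensities(spec)
  expect_equal(sim$intensity_holo / sim$intensity_apo, c(4, 1, 1, 2))
  prof <- tibble::tibble(residue_number = sim$residue_number,
                         ratio = sim$intensity_holo / sim$intensity_apo)
  cls <- classify_enhancement(prof)
  expect_identical(as.character(cls$enhancement_class),
                   c("strong", "none", "none", "moderate"))
})

test_that("lognormal intensity noise has the designed mean ratio", {
  spec <- intensity_sim_spec(1:500, base_intensity = 1e6,
                             enhancement_factor = 2, noise_cv = 0.05,
                             seed = 12)
  sim <- simulate_intensities(spec)
  ratio <- sim$intensity_holo / sim$intensity_apo
  expect_lt(abs(mean(ratio) - 2) / 2, 0.03)
  expect_error(intensity_sim_spec(1:2, base_intensity = 0), "> 0")
})

test_that("toy ensembles realise designed displacement and contacts", {
  tmpl <- toy_backbone_template(30)
  regions <- region_set(all = c(1, 30))
  # zero displacement -> identical conformers
  spec0 <- ensemble_sim_spec(tmpl, n_models = 5, regions = regions,
                             displacement_sd = c(all = 0), seed = 2)
  ens0 <- make_toy_ensemble(spec0)
  r0 <- rmsd_to_mean(ens0, regions, "all")
  expect_equal(r0$rmsd, rep(0, 5), tolerance = 1e-12)

  # displacement on one region matches the isotropic closed form
  tmpl2 <- toy_backbone_template(40)
  reg2 <- region_set(core = c(1, 25), mobile = c(26, 40))
  spec2 <- ensemble_sim_spec(tmpl2, n_models = 20, regions = reg2,
                             displacement_sd = c(mobile = 0.5), seed = 3)
  ens2 <- make_toy_ensemble(spec2)
  r2 <- rmsd_to_mean(ens2, reg2, "mobile")
  expected <- 0.5 * sqrt(3 * (1 - 1 / 20))
  expect_lt(abs(attr(r2, "mean") - expected) / expected, 0.15)

  # constructed salt bridge with zero jitter is exact
  sc <- tibble::tibble(residue_number = c(5L, 9L),
                       atom_name = c("OE1", "NZ"),
                       residue_name = c("GLU", "LYS"),
                       dx = c(2, 4), dy = c(0, 1), dz = c(0, 0.5))
  tmpl3 <- toy_backbone_template(10, side_chain_atoms = sc)
  spec3 <- ensemble_sim_spec(
    tmpl3, n_models = 4, regions = region_set(all = c(1, 10)),
    salt_bridges = list(list(donor_residue = 5L, donor_atoms = "OE1",
                             acceptor_residue = 9L, acceptor_atoms = "NZ",
                             target = 3.4, jitter_sd = 0)),
    seed = 4)
  ens3 <- make_toy_ensemble(spec3)
  sb <- salt_bridge_stats(ens3, list(residue = 5L, atoms = "OE1"),
                          list(residue = 9L, atoms = "NZ"))
  expect_equal(sb$distance, rep(3.4, 4), tolerance = 1e-9)
  expect_equal(attr(sb, "sd"), 0, tolerance = 1e-9)
  expect_true(all(sb$satisfied))

  expect_error(
    ensemble_sim_spec(tmpl, n_models = 3, regions = regions,
                      displacement_sd = c(nope = 1)),
    "not in")
})

test_that("alignment simulation evolves sequences down the tree", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln0 <- simulate_alignment(alignment_sim_spec(tr, 100, seed = 5))
  expect_identical(length(unique(unname(aln0))), 1L)
  expect_true(all(p_distance(aln0) == 0))

  tr2 <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
  a1 <- simulate_alignment(alignment_sim_spec(tr2, 300, seed = 6))
  a2 <- simulate_alignment(alignment_sim_spec(tr2, 300, seed = 6))
  expect_identical(a1, a2)
  expect_false(identical(
    a1, simulate_alignment(alignment_sim_spec(tr2, 300, seed = 7))))
  # close pairs are more similar than distant pairs
  dm <- p_distance(a1)
  expect_lt(dm["A", "B"], dm["A", "C"])
})

test_that("NJ on simulated alignments recovers the generating topology", {
  tr <- ape::read.tree(text = "((A:0.08,B:0.08):0.1,(C:0.08,D:0.08):0.1);")
  hits <- vapply(1:40, function(s) {
    aln <- simulate_alignment(alignment_sim_spec(tr, 10000, seed = 100 + s))
    nj <- neighbor_joining(p_distance(aln))
    phangorn::RF.dist(ape::unroot(tr), nj) == 0
  }, logical(1))
  expect_gte(sum(hits), ceiling(0.95 * 40))
})

test_that("simulated series round-trip through the package writers", {
  fx <- td151_fixture()
  d <- withr::local_tempdir()
  write_titration_series(fx$series, d)
  expect_equal(read_titration_series(d)$peaks, fx$series$peaks,
               ignore_attr = TRUE)
  ens <- synthetic_td151_ensemble(n_models = 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  back <- read_pdb_ensemble(f)
  expect_identical(nrow(back), nrow(ens))
  expect_lt(max(abs(back$x - ens$x), abs(back$y - ens$y),
                abs(back$z - ens$z)), 5.01e-4)
  aln <- simulate_alignment(alignment_sim_spec(
    ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);"),
    120, seed = 8))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, f2)
  expect_identical(read_fasta(f2), aln)
})

test_that("the packaged TD151-like fixture carries its designed truth", {
  fx <- td151_fixture()
  expect_identical(fx$truth$kd, 22)
  expect_identical(fx$truth$n_sites, 3)
  expect_match(fx$series$ligand_id, "CTCAGGTCAAAGGTCACG")
  pk <- fx$series$peaks
  expect_true(all(pk$flags[pk$residue_number %in% fx$truth$prolines] ==
                    "proline"))
  expect_identical(max(pk$ratio), 1.6)
  expect_true(all(is.finite(pk$intensity[pk$ratio == 1.6 &
                                           !pk$residue_number %in%
                                           fx$truth$prolines])))
  dup <- dna_duplexes()
  expect_identical(nrow(dup), 5L)
  expect_identical(nchar(dup$forward), as.integer(dup$length_bp))
  expect_identical(nchar(dup$backward), as.integer(dup$length_bp))
})
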