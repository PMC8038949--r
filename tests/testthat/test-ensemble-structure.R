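make_pdb_lines <- function(models) {
  # models: list of data frames with atom_name, residue_number, x, y, z
  out <- character()
  for (m in seq_along(models)) {
    df <- models[[m]]
    out <- c(out, sprintf("MODEL     %4d", m))
    nm <- ifelse(nchar(df$atom_name) < 4, sprintf(" %-3s", df$atom_name),
                 df$atom_name)
    occ <- if ("occupancy" %in% names(df)) df$occupancy else 1
    alt <- if ("alt_loc" %in% names(df)) df$alt_loc else ""
    out <- c(out, sprintf(
      "ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(df)), nm, alt, "ALA", df$residue_number,
      df$x, df$y, df$z, occ, 0))
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

test_that("multi-model PDB files split into conformers", {
  df <- tibble::tibble(atom_name = c("N", "CA", "C"),
                       residue_number = 1L, x = 1:3, y = 0, z = 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(df, df, df)), f)
  ens <- read_pdb_ensemble(f)
  expect_identical(sort(unique(ens$model)), 1:3)
  expect_identical(nrow(ens), 9L)

  # a single structure without MODEL records
  f2 <- withr::local_tempfile(fileext = ".pdb")
  lines <- make_pdb_lines(list(df))
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], f2)
  ens2 <- read_pdb_ensemble(f2)
  expect_identical(unique(ens2$model), 1L)
  r <- rmsd_to_mean(ens2, selection = NULL)
  expect_identical(r$rmsd, 0)
})

test_that("altlocs resolve by occupancy then first, and atom sets intersect", {
  df <- tibble::tibble(atom_name = c("N", "CA", "CA", "C"),
                       residue_number = 1L,
                       x = c(0, 1, 5, 2), y = 0, z = 0,
                       occupancy = c(1, 0.4, 0.6, 1),
                       alt_loc = c("", "A", "B", ""))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(df)), f)
  ens <- read_pdb_ensemble(f)
  expect_identical(nrow(ens), 3L)
  expect_equal(ens$x[ens$atom_name == "CA"], 5)  # higher occupancy B wins

  dfa <- tibble::tibble(atom_name = c("N", "CA", "C"),
                        residue_number = 1L, x = 1:3, y = 0, z = 0)
  dfb <- dfa[1:2, ]
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(dfa, dfb)), f2)
  expect_warning(ens2 <- read_pdb_ensemble(f2), "intersection")
  expect_identical(sort(unique(ens2$atom_name[ens2$model == 1])),
                   c("CA", "N"))
})

test_that("the in-package reader agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  ens <- synthetic_td151_ensemble(n_models = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  ours <- read_pdb_ensemble(f)
  theirs <- suppressWarnings(bio3d::read.pdb(f, multi = TRUE))
  xyz1 <- matrix(theirs$xyz[1, ], ncol = 3, byrow = TRUE)
  ours1 <- ours[ours$model == 1, ]
  expect_equal(cbind(ours1$x, ours1$y, ours1$z), xyz1,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("kabsch_superpose recovers known rigid transforms", {
  set.seed(17)
  pts <- matrix(rnorm(30), ncol = 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_lt(same$rmsd, 1e-12)

  th <- 30 * pi / 180
  rot_z <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, byrow = TRUE)
  moved <- sweep(pts %*% t(rot_z), 2, c(1, -2, 3), `+`)
  fit <- kabsch_superpose(moved, pts)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$transformed, pts, tolerance = 1e-8)

  # degenerate inputs are refused
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "Degenerate")
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "3 points")
})

test_that("kabsch fit beats random rotations and matches bio3d", {
  set.seed(23)
  for (i in 1:5) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- matrix(rnorm(30), ncol = 3)
    fit <- kabsch_superpose(a, b)
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    brute <- vapply(1:200, function(k) plain_rmsd(ac %*% random_rotation(), bc),
                    numeric(1))
    expect_true(all(fit$rmsd <= brute + 1e-12))
  }
  skip_if_not_installed("bio3d")
  a <- matrix(rnorm(30), ncol = 3)
  b <- a %*% random_rotation() + matrix(rnorm(30, sd = 0.1), ncol = 3)
  fit <- kabsch_superpose(b, a)
  bf <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(a)), mobile = as.numeric(t(b))))
  expect_equal(fit$rmsd, plain_rmsd(matrix(bf, ncol = 3, byrow = TRUE), a),
               tolerance = 1e-6)
})

test_that("rmsd_to_mean matches the two-conformer closed form", {
  # Two conformers differing by displacement d at a single atom placed at
  # the selection centroid (so the optimal rotation is exactly the
  # identity). With the optimal translation absorbing d/N, each
  # conformer's RMSD to the midpoint mean is (d/2) * sqrt((1 - 1/N) / N);
  # the textbook (d/2)/sqrt(N) value ignores the re-superposition and is
  # approached with relative error 1/(2N).
  tmpl <- toy_backbone_template(12)
  cen <- colMeans(as.matrix(tmpl[tmpl$atom_name %in% c("N", "CA", "C"),
                                 c("x", "y", "z")]))
  tmpl <- dplyr::bind_rows(tmpl, tibble::tibble(
    atom_name = "CA", residue_name = "GLY", residue_number = 13L,
    chain = "A", x = cen[1], y = cen[2], z = cen[3]))
  n_sel <- sum(tmpl$atom_name %in% c("N", "CA", "C"))
  d <- 0.8
  m2 <- tmpl
  k <- which(m2$residue_number == 13L)
  m2$z[k] <- m2$z[k] + d
  ens <- nmrbind:::new_atom_ensemble(dplyr::bind_rows(
    dplyr::mutate(tmpl, model = 1, .before = 1),
    dplyr::mutate(m2, model = 2, .before = 1)))
  r <- rmsd_to_mean(ens)
  exact <- (d / 2) * sqrt((1 - 1 / n_sel) / n_sel)
  expect_equal(r$rmsd, rep(exact, 2), tolerance = 1e-12)
  naive <- (d / 2) / sqrt(n_sel)
  expect_lt(abs(attr(r, "mean") - naive) / naive, 1 / n_sel)
  # the converged per-conformer RMSD is half the optimal pairwise RMSD
  a <- as.matrix(dplyr::filter(ens, model == 1,
                               atom_name %in% c("N", "CA", "C"))[, c("x", "y", "z")])
  b <- as.matrix(dplyr::filter(ens, model == 2,
                               atom_name %in% c("N", "CA", "C"))[, c("x", "y", "z")])
  expect_equal(r$rmsd[1], kabsch_superpose(b, a)$rmsd / 2, tolerance = 1e-12)
})

test_that("rmsd_to_mean is invariant to a global rigid transform", {
  ens <- synthetic_td151_ensemble(n_models = 6, seed = 31)
  reg <- htd_regions()
  base <- rmsd_to_mean(ens, reg, "htd1_ss")
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(ens[, c("x", "y", "z")]) %*% t(rot)
  moved <- dplyr::mutate(ens, x = xyz[, 1] + 11, y = xyz[, 2] - 4,
                         z = xyz[, 3] + 2)
  again <- rmsd_to_mean(moved, reg, "htd1_ss")
  expect_equal(again$rmsd, base$rmsd, tolerance = 1e-8)
})

test_that("expanding a rigid selection into a mobile region raises the RMSD", {
  ens <- synthetic_td151_ensemble(n_models = 10, seed = 41)
  reg <- htd_regions()
  r1 <- attr(rmsd_to_mean(ens, reg, "htd1_ss"), "mean")
  r2 <- attr(rmsd_to_mean(ens, reg, "htd2_ss"), "mean")
  rall <- attr(rmsd_to_mean(ens, reg, "all_ss"), "mean")
  expect_gt(rall, r1)
  expect_gt(rall, r2)
})

test_that("salt bridge statistics take pair minima and are symmetric", {
  sc <- tibble::tibble(residue_number = c(5L, 5L, 9L),
                       atom_name = c("OE1", "OE2", "NZ"),
                       residue_name = c("GLU", "GLU", "LYS"),
                       dx = c(2, 6, 4), dy = c(0, 0, 1), dz = c(0, 0, 0.5))
  tmpl <- toy_backbone_template(10, side_chain_atoms = sc)
  spec <- ensemble_sim_spec(
    tmpl, n_models = 3, regions = region_set(all = c(1, 10)),
    salt_bridges = list(list(donor_residue = 5L,
                             donor_atoms = c("OE1", "OE2"),
                             acceptor_residue = 9L, acceptor_atoms = "NZ",
                             target = 4.5, jitter_sd = 0)),
    seed = 51)
  ens <- make_toy_ensemble(spec)
  don <- list(residue = 5L, atoms = c("OE1", "OE2"))
  acc <- list(residue = 9L, atoms = "NZ")
  sb <- salt_bridge_stats(ens, don, acc, cutoff = 4.0)
  expect_equal(sb$distance, rep(4.5, 3), tolerance = 1e-9)
  expect_false(any(sb$satisfied))   # 4.5 > 4.0 cutoff
  swapped <- salt_bridge_stats(ens, acc, don, cutoff = 4.0)
  expect_equal(swapped$distance, sb$distance)
  expect_error(
    salt_bridge_stats(ens, list(residue = 5L, atoms = "OD1"), acc),
    "Missing atom")
})
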