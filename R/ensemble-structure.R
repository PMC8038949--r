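new_atom_ensemble <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("model", "atom_name", "residue_name", "residue_number",
            "chain", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(sprintf("Atom ensemble needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  tibble::new_tibble(df, class = "atom_ensemble")
}

#' Build a labelled residue-range set
#'
#' Regions are named lists of inclusive residue ranges used to restrict
#' ensemble metrics (and to drive the toy-ensemble generator). Ranges
#' within a label must not overlap.
#'
#' @param ... Named arguments; each is a numeric vector `c(start, end)` or
#'   a list of such vectors.
#' @return A tibble with columns `region`, `start`, `end`.
#' @examples
#' region_set(core = list(c(8, 34), c(87, 110)), tail = c(111, 151))
#' @export
region_set <- function(...) {
  args <- list(...)
  if (is.null(names(args)) || any(names(args) == "")) {
    abort("All regions must be named.")
  }
  rows <- purrr::imap(args, function(rr, nm) {
    if (is.numeric(rr)) rr <- list(rr)
    tb <- purrr::map_dfr(rr, function(v) {
      if (length(v) != 2L || v[1] > v[2]) {
        abort(sprintf("Region '%s': ranges must be c(start, end).", nm))
      }
      tibble::tibble(region = nm, start = as.integer(v[1]),
                     end = as.integer(v[2]))
    })
    o <- order(tb$start)
    if (any(tb$start[o][-1] <= tb$end[o][-nrow(tb)])) {
      abort(sprintf("Region '%s': overlapping ranges.", nm))
    }
    tb
  })
  dplyr::bind_rows(rows)
}

#' Double-Tudor region definitions for a 151-residue construct
#'
#' Residue ranges of the two hybrid Tudor subdomains (HTD-1 is formed by
#' the N- and C-terminal beta-strands, HTD-2 by the middle strands) and of
#' their regular secondary-structure elements, plus the disordered
#' N-terminal and C-terminal segments. These drive the region-restricted
#' ensemble metrics and the synthetic ensemble generator.
#'
#' @return A [region_set()] tibble with labels `htd1`, `htd2`, `htd1_ss`,
#'   `htd2_ss`, `all_ss`, `nterm`, `tail`.
#' @export
htd_regions <- function() {
  region_set(
    htd1 = list(c(8, 34), c(87, 110)),
    htd2 = c(35, 86),
    htd1_ss = list(c(15, 20), c(23, 33), c(88, 92), c(98, 108)),
    htd2_ss = list(c(36, 42), c(48, 57), c(65, 69), c(75, 85)),
    all_ss = list(c(15, 20), c(23, 33), c(36, 42), c(48, 57),
                  c(65, 69), c(75, 85), c(88, 92), c(98, 108)),
    nterm = c(1, 7),
    tail = c(111, 151)
  )
}

parse_pdb_atom <- function(line) {
  # fixed-column PDB ATOM/HETATM record
  list(
    serial = suppressWarnings(as.integer(substr(line, 7, 11))),
    atom_name = trimws(substr(line, 13, 16)),
    alt_loc = trimws(substr(line, 17, 17)),
    residue_name = trimws(substr(line, 18, 20)),
    chain = trimws(substr(line, 22, 22)),
    residue_number = suppressWarnings(as.integer(substr(line, 23, 26))),
    x = suppressWarnings(as.numeric(substr(line, 31, 38))),
    y = suppressWarnings(as.numeric(substr(line, 39, 46))),
    z = suppressWarnings(as.numeric(substr(line, 47, 54))),
    occupancy = suppressWarnings(as.numeric(substr(line, 55, 60)))
  )
}

#' Read a multi-model PDB file as a tidy atom ensemble
#'
#' Conformers are split on MODEL/ENDMDL records (a file without MODEL
#' records yields a single-model ensemble). Alternate locations are
#' resolved per atom by highest occupancy, then first occurrence.
#' Hydrogens are retained (default metric selections exclude them by
#' naming heavy atoms). If models do not share the same atom set, a
#' warning is issued and the intersection (on chain, residue and atom
#' name) is used.
#'
#' @param path PDB file.
#' @return An `atom_ensemble` tibble: `model`, `serial`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain`, `x`, `y`, `z`,
#'   `occupancy`.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_id <- cumsum(trimws(rec) == "MODEL")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort(sprintf("No ATOM records in %s", path))
  if (max(model_id) == 0L) model_id <- model_id + 1L
  at <- lines[is_atom]
  mid <- model_id[is_atom]
  fields <- lapply(at, parse_pdb_atom)
  df <- tibble::tibble(
    model = mid,
    serial = vapply(fields, `[[`, integer(1), "serial"),
    atom_name = vapply(fields, `[[`, character(1), "atom_name"),
    alt_loc = vapply(fields, `[[`, character(1), "alt_loc"),
    residue_name = vapply(fields, `[[`, character(1), "residue_name"),
    residue_number = vapply(fields, `[[`, integer(1), "residue_number"),
    chain = vapply(fields, `[[`, character(1), "chain"),
    x = vapply(fields, `[[`, numeric(1), "x"),
    y = vapply(fields, `[[`, numeric(1), "y"),
    z = vapply(fields, `[[`, numeric(1), "z"),
    occupancy = vapply(fields, `[[`, numeric(1), "occupancy")
  )
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort(sprintf("Malformed coordinates in %s", path))
  }
  # altloc: highest occupancy then first
  df$occupancy[is.na(df$occupancy)] <- 1
  df <- df |>
    dplyr::group_by(.data$model, .data$chain, .data$residue_number,
                    .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$model, .data$serial)
  # atom-set consistency across models
  df$key <- paste(df$chain, df$residue_number, df$atom_name, sep = "|")
  keys <- split(df$key, df$model)
  common <- Reduce(intersect, keys)
  if (any(vapply(keys, length, integer(1)) != length(common))) {
    warn("Models have inconsistent atom sets; using their intersection.")
    df <- dplyr::filter(df, .data$key %in% common)
  }
  df$key <- NULL
  df$alt_loc <- NULL
  new_atom_ensemble(df)
}

#' Write an atom ensemble as a multi-model PDB file
#'
#' Emits standard fixed-column ATOM records wrapped in MODEL/ENDMDL pairs.
#' Coordinates are written with 3 decimal places (the PDB convention), so
#' round-tripping through [read_pdb_ensemble()] reproduces coordinates to
#' 0.0005 Angstrom.
#'
#' @param ensemble An `atom_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in unique(ensemble$model)) {
    sub <- ensemble[ensemble$model == m, ]
    writeLines(sprintf("MODEL     %4d", m), con)
    nm <- ifelse(nchar(sub$atom_name) < 4L,
                 sprintf(" %-3s", sub$atom_name), sub$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(sub)), nm, sub$residue_name, sub$chain,
      sub$residue_number, sub$x, sub$y, sub$z, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

select_coords <- function(ensemble, regions = NULL, region = NULL,
                          selection = c("N", "CA", "C")) {
  df <- ensemble
  if (!is.null(selection)) {
    df <- dplyr::filter(df, .data$atom_name %in% selection)
  }
  if (!is.null(region)) {
    if (is.null(regions)) abort("`region` given without `regions`.")
    rr <- regions[regions$region == region, , drop = FALSE]
    if (nrow(rr) == 0L) abort(sprintf("Unknown region label '%s'.", region))
    keep <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(rr))) {
      keep <- keep | (df$residue_number >= rr$start[i] &
                        df$residue_number <= rr$end[i])
    }
    df <- df[keep, ]
  }
  if (nrow(df) == 0L) abort("Empty atom selection.")
  models <- sort(unique(ensemble$model))
  key0 <- NULL
  coords <- lapply(models, function(m) {
    sub <- df[df$model == m, ]
    sub <- dplyr::arrange(sub, .data$chain, .data$residue_number,
                          .data$atom_name)
    key <- paste(sub$chain, sub$residue_number, sub$atom_name)
    if (is.null(key0)) {
      key0 <<- key
    } else if (!identical(key, key0)) {
      abort("Selection atoms are not identical across models.")
    }
    cbind(sub$x, sub$y, sub$z)
  })
  list(coords = coords, models = models, key = key0)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired coordinate sets, via the SVD of the covariance matrix with a
#' determinant sign correction so no reflection is introduced.
#'
#' @param mobile,reference N x 3 coordinate matrices (N >= 3,
#'   non-collinear).
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length
#'   3), `rmsd`, and `transformed` (`mobile %*% rotation + translation`,
#'   the least-squares fit onto `reference`).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    abort("`mobile` and `reference` must be equal-size N x 3 matrices.")
  }
  if (nrow(mobile) < 3L) abort("Need at least 3 points.")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  a <- sweep(mobile, 2, mc); b <- sweep(reference, 2, rc)
  h <- crossprod(a, b)
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    abort("Degenerate (collinear or coincident) point set.")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- rc - as.numeric(mc %*% rot)
  fitted <- sweep(mobile %*% rot, 2, trans, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transformed = fitted)
}

#' RMSD of each conformer to the converged mean structure
#'
#' The standard NMR-ensemble precision metric: all conformers are
#' superposed on the first conformer over the selection, the coordinate
#' mean is computed, all conformers are re-superposed on that mean and the
#' mean recomputed, iterating until the mean moves by less than `tol`
#' (max 100 iterations). Each conformer's RMSD to the converged mean is
#' reported along with the ensemble mean and SD.
#'
#' @param ensemble An `atom_ensemble`.
#' @param regions Optional [region_set()]; with `region`, restricts the
#'   selection to those residue ranges.
#' @param region Region label in `regions`.
#' @param selection Atom names to use; default backbone `N, CA, C` (set
#'   `c("N","CA","C","O")` to include the carbonyl oxygen, or `NULL` for
#'   all atoms).
#' @param tol Convergence tolerance on the mean coordinates (Angstrom).
#' @param max_iter Iteration cap.
#' @return A tibble of class `ensemble_rmsd` (`model`, `rmsd`) with
#'   attributes `mean`, `sd`, `region`, `selection`, `n_atoms`, and the
#'   converged `mean_coords`.
#' @export
rmsd_to_mean <- function(ensemble, regions = NULL, region = NULL,
                         selection = c("N", "CA", "C"),
                         tol = 1e-6, max_iter = 100) {
  sel <- select_coords(ensemble, regions, region, selection)
  coords <- sel$coords
  if (length(coords) == 1L) {
    out <- tibble::new_tibble(
      tibble::tibble(model = sel$models, rmsd = 0),
      class = "ensemble_rmsd")
    attr(out, "mean") <- 0; attr(out, "sd") <- NA_real_
    attr(out, "region") <- region; attr(out, "selection") <- selection
    attr(out, "n_atoms") <- nrow(coords[[1]])
    return(out)
  }
  fitted <- lapply(coords, function(m) kabsch_superpose(m, coords[[1]])$transformed)
  mean_c <- Reduce(`+`, fitted) / length(fitted)
  for (it in seq_len(max_iter)) {
    fitted <- lapply(coords, function(m) kabsch_superpose(m, mean_c)$transformed)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- max(abs(new_mean - mean_c))
    mean_c <- new_mean
    if (shift < tol) break
  }
  rmsds <- vapply(fitted, function(f) sqrt(mean(rowSums((f - mean_c)^2))),
                  numeric(1))
  out <- tibble::new_tibble(
    tibble::tibble(model = sel$models, rmsd = rmsds),
    class = "ensemble_rmsd")
  attr(out, "mean") <- mean(rmsds)
  attr(out, "sd") <- sd(rmsds)
  attr(out, "region") <- region
  attr(out, "selection") <- selection
  attr(out, "n_atoms") <- nrow(mean_c)
  attr(out, "mean_coords") <- mean_c
  out
}

#' @export
print.ensemble_rmsd <- function(x, ...) {
  cat(sprintf("<ensemble_rmsd> %d conformers, %d atoms%s\n",
              nrow(x), attr(x, "n_atoms"),
              if (!is.null(attr(x, "region"))) {
                sprintf(", region '%s'", attr(x, "region"))
              } else ""))
  cat(sprintf("  RMSD to mean structure: %.2f +/- %.2f Angstrom\n",
              attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

#' Ensemble salt-bridge distance statistics
#'
#' For each conformer, the contact distance is the minimum over all
#' donor-atom x acceptor-atom pairs (e.g. min over Glu OE1/OE2 to Lys NZ),
#' so the chemically equivalent carboxylate oxygens are handled without
#' choosing one. The bridge is scored satisfied in a conformer when the
#' distance is at or below `cutoff` (default 4.0 Angstrom, the common
#' N-O salt-bridge criterion). The measure is symmetric in donor and
#' acceptor.
#'
#' @param ensemble An `atom_ensemble`.
#' @param donor,acceptor Lists `list(residue =, atoms =)` naming one
#'   residue number and its side-chain atom names.
#' @param cutoff Distance criterion (Angstrom).
#' @return A tibble of class `salt_bridge_stat` (`model`, `distance`,
#'   `satisfied`) with attributes `mean`, `sd`, `cutoff`, `donor`,
#'   `acceptor`.
#' @export
salt_bridge_stats <- function(ensemble, donor, acceptor, cutoff = 4.0) {
  get_xyz <- function(spec, m) {
    sub <- ensemble[ensemble$model == m &
                      ensemble$residue_number == spec$residue &
                      ensemble$atom_name %in% spec$atoms, ]
    if (nrow(sub) != length(spec$atoms)) {
      abort(sprintf("Missing atom(s) %s of residue %d in model %d.",
                    paste(setdiff(spec$atoms, sub$atom_name), collapse = ","),
                    spec$residue, m))
    }
    cbind(sub$x, sub$y, sub$z)
  }
  models <- sort(unique(ensemble$model))
  dists <- vapply(models, function(m) {
    dxyz <- get_xyz(donor, m); axyz <- get_xyz(acceptor, m)
    min(apply(dxyz, 1, function(p) {
      sqrt(rowSums(sweep(axyz, 2, p)^2))
    }))
  }, numeric(1))
  out <- tibble::new_tibble(
    tibble::tibble(model = models, distance = dists,
                   satisfied = dists <= cutoff),
    class = "salt_bridge_stat")
  attr(out, "mean") <- mean(dists)
  attr(out, "sd") <- sd(dists)
  attr(out, "cutoff") <- cutoff
  attr(out, "donor") <- donor
  attr(out, "acceptor") <- acceptor
  out
}

#' @export
print.salt_bridge_stat <- function(x, ...) {
  d <- attr(x, "donor"); a <- attr(x, "acceptor")
  cat(sprintf("<salt_bridge_stat> residue %d {%s} -- residue %d {%s}\n",
              d$residue, paste(d$atoms, collapse = ","),
              a$residue, paste(a$atoms, collapse = ",")))
  cat(sprintf("  distance %.2f +/- %.2f Angstrom; <= %.1f in %d/%d conformers\n",
              attr(x, "mean"), attr(x, "sd"), attr(x, "cutoff"),
              sum(x$satisfied), nrow(x)))
  invisible(x)
}

#' @describeIn rmsd_to_mean Per-conformer RMSD bar chart.
#' @param object An `ensemble_rmsd`.
#' @param ... Unused.
#' @export
autoplot.ensemble_rmsd <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$model), y = .data$rmsd)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = 2, colour = "red3") +
    ggplot2::labs(x = "conformer", y = "RMSD to mean (Angstrom)") +
    ggplot2::theme_minimal()
}
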