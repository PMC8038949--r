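PEAK_FLAGS <- c("proline", "unassigned", "overlapped")
PEAK_COLS <- c("residue_number", "residue_type", "shift_h_ppm",
               "shift_n_ppm", "intensity", "flags")

validate_flags <- function(flags) {
  flags[is.na(flags)] <- ""
  parts <- strsplit(flags, ";", fixed = TRUE)
  bad <- vapply(parts, function(p) any(!p %in% PEAK_FLAGS), logical(1))
  if (any(bad)) {
    abort(sprintf("Unknown flag value(s): %s (allowed: %s)",
                  paste(unique(unlist(parts[bad])), collapse = ", "),
                  paste(PEAK_FLAGS, collapse = ", ")))
  }
  flags
}

new_peak_table <- function(residue_number, residue_type, shift_h, shift_n,
                           intensity = NA_real_, flags = "") {
  tb <- tibble::tibble(
    residue_number = as.integer(residue_number),
    residue_type = as.character(residue_type),
    shift_h = as.numeric(shift_h),
    shift_n = as.numeric(shift_n),
    intensity = as.numeric(intensity),
    flags = validate_flags(as.character(flags))
  )
  if (anyNA(tb$residue_number) || any(tb$residue_number < 1L)) {
    abort("residue_number must be integers >= 1.")
  }
  dup <- tb$residue_number[duplicated(tb$residue_number)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate residue entries: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  unflagged <- tb$flags == ""
  if (any(unflagged & (!is.finite(tb$shift_h) | !is.finite(tb$shift_n)))) {
    abort("Non-finite shifts for unflagged residues.")
  }
  tb
}

#' Read an assigned 2D peak table
#'
#' Two dialects are supported. `"tsv"` is the package's own tab-separated
#' format with a mandatory header row and columns `residue_number`,
#' `residue_type`, `shift_h_ppm`, `shift_n_ppm`, `intensity`, `flags`
#' (semicolon-separated subset of proline/unassigned/overlapped; empty for
#' none). `"sparky"` parses Sparky-style `.list` files with lines such as
#' `G22N-H 109.10 8.31 5.0e5`: an assignment followed by w1 (15N ppm),
#' w2 (1H ppm) and an optional peak height -- note w1 is the nitrogen
#' dimension, so the two shift columns are swapped relative to the TSV
#' dialect.
#'
#' Residues typed `P`/`PRO` are automatically flagged `proline` (they have
#' no backbone amide). Unknown residue codes give a warning and an
#' `unassigned` flag. Duplicate residue numbers and malformed lines are
#' errors reported with line numbers.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"sparky"`.
#' @return A tibble with columns `residue_number`, `residue_type`,
#'   `shift_h`, `shift_n`, `intensity`, `flags`.
#' @export
read_peak_table <- function(path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (dialect == "tsv") {
    tb <- readr::read_tsv(path, col_types = readr::cols(
      residue_number = readr::col_integer(),
      residue_type = readr::col_character(),
      shift_h_ppm = readr::col_double(),
      shift_n_ppm = readr::col_double(),
      intensity = readr::col_double(),
      flags = readr::col_character()
    ), progress = FALSE)
    prob <- readr::problems(tb)
    if (nrow(prob) > 0L) {
      abort(sprintf("Malformed line(s) in %s: %s", path,
                    paste(sprintf("row %d (%s)", prob$row, prob$expected),
                          collapse = "; ")))
    }
    if (!all(PEAK_COLS %in% names(tb))) {
      abort(sprintf("Missing column(s): %s",
                    paste(setdiff(PEAK_COLS, names(tb)), collapse = ", ")))
    }
    if (nrow(tb) == 0L) abort(sprintf("No records in %s", path))
    out <- new_peak_table(tb$residue_number, tb$residue_type,
                          tb$shift_h_ppm, tb$shift_n_ppm,
                          tb$intensity, tb$flags)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    keep <- lines != "" & !grepl("^Assignment", lines, ignore.case = TRUE)
    lines <- lines[keep]
    lineno <- which(keep)
    if (length(lines) == 0L) abort(sprintf("No records in %s", path))
    m <- regexec("^([A-Za-z]{1,3})(\\d+)N-?H?\\s+(\\S+)\\s+(\\S+)(\\s+(\\S+))?",
                 lines)
    parts <- regmatches(lines, m)
    bad <- lengths(parts) == 0L
    if (any(bad)) {
      abort(sprintf("Malformed Sparky line(s) at: %s",
                    paste(lineno[bad], collapse = ", ")))
    }
    get <- function(i) vapply(parts, `[`, character(1), i)
    w1 <- suppressWarnings(as.numeric(get(4)))  # 15N
    w2 <- suppressWarnings(as.numeric(get(5)))  # 1H
    ht <- suppressWarnings(as.numeric(get(7)))
    if (anyNA(w1) || anyNA(w2)) {
      abort(sprintf("Non-numeric shifts at line(s): %s",
                    paste(lineno[is.na(w1) | is.na(w2)], collapse = ", ")))
    }
    out <- new_peak_table(as.integer(get(3)), get(2), w2, w1, ht)
  }
  # proline auto-flag and unknown-code warning
  one <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  three <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  ty <- toupper(out$residue_type)
  is_pro <- ty %in% c("P", "PRO")
  out$flags <- ifelse(is_pro & !grepl("proline", out$flags),
                      sub("^;", "", paste(out$flags, "proline", sep = ";")),
                      out$flags)
  out$flags <- sub("^;", "", out$flags)
  unknown <- !(ty %in% c(one, three))
  if (any(unknown)) {
    warn(sprintf("Unknown residue code(s): %s (flagged unassigned)",
                 paste(unique(out$residue_type[unknown]), collapse = ", ")))
    out$flags[unknown] <- sub("^;", "", paste(out$flags[unknown],
                                              "unassigned", sep = ";"))
  }
  out
}

#' Write a peak table in the package TSV dialect
#'
#' Inverse of [read_peak_table()] for the `"tsv"` dialect; the round trip
#' is lossless (doubles are written with shortest round-trip precision).
#'
#' @param peaks Peak table (as returned by [read_peak_table()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  out <- tibble::tibble(
    residue_number = peaks$residue_number,
    residue_type = peaks$residue_type,
    shift_h_ppm = peaks$shift_h,
    shift_n_ppm = peaks$shift_n,
    intensity = peaks$intensity,
    flags = peaks$flags
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble peak tables into a titration series
#'
#' Combines one peak table per titration point into a validated series.
#' Tables are reordered by ratio if needed (with a warning); the first
#' point must be the apo spectrum (`r = 0`). Residues present in the apo
#' table but missing at a later point are inserted there as placeholder
#' records flagged `overlapped` (masked at that point only, not dropped).
#' Residues absent from the apo table are dropped with a warning, since
#' CSPs are referenced to the apo positions.
#'
#' @param tables List of peak tables (see [read_peak_table()]).
#' @param ratios Numeric vector of ligand:protein molar ratios, same
#'   length as `tables`, strictly increasing once sorted, first element 0.
#' @param c_pro Initial protein concentration (uM).
#' @param c_lig Ligand stock concentration (uM).
#' @param protein_id,ligand_id Free-text identifiers.
#' @return An object of class `nmr_titration`: a list with the metadata
#'   and a long `peaks` tibble (one row per residue per point).
#' @export
assemble_series <- function(tables, ratios, c_pro, c_lig,
                            protein_id = "protein", ligand_id = "ligand") {
  if (!is.list(tables) || length(tables) != length(ratios)) {
    abort("`tables` must be a list with one peak table per ratio.")
  }
  if (length(tables) < 2L) abort("Need at least two titration points.")
  if (anyDuplicated(ratios)) abort("Ratios must be strictly increasing.")
  if (is.unsorted(ratios)) {
    warn("Tables given out of ratio order; reordering by ratio.")
    ord <- order(ratios)
    tables <- tables[ord]
    ratios <- ratios[ord]
  }
  if (ratios[1] != 0) abort("No apo point: the first ratio must be 0.")
  check_number(c_pro, "c_pro", lower = 0, allow_zero = FALSE)
  check_number(c_lig, "c_lig", lower = 0, allow_zero = FALSE)

  apo <- tables[[1]]
  apo_res <- apo$residue_number
  pts <- purrr::map2(tables, ratios, function(tb, r) {
    extra <- setdiff(tb$residue_number, apo_res)
    if (length(extra) > 0L) {
      warn(sprintf("Ratio %g: residue(s) %s absent from apo point; dropped.",
                   r, paste(extra, collapse = ", ")))
      tb <- dplyr::filter(tb, .data$residue_number %in% apo_res)
    }
    missing <- setdiff(apo_res, tb$residue_number)
    if (length(missing) > 0L) {
      filler <- tibble::tibble(
        residue_number = as.integer(missing),
        residue_type = apo$residue_type[match(missing, apo_res)],
        shift_h = NA_real_, shift_n = NA_real_, intensity = NA_real_,
        flags = "overlapped"
      )
      tb <- dplyr::bind_rows(tb, filler)
    }
    dplyr::mutate(dplyr::arrange(tb, .data$residue_number), ratio = r,
                  .before = 1)
  })
  peaks <- dplyr::bind_rows(pts)
  structure(list(protein_id = protein_id, ligand_id = ligand_id,
                 c_pro = c_pro, c_lig = c_lig, peaks = peaks),
            class = "nmr_titration")
}

#' @export
print.nmr_titration <- function(x, ...) {
  rts <- unique(x$peaks$ratio)
  cat(sprintf("<nmr_titration> %s + %s\n", x$protein_id, x$ligand_id))
  cat(sprintf("  c_pro = %g uM, c_lig = %g uM\n", x$c_pro, x$c_lig))
  cat(sprintf("  %d points (r = %s), %d residues\n", length(rts),
              paste(signif(rts, 3), collapse = ", "),
              length(unique(x$peaks$residue_number))))
  invisible(x)
}

#' Write / read a whole titration series as a directory of TSV files
#'
#' `write_titration_series()` writes `meta.tsv` (ids, concentrations,
#' ratios and point file names) plus one peak table per titration point in
#' the package TSV dialect; `read_titration_series()` reassembles the
#' series with [assemble_series()]. The round trip is lossless.
#'
#' @param series An `nmr_titration`.
#' @param dir Directory to write into (created if needed).
#' @return The directory (write) or an `nmr_titration` (read).
#' @export
write_titration_series <- function(series, dir) {
  stopifnot(inherits(series, "nmr_titration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rts <- unique(series$peaks$ratio)
  files <- sprintf("point_%02d.tsv", seq_along(rts))
  for (i in seq_along(rts)) {
    pk <- dplyr::filter(series$peaks, .data$ratio == rts[i])
    write_peak_table(pk, file.path(dir, files[i]))
  }
  meta <- tibble::tibble(
    key = c("protein_id", "ligand_id", "c_pro", "c_lig"),
    value = c(series$protein_id, series$ligand_id,
              format(series$c_pro, digits = 17),
              format(series$c_lig, digits = 17))
  )
  readr::write_tsv(meta, file.path(dir, "meta.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(ratio = rts, file = files),
                   file.path(dir, "points.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_titration_series
#' @export
read_titration_series <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "meta.tsv"),
                          col_types = "cc", progress = FALSE)
  kv <- setNames(meta$value, meta$key)
  pts <- readr::read_tsv(file.path(dir, "points.tsv"),
                         col_types = "dc", progress = FALSE)
  tables <- lapply(file.path(dir, pts$file), read_peak_table)
  assemble_series(tables, pts$ratio,
                  c_pro = as.numeric(kv[["c_pro"]]),
                  c_lig = as.numeric(kv[["c_lig"]]),
                  protein_id = kv[["protein_id"]],
                  ligand_id = kv[["ligand_id"]])
}
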