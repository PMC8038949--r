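#' Classify residues by CSP relative to mean and SD
#'
#' The standard chemical-shift mapping rule: over the valid (non-excluded)
#' residues at one titration point, compute the mean and standard
#' deviation of the CSPs; residues with `CSP >= mean + SD` are `strong`,
#' `mean <= CSP < mean + SD` are `moderate`, the rest `below_mean`.
#' Both thresholds are inclusive at the lower edge ("ties go up").
#' Prolines and residues without assignment or with overlapped signals
#' contribute nothing to the statistics and are classed `excluded`.
#'
#' @param profile A [csp_profile()] (uses `valid`), or any data frame
#'   with columns `residue_number` and `csp` (rows with `NA` csp, or
#'   `valid = FALSE` if present, are excluded).
#' @param at_ratio Titration point to classify at; default the largest
#'   ratio present (the endpoint of the titration).
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A tibble of class `csp_classes` with columns `residue_number`,
#'   `csp`, `csp_class` (factor: strong/moderate/below_mean/excluded) and
#'   attributes `mean`, `sd`, `threshold_strong`, `at_ratio`.
#' @export
classify_csp <- function(profile, at_ratio = NULL,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  df <- tibble::as_tibble(profile)
  if (!all(c("residue_number", "csp") %in% names(df))) {
    abort("`profile` needs columns residue_number and csp.")
  }
  if ("ratio" %in% names(df)) {
    at_ratio <- at_ratio %||% max(df$ratio)
    df <- dplyr::filter(df, .data$ratio == at_ratio)
    if (nrow(df) == 0L) abort("No rows at the requested ratio.")
  }
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df$valid <- df$valid & is.finite(df$csp)
  vals <- df$csp[df$valid]
  if (length(vals) < 2L) abort("Need at least 2 valid residues.")
  m <- mean(vals)
  s <- sd(vals)
  if (sd_type == "population") {
    s <- sqrt(mean((vals - m)^2))
  }
  thr <- m + s
  cls <- ifelse(!df$valid, "excluded",
                ifelse(df$csp >= thr, "strong",
                       ifelse(df$csp >= m, "moderate", "below_mean")))
  out <- tibble::new_tibble(
    tibble::tibble(
      residue_number = df$residue_number,
      csp = ifelse(df$valid, df$csp, NA_real_),
      csp_class = factor(cls, levels = c("strong", "moderate",
                                         "below_mean", "excluded"))
    ),
    class = "csp_classes")
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  attr(out, "threshold_strong") <- thr
  attr(out, "at_ratio") <- at_ratio
  out
}

#' Per-residue intensity ratio between a titration point and the apo point
#'
#' Peak-height ratio (with ligand / without ligand) at the requested
#' molar ratio. Residues missing either intensity, or with a
#' non-positive apo intensity, are marked invalid rather than producing
#' infinities.
#'
#' @param series An `nmr_titration` whose apo and target points carry
#'   intensities.
#' @param point_ratio The molar ratio of the bound-state point.
#' @return A tibble of class `intensity_profile`: `residue_number`,
#'   `intensity_apo`, `intensity_holo`, `ratio`, `valid`.
#' @export
intensity_ratio <- function(series, point_ratio) {
  stopifnot(inherits(series, "nmr_titration"))
  pk <- series$peaks
  if (!point_ratio %in% pk$ratio) {
    abort(sprintf("No titration point at ratio %g.", point_ratio))
  }
  apo <- dplyr::filter(pk, .data$ratio == 0)
  holo <- dplyr::filter(pk, .data$ratio == point_ratio)
  out <- dplyr::left_join(
    dplyr::select(apo, "residue_number", intensity_apo = "intensity"),
    dplyr::select(holo, "residue_number", intensity_holo = "intensity"),
    by = "residue_number") |>
    dplyr::mutate(
      valid = is.finite(.data$intensity_apo) &
        is.finite(.data$intensity_holo) & .data$intensity_apo > 0,
      ratio = ifelse(.data$valid,
                     .data$intensity_holo / .data$intensity_apo, NA_real_)
    )
  tibble::new_tibble(out, class = "intensity_profile")
}

#' Classify intensity enhancement of disordered residues
#'
#' Peak-height enhancement on ligand binding flags disordered residues
#' that rigidify in the complex: ratios strictly greater than 3 are
#' `strong`, ratios in (1.5, 3] are `moderate`, the rest `none`
#' (boundaries are strict at 3 and at 1.5). Invalid ratios give
#' `invalid`.
#'
#' @param profile An `intensity_profile` from [intensity_ratio()], or any
#'   data frame with `residue_number`, `ratio` (and optionally `valid`).
#' @return The input with an `enhancement_class` factor column
#'   (strong/moderate/none/invalid) appended.
#' @export
classify_enhancement <- function(profile) {
  df <- tibble::as_tibble(profile)
  if (!all(c("residue_number", "ratio") %in% names(df))) {
    abort("`profile` needs columns residue_number and ratio.")
  }
  if (!"valid" %in% names(df)) df$valid <- is.finite(df$ratio)
  cls <- ifelse(!df$valid, "invalid",
                ifelse(df$ratio > 3, "strong",
                       ifelse(df$ratio > 1.5, "moderate", "none")))
  df$enhancement_class <- factor(cls, levels = c("strong", "moderate",
                                                 "none", "invalid"))
  df
}

#' Derive docking active residues from CSP classes
#'
#' The data-driven restraint rule for chemical-shift-based docking:
#' residues with weighted CSP at or above mean + SD (class `strong`)
#' become `active`; excluded residues are never active; everything else
#' is `none`. Passive residues are left to the docking program (or to the
#' user) and are not auto-derived here. An optional contiguity smoothing
#' (off by default) promotes a single `moderate` residue flanked on both
#' sides by active residues.
#'
#' @param classes A `csp_classes` tibble from [classify_csp()].
#' @param smooth Logical; apply contiguity smoothing (default `FALSE`).
#' @return A tibble `residue_number`, `csp_class`, `docking_role`
#'   (active/passive/none) with attribute `active_ranges`, a compact
#'   comma-separated range string (e.g. `"19-22,33"`) for export.
#' @export
derive_active_residues <- function(classes, smooth = FALSE) {
  df <- tibble::as_tibble(classes)
  role <- ifelse(df$csp_class == "strong", "active", "none")
  if (smooth) {
    ord <- order(df$residue_number)
    act <- role[ord] == "active"
    mod <- df$csp_class[ord] == "moderate"
    promote <- which(mod & dplyr::lag(act, default = FALSE) &
                       dplyr::lead(act, default = FALSE))
    role[ord][promote] <- "active"
  }
  df$docking_role <- factor(role, levels = c("active", "passive", "none"))
  if (!any(role == "active")) {
    warn("No residues classed strong: empty active list.")
  }
  attr(df, "active_ranges") <-
    residue_ranges(sort(df$residue_number[role == "active"]))
  df
}

#' Collapse residue numbers into a compact range string
#'
#' @param x Sorted integer residue numbers.
#' @return A string such as `"19-22,33,37"` (empty string for no input).
#' @export
residue_ranges <- function(x) {
  if (length(x) == 0L) return("")
  x <- sort(unique(as.integer(x)))
  brk <- c(0L, which(diff(x) != 1L), length(x))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- x[brk[i] + 1L]; b <- x[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = ",")
}

ANNOT_COLS <- c("residue_number", "csp_class", "enhancement_class",
                "docking_role")

#' Export per-residue annotations
#'
#' `"tsv"` writes one row per residue with the CSP class, enhancement
#' class and docking role (read back by [read_annotations()]).
#' `"graphics_script"` writes a generic molecular-viewer command script
#' using the conventional CSP colour map (red = strong, pink = moderate,
#' white = below mean, yellow = excluded) with one `color` command per
#' non-white residue, plus a cyan side-chain highlight for
#' strong-enhancement residues.
#'
#' @param annotations Data frame with columns `residue_number`,
#'   `csp_class` and optionally `enhancement_class`, `docking_role`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphics_script"`.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(annotations,
                               path, format = c("tsv", "graphics_script")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(annotations)
  if (!all(c("residue_number", "csp_class") %in% names(df))) {
    abort("`annotations` needs residue_number and csp_class.")
  }
  if (!"enhancement_class" %in% names(df)) {
    df$enhancement_class <- factor("none", levels = levels(factor(c(
      "strong", "moderate", "none", "invalid"))))
  }
  if (!"docking_role" %in% names(df)) df$docking_role <- "none"
  df <- df[, ANNOT_COLS]
  if (format == "tsv") {
    out <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    colmap <- c(strong = "red", moderate = "pink", below_mean = "white",
                excluded = "yellow")
    cmds <- character()
    for (i in seq_len(nrow(df))) {
      col <- colmap[[as.character(df$csp_class[i])]]
      if (col != "white") {
        cmds <- c(cmds, sprintf("color %s :%d", col, df$residue_number[i]))
      }
      if (as.character(df$enhancement_class[i]) == "strong") {
        cmds <- c(cmds, sprintf("color cyan :%d@sidechain",
                                df$residue_number[i]))
      }
    }
    writeLines(cmds, path)
  }
  invisible(path)
}

#' @rdname export_annotations
#' @export
read_annotations <- function(path) {
  tb <- readr::read_tsv(path, col_types = "iccc", progress = FALSE)
  tb$csp_class <- factor(tb$csp_class,
                         levels = c("strong", "moderate", "below_mean",
                                    "excluded"))
  tb$enhancement_class <- factor(tb$enhancement_class,
                                 levels = c("strong", "moderate", "none",
                                            "invalid"))
  tb$docking_role <- factor(tb$docking_role,
                            levels = c("active", "passive", "none"))
  tb
}
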