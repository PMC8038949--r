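#' Weighted amide chemical shift perturbation
#'
#' Combines the amide proton and nitrogen chemical-shift changes between the
#' apo and ligand-bound states into a single weighted perturbation,
#' `CSP = sqrt(delta_h^2 + (nitrogen_weight * delta_n)^2)`. The default
#' nitrogen weight of 1/5 accounts for the larger chemical-shift range of
#' the 15N nucleus.
#'
#' @param delta_h Change in 1H amide shift (ppm). Vectorised.
#' @param delta_n Change in 15N amide shift (ppm). Vectorised.
#' @param nitrogen_weight Scaling applied to `delta_n`; default `1/5`.
#' @return Numeric vector of combined CSPs (ppm), `NA` where either input
#'   is `NA`.
#' @examples
#' compute_csp(0.10, 0.50)   # 0.1414
#' compute_csp(0, 0.50)      # 0.10: the 15N change is down-weighted 5x
#' @export
compute_csp <- function(delta_h, delta_n, nitrogen_weight = 1 / 5) {
  if (!is.numeric(delta_h) || !is.numeric(delta_n)) {
    abort("`delta_h` and `delta_n` must be numeric.")
  }
  bad <- (is.nan(delta_h) | is.infinite(delta_h) |
            is.nan(delta_n) | is.infinite(delta_n))
  if (any(bad, na.rm = TRUE)) {
    abort("`delta_h`/`delta_n` must be finite (NaN or Inf found).")
  }
  check_number(nitrogen_weight, "nitrogen_weight", lower = 0)
  sqrt(delta_h^2 + (nitrogen_weight * delta_n)^2)
}

#' Protein concentration after titrant dilution
#'
#' During a titration the protein is diluted by each addition of ligand
#' stock. At molar ratio `r` the protein concentration is
#' `1 / (1/c_pro + r/c_lig)`: it equals `c_pro` at `r = 0` and decreases
#' strictly with `r`.
#'
#' @param r Molar ratio of ligand to protein (dimensionless, >= 0).
#' @param c_pro Initial protein concentration (uM).
#' @param c_lig Ligand stock concentration (uM).
#' @return Protein concentration (uM) at each `r`.
#' @export
total_protein_conc <- function(r, c_pro, c_lig) {
  check_number(c_pro, "c_pro", lower = 0, allow_zero = FALSE)
  check_number(c_lig, "c_lig", lower = 0, allow_zero = FALSE)
  if (any(!is.finite(r)) || any(r < 0)) {
    abort("`r` must be finite and non-negative.")
  }
  1 / (1 / c_pro + r / c_lig)
}

#' Predicted CSP under the n-equivalent-sites binding isotherm
#'
#' Fast-exchange binding model for a titration in which each ligand
#' molecule carries `n_sites` equivalent and independent protein-binding
#' sites, with correction for dilution of the protein by the ligand stock:
#'
#' \deqn{CSP = \frac{CSP_{max}}{2}\Big[(1 + nr + nK_D(1/C_{pro} + r/C_{lig}))
#'   - n\sqrt{(1/n + r + K_D(1/C_{pro} + r/C_{lig}))^2 - 4r/n}\Big]}
#'
#' The bracket equals twice the bound fraction of protein obtained from the
#' mass-action quadratic with total sites \eqn{S_t = n r P_t} and
#' macroscopic constant \eqn{K = n K_D}, where \eqn{P_t} is the diluted
#' protein concentration ([total_protein_conc()]). The implementation uses
#' the algebraically equivalent form \eqn{CSP_{max} \cdot 2nr / (A + nD)}
#' with \eqn{A} the linear term and \eqn{D} the discriminant root, which
#' avoids catastrophic cancellation at weak binding.
#'
#' @param r Molar ratio(s) of ligand to protein (>= 0). Vectorised.
#' @param kd Dissociation constant (uM, >= 0).
#' @param cspmax CSP at saturation (ppm, >= 0).
#' @param n_sites Number of equivalent independent sites per ligand (> 0).
#' @param c_pro,c_lig Initial protein and ligand stock concentrations (uM).
#' @return Predicted CSP (ppm), in `[0, cspmax]`, nondecreasing in `r`.
#' @examples
#' predict_csp(0.5, kd = 22, cspmax = 0.2, n_sites = 3,
#'             c_pro = 100, c_lig = 5000)
#' @export
predict_csp <- function(r, kd, cspmax = 1, n_sites, c_pro, c_lig) {
  check_number(kd, "kd", lower = 0)
  check_number(cspmax, "cspmax", lower = 0)
  check_number(n_sites, "n_sites", lower = 0, allow_zero = FALSE)
  if (any(!is.finite(r)) || any(r < 0)) {
    abort("`r` must be finite and non-negative.")
  }
  n <- n_sites
  k <- kd / total_protein_conc(r, c_pro, c_lig)  # kd * (1/c_pro + r/c_lig)
  disc <- (1 / n + r + k)^2 - 4 * r / n
  tol <- 1e-12 * pmax(1, (1 / n + r + k)^2)
  if (any(disc < -tol)) {
    abort("Negative discriminant in the binding isotherm: invalid parameters.")
  }
  disc <- pmax(disc, 0)
  a <- 1 + n * r + n * k
  # stable equivalent of (cspmax / 2) * (a - n * sqrt(disc))
  out <- cspmax * (2 * n * r) / (a + n * sqrt(disc))
  out[r == 0] <- 0
  out
}

#' Per-residue CSP trajectories from a titration series
#'
#' For every residue and titration point, computes the 1H and 15N shift
#' changes relative to the apo (`r = 0`) point and the combined weighted
#' CSP. Residues flagged proline/unassigned/overlapped at a point, or with
#' missing shifts there, are masked (`valid = FALSE`) at that point only.
#'
#' @param series A titration series from [assemble_series()] or
#'   [simulate_titration()].
#' @param nitrogen_weight Passed to [compute_csp()].
#' @return A tibble of class `csp_profile` with columns `residue_number`,
#'   `residue_type`, `ratio`, `delta_h`, `delta_n`, `csp`, `valid`, and
#'   attributes `c_pro`, `c_lig` carried over from the series.
#' @export
csp_profile <- function(series, nitrogen_weight = 1 / 5) {
  stopifnot(inherits(series, "nmr_titration"))
  peaks <- series$peaks
  apo <- dplyr::filter(peaks, .data$ratio == 0)
  if (nrow(apo) == 0L) abort("Series has no apo (r = 0) point.")
  apo_ref <- dplyr::select(apo, "residue_number",
                           apo_h = "shift_h", apo_n = "shift_n",
                           apo_flags = "flags")
  prof <- peaks |>
    dplyr::left_join(apo_ref, by = "residue_number") |>
    dplyr::mutate(
      delta_h = .data$shift_h - .data$apo_h,
      delta_n = .data$shift_n - .data$apo_n,
      valid = .data$flags == "" & .data$apo_flags == "" &
        is.finite(.data$delta_h) & is.finite(.data$delta_n)
    ) |>
    dplyr::mutate(
      csp = ifelse(.data$valid,
                   compute_csp(ifelse(.data$valid, .data$delta_h, 0),
                               ifelse(.data$valid, .data$delta_n, 0),
                               nitrogen_weight),
                   NA_real_),
      delta_h = ifelse(.data$valid, .data$delta_h, NA_real_),
      delta_n = ifelse(.data$valid, .data$delta_n, NA_real_)
    ) |>
    dplyr::select("residue_number", "residue_type", "ratio",
                  "delta_h", "delta_n", "csp", "valid") |>
    dplyr::arrange(.data$ratio, .data$residue_number)
  out <- tibble::new_tibble(prof, class = "csp_profile")
  attr(out, "c_pro") <- series$c_pro
  attr(out, "c_lig") <- series$c_lig
  attr(out, "protein_id") <- series$protein_id
  attr(out, "ligand_id") <- series$ligand_id
  out
}

# Profiled residual sum of squares at a fixed kd: given kd the model is
# linear in each residue's cspmax, so the optimal cspmax has a closed form
# (clamped to its bounds). Returns rss plus the per-residue cspmax.
profiled_rss <- function(kd, dat, n_sites, c_pro, c_lig, cap) {
  f <- predict_csp(dat$ratio, kd = kd, cspmax = 1, n_sites = n_sites,
                   c_pro = c_pro, c_lig = c_lig)
  denom <- as.numeric(rowsum(f^2, dat$res_idx))
  num <- as.numeric(rowsum(dat$csp * f, dat$res_idx))
  ci <- ifelse(denom > 0, num / denom, 0)
  cspmax <- pmin(pmax(ci, 0), cap)
  names(cspmax) <- names(cap)
  res <- dat$csp - cspmax[dat$res_idx] * f
  list(rss = sum(res^2), cspmax = cspmax, fitted_unit = f)
}

fit_kd_core <- function(dat, n_sites, c_pro, c_lig, kd_bounds, n_starts) {
  cap_tbl <- dat |>
    dplyr::group_by(.data$res_idx) |>
    dplyr::summarise(cap = 10 * max(.data$csp), .groups = "drop") |>
    dplyr::arrange(.data$res_idx)
  cap <- cap_tbl$cap
  names(cap) <- levels(dat$residue_f)[cap_tbl$res_idx]
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])
  cuts <- seq(lb, ub, length.out = n_starts + 1L)
  best <- NULL
  obj <- function(lk) {
    profiled_rss(10^lk, dat, n_sites, c_pro, c_lig, cap)$rss
  }
  for (s in seq_len(n_starts)) {
    op <- optimize(obj, lower = cuts[s], upper = cuts[s + 1L], tol = 1e-9)
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  # endpoints, in case the optimum sits on a subinterval boundary
  for (lk in c(lb, ub)) {
    o <- obj(lk)
    if (o < best$objective) best <- list(minimum = lk, objective = o)
  }
  kd_hat <- 10^best$minimum
  pr <- profiled_rss(kd_hat, dat, n_sites, c_pro, c_lig, cap)
  at_bound <- best$minimum <= lb + 1e-6 || best$minimum >= ub - 1e-6
  list(kd = kd_hat, cspmax = pr$cspmax, rss = pr$rss,
       fitted = pr$cspmax[dat$res_idx] * pr$fitted_unit,
       converged = !at_bound, cap = cap)
}

#' Fit a dissociation constant to CSP titration profiles
#'
#' Nonlinear least-squares fit of the n-equivalent-sites isotherm
#' ([predict_csp()]) to per-residue CSP trajectories. In `"global"` mode a
#' single K_D is shared across residues, each with its own CSP_max; in
#' `"per_residue"` mode each residue is fitted independently. The number of
#' sites `n_sites` is held fixed (its fitted value is hard to interpret, so
#' it is chosen from the experimental design rather than estimated).
#'
#' Because the model is conditionally linear in CSP_max, the fit profiles
#' CSP_max out analytically and minimises over log10(K_D) alone, using
#' multiple log-spaced bracketing intervals (`n_starts`) and keeping the
#' best solution. CSP_max is bounded in `[0, 10 * max observed CSP]` per
#' residue and K_D in `kd_bounds`. The loss is unweighted in ppm.
#'
#' @param profile A `csp_profile` (see [csp_profile()]) or any data frame
#'   with columns `residue_number`, `ratio`, `csp` (and optionally `valid`).
#' @param n_sites Fixed number of equivalent sites per ligand.
#' @param mode `"global"` (one shared K_D; default) or `"per_residue"`.
#' @param residues Residue numbers to fit. Default: in global mode, the
#'   residues whose final-point CSP is at or above the mean final-point CSP
#'   (the clearly shifting set); in per-residue mode, all valid residues.
#' @param c_pro,c_lig Concentrations (uM); default taken from the profile's
#'   attributes.
#' @param kd_bounds Bounds for K_D (uM).
#' @param n_starts Number of log-spaced bracketing intervals (>= 5 gives
#'   the multi-start behaviour; default 5).
#' @param bootstrap Number of residual-resampling bootstrap draws for a
#'   95% K_D confidence interval (0 = none). Global mode only.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `kd_fit` with elements `kd`, `kd_ci`,
#'   `per_residue` (tibble: residue, kd, cspmax, rss, n_points, converged),
#'   `residuals` (per-point tibble), `rss`, `converged`, `mode`, `n_sites`,
#'   `n_was_fixed`, `boot_kd`. Use [tidy()], [glance()], [autoplot()].
#' @export
fit_kd <- function(profile, n_sites, mode = c("global", "per_residue"),
                   residues = NULL,
                   c_pro = attr(profile, "c_pro"),
                   c_lig = attr(profile, "c_lig"),
                   kd_bounds = c(1e-4, 1e6), n_starts = 5,
                   bootstrap = 0, seed = NULL) {
  mode <- match.arg(mode)
  check_number(n_sites, "n_sites", lower = 0, allow_zero = FALSE)
  if (is.null(c_pro) || is.null(c_lig)) {
    abort("`c_pro`/`c_lig` missing: supply them or use a csp_profile.")
  }
  df <- tibble::as_tibble(profile)
  if (!all(c("residue_number", "ratio", "csp") %in% names(df))) {
    abort("`profile` needs columns residue_number, ratio, csp.")
  }
  if (!"valid" %in% names(df)) df$valid <- is.finite(df$csp)
  df <- dplyr::filter(df, .data$valid, is.finite(.data$csp))

  # residue selection
  if (is.null(residues)) {
    if (mode == "global") {
      fin <- df |>
        dplyr::group_by(.data$residue_number) |>
        dplyr::slice_max(.data$ratio, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      residues <- fin$residue_number[fin$csp >= mean(fin$csp)]
    } else {
      residues <- unique(df$residue_number)
    }
  }
  df <- dplyr::filter(df, .data$residue_number %in% residues)

  # need enough points per residue to constrain (kd, cspmax)
  counts <- dplyr::count(df, .data$residue_number)
  drop <- counts$residue_number[counts$n < 3L]
  if (length(drop) > 0L) {
    warn(sprintf("Dropping %d residue(s) with < 3 valid points: %s",
                 length(drop), paste(drop, collapse = ", ")))
    df <- dplyr::filter(df, !.data$residue_number %in% drop)
  }
  if (nrow(df) == 0L) abort("No residues with enough valid points to fit.")

  empty_fit <- function(msg) {
    structure(list(kd = NA_real_, kd_ci = c(NA_real_, NA_real_),
                   per_residue = tibble::tibble(),
                   residuals = tibble::tibble(), rss = NA_real_,
                   converged = FALSE, mode = mode, n_sites = n_sites,
                   n_was_fixed = TRUE, boot_kd = numeric(),
                   c_pro = c_pro, c_lig = c_lig, message = msg),
              class = "kd_fit")
  }
  if (all(df$csp == 0)) {
    inform("All CSPs are zero: no binding signal, nothing fitted.")
    return(empty_fit("no binding signal (all CSPs zero)"))
  }

  df$residue_f <- factor(df$residue_number, levels = sort(unique(df$residue_number)))
  df$res_idx <- as.integer(df$residue_f)

  if (mode == "global") {
    fit <- fit_kd_core(df, n_sites, c_pro, c_lig, kd_bounds, n_starts)
    resid_tbl <- tibble::tibble(
      residue_number = df$residue_number, ratio = df$ratio,
      csp = df$csp, fitted = fit$fitted,
      residual = df$csp - fit$fitted
    )
    per_res <- resid_tbl |>
      dplyr::group_by(.data$residue_number) |>
      dplyr::summarise(rss = sum(.data$residual^2),
                       n_points = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(kd = fit$kd,
                    cspmax = unname(fit$cspmax),
                    converged = fit$converged) |>
      dplyr::select("residue_number", "kd", "cspmax", "rss",
                    "n_points", "converged")
    boot_kd <- numeric()
    kd_ci <- c(NA_real_, NA_real_)
    if (bootstrap > 0) {
      # bootstrap refits search a +/- 1.5 log-decade bracket around the
      # point estimate (the resampled optimum stays nearby)
      bb <- c(max(kd_bounds[1], fit$kd * 10^-1.5),
              min(kd_bounds[2], fit$kd * 10^1.5))
      boot_kd <- with_seed(seed, {
        vapply(seq_len(bootstrap), function(b) {
          idx <- sample.int(nrow(df), replace = TRUE)
          db <- df
          db$csp <- fit$fitted + resid_tbl$residual[idx]
          fit_kd_core(db, n_sites, c_pro, c_lig, bb, 2L)$kd
        }, numeric(1))
      })
      kd_ci <- unname(quantile(boot_kd, c(0.025, 0.975)))
    }
    out <- list(kd = fit$kd, kd_ci = kd_ci, per_residue = per_res,
                residuals = resid_tbl, rss = fit$rss,
                converged = fit$converged, mode = mode, n_sites = n_sites,
                n_was_fixed = TRUE, boot_kd = boot_kd,
                c_pro = c_pro, c_lig = c_lig, message = NULL)
  } else {
    pieces <- lapply(split(df, df$residue_f), function(d1) {
      if (all(d1$csp == 0)) return(NULL)
      d1$res_idx <- 1L
      d1$residue_f <- factor(d1$residue_number[1])
      f1 <- fit_kd_core(d1, n_sites, c_pro, c_lig, kd_bounds, n_starts)
      list(res = tibble::tibble(residue_number = d1$residue_number[1],
                                kd = f1$kd, cspmax = unname(f1$cspmax),
                                rss = f1$rss, n_points = nrow(d1),
                                converged = f1$converged),
           pts = tibble::tibble(residue_number = d1$residue_number,
                                ratio = d1$ratio, csp = d1$csp,
                                fitted = f1$fitted,
                                residual = d1$csp - f1$fitted))
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces) == 0L) {
      inform("All per-residue profiles are zero: nothing fitted.")
      return(empty_fit("no binding signal (all CSPs zero)"))
    }
    per_res <- dplyr::bind_rows(lapply(pieces, `[[`, "res"))
    resid_tbl <- dplyr::bind_rows(lapply(pieces, `[[`, "pts"))
    out <- list(kd = NA_real_, kd_ci = c(NA_real_, NA_real_),
                per_residue = per_res, residuals = resid_tbl,
                rss = sum(per_res$rss), converged = all(per_res$converged),
                mode = mode, n_sites = n_sites, n_was_fixed = TRUE,
                boot_kd = numeric(), c_pro = c_pro, c_lig = c_lig,
                message = NULL)
  }
  structure(out, class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<kd_fit> mode:", x$mode, " n_sites (fixed):", x$n_sites, "\n")
  if (x$mode == "global") {
    cat(sprintf("  K_D = %.4g uM", x$kd))
    if (all(is.finite(x$kd_ci))) {
      cat(sprintf("  (95%% bootstrap CI %.4g - %.4g)", x$kd_ci[1], x$kd_ci[2]))
    }
    cat("\n")
  } else if (nrow(x$per_residue) > 0) {
    cat(sprintf("  per-residue K_D: median %.4g uM over %d residues\n",
                stats::median(x$per_residue$kd), nrow(x$per_residue)))
  }
  cat(sprintf("  residues fitted: %d   RSS = %.4g ppm^2   converged: %s\n",
              nrow(x$per_residue), x$rss, x$converged))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' @describeIn fit_kd Per-residue fit table (residue, kd, cspmax, rss, ...).
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) x$per_residue

#' @describeIn fit_kd One-row fit summary (kd, ci, rss, convergence).
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, kd_ci_low = x$kd_ci[1], kd_ci_high = x$kd_ci[2],
                 n_sites = x$n_sites, mode = x$mode, rss = x$rss,
                 n_residues = nrow(x$per_residue),
                 n_points = nrow(x$residuals), converged = x$converged)
}

#' @describeIn fit_kd Titration curves: observed CSP vs molar ratio with
#'   the fitted isotherm, one facet per residue.
#' @param object A `kd_fit` object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  if (nrow(object$residuals) == 0) abort("Nothing was fitted.")
  grid <- object$per_residue |>
    dplyr::mutate(curve = purrr::map2(.data$kd, .data$cspmax, function(k, cm) {
      r <- seq(0, max(object$residuals$ratio), length.out = 80)
      tibble::tibble(ratio = r,
                     csp = predict_csp(r, k, cm, object$n_sites,
                                       object$c_pro, object$c_lig))
    })) |>
    dplyr::select("residue_number", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$ratio, y = .data$csp)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~residue_number) +
    ggplot2::labs(x = "molar ratio (ligand : protein)",
                  y = "CSP (ppm)") +
    ggplot2::theme_minimal()
}

#' @describeIn csp_profile Per-residue CSP bar chart at one titration point
#'   (default: the final point), the classic CSP-vs-residue plot.
#' @param object A `csp_profile`.
#' @param at_ratio Titration point to display; default the largest ratio.
#' @param ... Unused.
#' @export
autoplot.csp_profile <- function(object, at_ratio = NULL, ...) {
  at_ratio <- at_ratio %||% max(object$ratio)
  d <- dplyr::filter(tibble::as_tibble(object), .data$ratio == at_ratio)
  if (nrow(d) == 0) abort("No rows at that ratio.")
  m <- mean(d$csp[d$valid], na.rm = TRUE)
  s <- sd(d$csp[d$valid], na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue_number, y = .data$csp)) +
    ggplot2::geom_col(width = 0.8, fill = "grey30", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(m, m + s), linetype = c(2, 3),
                        colour = c("pink3", "red3")) +
    ggplot2::labs(x = "residue number", y = "CSP (ppm)",
                  title = sprintf("CSP at molar ratio %.3g (mean, mean+SD lines)",
                                  at_ratio)) +
    ggplot2::theme_minimal()
}
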