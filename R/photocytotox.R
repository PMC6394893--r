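## SRB photo-cytotoxicity analysis: viability normalization,
## four-parameter-logistic dose-response fitting with bootstrap EC50
## confidence intervals, activity calls, and the dark/irradiated
## selectivity index S.I. = EC50,dark / EC50,irradiated.

#' Normalize raw SRB optical densities to percent viability
#'
#' `viability = 100 * (od - mean(blanks)) / (mean(untreated) - mean(blanks))`.
#' The SRB (sulforhodamine B) protein stain is redox-independent, so this
#' linear normalization against untreated controls is valid for
#' photosensitizer screens where redox-active dyes (MTT and analogues)
#' give false positives.
#'
#' @param raw_od numeric vector of sample well ODs.
#' @param untreated_controls ODs of untreated control wells (>= 1).
#' @param blanks ODs of cell-free blank wells (>= 1).
#' @return viability in percent of the untreated control.
#' @export
normalize_srb <- function(raw_od, untreated_controls, blanks) {
  if (!length(untreated_controls) || !length(blanks)) {
    stop("need at least one untreated control and one blank", call. = FALSE)
  }
  b <- mean(blanks)
  u <- mean(untreated_controls)
  if (u <= b) {
    stop("assay failure: mean untreated OD (", signif(u, 3),
         ") does not exceed mean blank OD (", signif(b, 3), ")", call. = FALSE)
  }
  100 * (raw_od - b) / (u - b)
}

## 4PL response: viability(c) = bottom + (top - bottom) / (1 + (c/ec50)^hill)
## hill > 0 gives decreasing viability with concentration.
four_pl <- function(conc, ec50, hill, top, bottom) {
  if (!is.finite(ec50)) return(rep(top, length(conc)))
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

## single bounded Levenberg-Marquardt fit on log10 concentration;
## returns NULL on failure
fit_4pl_once <- function(logc, viab, start, lower, upper) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      viab ~ bottom + (top - bottom) / (1 + 10^(hill * (logc - logec50))),
      data = data.frame(logc = logc, viab = viab),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(par = p, rss = sum(stats::resid(fit)^2))
}

## multistart 4PL point fit; starts from three EC50 guesses spanning the
## tested range (min, geometric mean, max)
fit_4pl_point <- function(conc, viab, start_par = NULL) {
  logc <- log10(conc)
  lo <- min(logc); hi <- max(logc)
  lower <- c(top = 80, bottom = -10, hill = -20, logec50 = lo - 3)
  upper <- c(top = 120, bottom = 40, hill = 20, logec50 = hi + 3)
  starts <- if (is.null(start_par)) {
    lapply(c(lo, (lo + hi) / 2, hi), function(g) {
      c(top = 100, bottom = 0, hill = 1, logec50 = g)
    })
  } else {
    list(pmin(pmax(start_par, lower), upper))
  }
  fits <- Filter(Negate(is.null), lapply(starts, function(s) {
    fit_4pl_once(logc, viab, as.list(s), lower, upper)
  }))
  if (!length(fits)) return(NULL)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

#' Fit a four-parameter-logistic dose-response curve
#'
#' Fits `v(c) = bottom + (top - bottom) / (1 + (c/EC50)^h)` to
#' replicate-level viability data by bounded Levenberg-Marquardt least
#' squares on log10 concentration, with a multistart over three initial
#' EC50 guesses (bounds: top in \[80, 120\], bottom in \[-10, 40\], Hill
#' slope unconstrained in sign). The 95% EC50 confidence interval comes
#' from a case-resampling bootstrap: replicates are resampled with
#' replacement within each concentration and the curve refit (started at
#' the point estimate). The interval is a t-type interval on log10 EC50,
#' `logEC50 +/- t(N - m) * SE_boot * sqrt(N / (N - m))` with N data
#' points over m concentrations: resampling n-of-n within a
#' concentration underestimates the group variance by (n-1)/n, so the
#' bootstrap SE is inflated by the residual-df factor (at triplicate
#' scale a plain percentile interval undercovers badly).
#'
#' Censoring: when the fitted EC50 exceeds the highest tested
#' concentration, or the fitted viability change across the tested
#' range falls below `min_effect` (a flat curve), the sample is
#' reported as inactive with EC50 "> max tested" rather than an
#' extrapolated number.
#'
#' @param data data frame with columns `concentration_ug_per_ml` and
#'   `viability_pct`, one row per replicate measurement (>= 4
#'   concentration levels).
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed optional seed for the bootstrap.
#' @param activity_cap concentration cap for the activity call
#'   (default 50 ug/mL: an extract is "active" only if its uncensored
#'   EC50 lies below the cap).
#' @param min_effect minimum fitted viability span, in percentage
#'   points, below which the curve is considered flat (default 25).
#' @param conf confidence level (default 0.95).
#' @return list of class `dose_response_fit` with elements `ec50`,
#'   `ec50_ci`, `hill`, `top`, `bottom`, `censored`, `max_tested`,
#'   `active`, `fit_ok`, `n_boot_ok`, `data`.
#' @export
fit_4pl <- function(data, n_boot = 1000, seed = NULL, activity_cap = 50,
                    min_effect = 25, conf = 0.95) {
  conc <- data$concentration_ug_per_ml
  viab <- data$viability_pct
  keep <- is.finite(conc) & is.finite(viab) & conc > 0
  conc <- conc[keep]; viab <- viab[keep]
  if (length(unique(conc)) < 4) {
    stop("need at least 4 concentration levels with finite viability",
         call. = FALSE)
  }
  if (any(viab < -20 | viab > 150)) {
    warning("viability values outside [-20, 150] present", call. = FALSE)
  }
  max_tested <- max(conc)

  pt <- fit_4pl_point(conc, viab)
  if (is.null(pt)) {
    return(structure(list(
      ec50 = NA_real_, ec50_ci = c(NA_real_, NA_real_), hill = NA_real_,
      top = NA_real_, bottom = NA_real_, censored = NA, max_tested = max_tested,
      active = FALSE, fit_ok = FALSE, n_boot_ok = 0L, data = data
    ), class = "dose_response_fit"))
  }
  p <- pt$par
  ec50 <- 10^p[["logec50"]]
  # flatness is judged by the fitted effect across the tested range, not
  # by top - bottom alone: a near-zero Hill slope can carry a large
  # nominal span while predicting essentially no effect anywhere
  v_ends <- four_pl(range(conc), ec50, p[["hill"]], p[["top"]], p[["bottom"]])
  flat <- abs(diff(v_ends)) < min_effect
  censored <- ec50 > max_tested || flat

  n_total <- length(conc)
  m_conc <- length(unique(conc))
  df_resid <- n_total - m_conc
  boot_log <- numeric(0)
  if (!censored && n_boot > 0 && df_resid > 0) {
    groups <- split(seq_along(conc), conc)
    do_boot <- function() {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      f <- fit_4pl_point(conc[idx], viab[idx], start_par = p)
      if (is.null(f)) return(NA_real_)
      f$par[["logec50"]]
    }
    boot_log <- if (is.null(seed)) {
      replicate(n_boot, do_boot())
    } else {
      with_seed(seed, replicate(n_boot, do_boot()))
    }
    boot_log <- boot_log[is.finite(boot_log)]
  }
  ci <- if (length(boot_log) >= 10) {
    infl <- sqrt(n_total / df_resid)
    half <- stats::qt(1 - (1 - conf) / 2, df_resid) * stats::sd(boot_log) * infl
    10^(p[["logec50"]] + c(-1, 1) * half)
  } else {
    c(NA_real_, NA_real_)
  }

  structure(list(
    ec50 = if (censored) Inf else ec50,
    ec50_ci = ci,
    hill = p[["hill"]], top = p[["top"]], bottom = p[["bottom"]],
    censored = censored, max_tested = max_tested,
    active = !censored && ec50 < activity_cap,
    fit_ok = TRUE, n_boot_ok = length(boot_log), data = data
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("<dose_response_fit> fit failed\n")
    return(invisible(x))
  }
  if (x$censored) {
    cat("<dose_response_fit> EC50 > ", signif(x$max_tested, 3),
        " (censored, inactive)\n", sep = "")
  } else {
    cat("<dose_response_fit> EC50 = ", signif(x$ec50, 3),
        " [", signif(x$ec50_ci[1], 3), ", ", signif(x$ec50_ci[2], 3),
        "] 95% CI, hill = ", signif(x$hill, 3),
        ", top = ", round(x$top, 1), ", bottom = ", round(x$bottom, 1),
        if (x$active) ", active" else ", not active", "\n", sep = "")
  }
  invisible(x)
}

#' Selectivity index of photo-enhanced toxicity
#'
#' `S.I. = EC50,dark / EC50,irradiated`. Censored EC50s propagate as
#' bounds, never as point values: a dark arm censored at the activity
#' cap with an active irradiated arm yields a lower bound
#' `cap / EC50,irradiated` (reported as "> bound"); an irradiated arm
#' censored with an active dark arm caps the S.I. from above and is not
#' photo-enhanced; both censored leaves the index undefined.
#'
#' @param dark,irr [fit_4pl()] results for the dark and irradiated arms.
#' @param threshold minimum S.I. for the photo-enhancement call
#'   (default 2).
#' @param cap concentration cap used for the censored-dark lower bound
#'   (default 50 ug/mL).
#' @return list of class `selectivity_result` with `si`, `si_censored`
#'   (TRUE when `si` is a lower bound), `photo_enhanced`.
#' @export
selectivity <- function(dark, irr, threshold = 2, cap = 50) {
  stopifnot(inherits(dark, "dose_response_fit"),
            inherits(irr, "dose_response_fit"))
  if (!dark$fit_ok || !irr$fit_ok) {
    return(structure(list(si = NA_real_, si_censored = NA,
                          photo_enhanced = FALSE),
                     class = "selectivity_result"))
  }
  if (dark$censored && irr$censored) {
    return(structure(list(si = NA_real_, si_censored = NA,
                          photo_enhanced = FALSE),
                     class = "selectivity_result"))
  }
  if (dark$censored) {
    bound <- cap / irr$ec50
    return(structure(list(si = bound, si_censored = TRUE,
                          photo_enhanced = bound >= threshold),
                     class = "selectivity_result"))
  }
  if (irr$censored) {
    # light adds nothing measurable; S.I. is at most dark/cap < 1
    return(structure(list(si = dark$ec50 / cap, si_censored = FALSE,
                          photo_enhanced = FALSE),
                     class = "selectivity_result"))
  }
  si <- dark$ec50 / irr$ec50
  structure(list(si = si, si_censored = FALSE,
                 photo_enhanced = si >= threshold),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("<selectivity_result> S.I. ",
      if (isTRUE(x$si_censored)) "> " else "= ",
      signif(x$si, 3),
      if (isTRUE(x$photo_enhanced)) " (photo-enhanced)", "\n", sep = "")
  invisible(x)
}

#' Fit dark and irradiated arms of a dose-response table
#'
#' Convenience wrapper: splits a long table by sample, cell line and
#' arm, fits each series, and pairs the arms into selectivity results.
#'
#' @param data data frame with columns `sample_id`, `cell_line`, `arm`
#'   (dark / irradiated), `concentration_ug_per_ml`, `replicate`,
#'   `viability_pct`.
#' @inheritParams fit_4pl
#' @param si_threshold photo-enhancement threshold passed to
#'   [selectivity()].
#' @return tibble with one row per sample x cell line:
#'   `ec50_dark, ec50_dark_low, ec50_dark_high, ec50_irr, ec50_irr_low,
#'   ec50_irr_high, hill_dark, hill_irr, censored_dark, censored_irr,
#'   active_dark, active_irr, si, si_censored, photo_enhanced`.
#' @export
fit_dose_response_table <- function(data, n_boot = 1000, seed = NULL,
                                    activity_cap = 50, min_effect = 25,
                                    si_threshold = 2) {
  stopifnot(all(c("sample_id", "cell_line", "arm", "concentration_ug_per_ml",
                  "viability_pct") %in% names(data)))
  bad_arm <- setdiff(unique(data$arm), c("dark", "irradiated"))
  if (length(bad_arm)) {
    stop("unknown dose-response arm(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(data[, c("sample_id", "cell_line")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$sample_id == keys$sample_id[i] &
                  data$cell_line == keys$cell_line[i], ]
    sub_seed <- if (is.null(seed)) NULL else seed + i
    fd <- fit_4pl(sub[sub$arm == "dark", ], n_boot = n_boot, seed = sub_seed,
                  activity_cap = activity_cap, min_effect = min_effect)
    fi <- fit_4pl(sub[sub$arm == "irradiated", ], n_boot = n_boot,
                  seed = if (is.null(sub_seed)) NULL else sub_seed + 10000L,
                  activity_cap = activity_cap, min_effect = min_effect)
    sel <- selectivity(fd, fi, threshold = si_threshold, cap = activity_cap)
    tibble::tibble(
      sample_id = keys$sample_id[i], cell_line = keys$cell_line[i],
      ec50_dark = fd$ec50, ec50_dark_low = fd$ec50_ci[1],
      ec50_dark_high = fd$ec50_ci[2],
      ec50_irr = fi$ec50, ec50_irr_low = fi$ec50_ci[1],
      ec50_irr_high = fi$ec50_ci[2],
      hill_dark = fd$hill, hill_irr = fi$hill,
      censored_dark = fd$censored, censored_irr = fi$censored,
      active_dark = fd$active, active_irr = fi$active,
      si = sel$si, si_censored = sel$si_censored,
      photo_enhanced = sel$photo_enhanced
    )
  })
  do.call(rbind, rows)
}
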