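# Enzyme-kinetics confirmation analytics: Michaelis-Menten and IC50 fits,
# Dixon regression, residual activity, fold changes, inhibition-type calls
# and substrate-selectivity ratios.

#' Residual enzyme activity from chromatogram peak areas
#'
#' \code{100 * area_sample / area_control} percent; scale-invariant in the
#' common factor of the two areas.
#'
#' @param area_sample Peak area with inhibitor (>= 0).
#' @param area_control Peak area of the no-inhibitor control (> 0).
#' @return Percent residual activity.
#' @export
residual_activity <- function(area_sample, area_control) {
  if (any(area_control <= 0)) stop("control area must be positive")
  if (any(area_sample < 0)) stop("sample area must be non-negative")
  100 * area_sample / area_control
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of \code{v = Vmax S / (Km + S)} with starting
#' values Vmax0 = max observed rate and Km0 = substrate concentration at
#' half-maximal rate, bounded to positive parameters.
#'
#' @param data Data frame with \code{substrate_conc_uM} and
#'   \code{rate_uM_min} (one inhibitor concentration at a time), or two
#'   numeric vectors via \code{substrate_conc} / \code{rate}.
#' @param substrate_conc,rate Optional numeric vectors instead of
#'   \code{data}.
#' @return Object of class \code{"mm_fit"}: list with \code{km},
#'   \code{vmax}, \code{se} (named), \code{rss}, \code{n}, \code{fit}.
#' @export
fit_michaelis_menten <- function(data = NULL, substrate_conc = NULL,
                                 rate = NULL) {
  if (!is.null(data)) {
    substrate_conc <- data$substrate_conc_uM
    rate <- data$rate_uM_min
  }
  stopifnot(length(substrate_conc) == length(rate))
  if (length(unique(substrate_conc)) < 4)
    stop("need at least 4 distinct substrate concentrations")
  d <- data.frame(S = substrate_conc, v = rate)
  vmax0 <- max(d$v)
  km0 <- d$S[which.min(abs(d$v - vmax0 / 2))]
  if (km0 <= 0) km0 <- median(d$S)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = d,
                           start = list(Vmax = vmax0, Km = km0),
                           lower = c(Vmax = 1e-12, Km = 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  if (any(cf <= 0)) stop("Michaelis-Menten fit returned a non-positive ",
                         "parameter")
  structure(list(km = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
                 se = c(km = unname(se["Km"]), vmax = unname(se["Vmax"])),
                 rss = sum(residuals(fit)^2), n = nrow(d), fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d): Km = %.4g uM, Vmax = %.4g uM/min\n",
              x$n, x$km, x$vmax))
  invisible(x)
}

#' Fold change of a kinetic parameter under an inhibitor
#'
#' Plain ratio \code{param_with_inhibitor / param_control}; rounding to the
#' conventional two decimals happens only at reporting time
#' (\code{\link{format_fold_change}}).
#'
#' @param param_with_inhibitor,param_control Positive parameter values.
#' @return The unrounded ratio.
#' @export
fold_change <- function(param_with_inhibitor, param_control) {
  if (any(param_control <= 0)) stop("control parameter must be positive")
  if (any(param_with_inhibitor <= 0)) stop("parameter must be positive")
  param_with_inhibitor / param_control
}

#' @rdname fold_change
#' @param x A fold change.
#' @param digits Decimals for presentation.
#' @export
format_fold_change <- function(x, digits = 2) round(x, digits)

#' Classify inhibition type from Km and Vmax fold changes
#'
#' "Unchanged" means the fold change is within \code{tol} of 1. Decision
#' table: Km up with Vmax unchanged is competitive; Km unchanged with Vmax
#' down is noncompetitive; both down is uncompetitive; Km up with Vmax down
#' is mixed; both unchanged is none (combinations outside the table, e.g. a
#' Vmax increase, also return none).
#'
#' @param km_fold,vmax_fold Positive fold changes (inhibitor / control).
#' @param tol Relative tolerance defining "unchanged" (default 0.15; the
#'   conventional qualitative reading treats 1.04 as unchanged and 1.28 as
#'   increased).
#' @return Object of class \code{"inhibition_call"}: list with \code{type},
#'   \code{km_fold}, \code{vmax_fold}, \code{tol}.
#' @export
classify_inhibition <- function(km_fold, vmax_fold, tol = 0.15) {
  stopifnot(km_fold > 0, vmax_fold > 0)
  km_state <- if (abs(km_fold - 1) <= tol) "unchanged"
    else if (km_fold > 1) "up" else "down"
  v_state <- if (abs(vmax_fold - 1) <= tol) "unchanged"
    else if (vmax_fold > 1) "up" else "down"
  type <- if (km_state == "up" && v_state == "unchanged") "competitive"
    else if (km_state == "unchanged" && v_state == "down") "noncompetitive"
    else if (km_state == "down" && v_state == "down") "uncompetitive"
    else if (km_state == "up" && v_state == "down") "mixed"
    else "none"
  structure(list(type = type, km_fold = km_fold, vmax_fold = vmax_fold,
                 tol = tol), class = "inhibition_call")
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat(sprintf("inhibition: %s (Km fold %.2f, Vmax fold %.2f, tol %.2f)\n",
              x$type, x$km_fold, x$vmax_fold, x$tol))
  invisible(x)
}

#' Dixon regression: 1/v against inhibitor concentration
#'
#' Ordinary least squares of \code{1/v} on \code{[I]} per substrate
#' concentration; the intersection geometry of the lines diagnoses the
#' inhibition type: intersection above the I-axis at negative \code{[I]} is
#' competitive, on the I-axis at negative \code{[I]} noncompetitive,
#' parallel lines uncompetitive, and flat lines mean no inhibition.
#'
#' @param data Data frame with \code{substrate_conc_uM},
#'   \code{inhibitor_conc_uM} and \code{rate_uM_min}; needs >= 2 substrate
#'   concentrations with >= 3 inhibitor concentrations each. Zero rates
#'   (1/v undefined) are dropped with a message.
#' @param slope_rtol Relative slope difference below which lines count as
#'   parallel.
#' @param height_rtol Intersection heights below this fraction of the
#'   typical intercept count as "on the axis".
#' @return Object of class \code{"dixon_fit"}: list with \code{lines}
#'   (data frame \code{substrate_conc_uM, intercept, slope}),
#'   \code{intersection} (\code{i}, \code{inv_v}, possibly NA), and
#'   \code{type}.
#' @export
dixon_regression <- function(data, slope_rtol = 0.05, height_rtol = 0.05) {
  zero <- data$rate_uM_min <= 0
  if (any(zero)) {
    message(sum(zero), " zero-rate point(s) excluded from Dixon regression")
    data <- data[!zero, , drop = FALSE]
  }
  ss <- sort(unique(data$substrate_conc_uM))
  if (length(ss) < 2) stop("need at least 2 substrate concentrations")
  lines <- lapply(ss, function(s) {
    d <- data[data$substrate_conc_uM == s, ]
    if (length(unique(d$inhibitor_conc_uM)) < 3)
      stop("need at least 3 inhibitor concentrations per substrate level")
    fit <- lm(I(1 / rate_uM_min) ~ inhibitor_conc_uM, data = d)
    data.frame(substrate_conc_uM = s, intercept = coef(fit)[1],
               slope = coef(fit)[2])
  })
  lines <- do.call(rbind, lines)
  rownames(lines) <- NULL

  s1 <- lines$slope[1]; s2 <- lines$slope[nrow(lines)]
  b1 <- lines$intercept[1]; b2 <- lines$intercept[nrow(lines)]
  slope_scale <- max(abs(c(s1, s2)))
  flat <- slope_scale < 1e-12 ||
    slope_scale * max(data$inhibitor_conc_uM) <
      1e-6 * max(abs(lines$intercept))
  parallel <- !flat && abs(s1 - s2) < slope_rtol * slope_scale
  if (flat) {
    type <- "none"
    intersection <- list(i = NA_real_, inv_v = NA_real_)
  } else if (parallel) {
    type <- "uncompetitive"
    intersection <- list(i = NA_real_, inv_v = NA_real_)
  } else {
    xi <- (b2 - b1) / (s1 - s2)
    yi <- b1 + s1 * xi
    on_axis <- abs(yi) < height_rtol * max(abs(lines$intercept))
    type <- if (xi < 0 && yi > 0 && !on_axis) "competitive"
      else if (xi < 0 && on_axis) "noncompetitive"
      else "undetermined"
    intersection <- list(i = xi, inv_v = yi)
  }
  structure(list(lines = lines, intersection = intersection, type = type),
            class = "dixon_fit")
}

#' @export
print.dixon_fit <- function(x, ...) {
  cat("Dixon regression over", nrow(x$lines), "substrate levels; type:",
      x$type, "\n")
  if (is.finite(x$intersection$i))
    cat(sprintf("  intersection at [I] = %.4g uM, 1/v = %.4g\n",
                x$intersection$i, x$intersection$inv_v))
  invisible(x)
}

#' Four-parameter logistic IC50 fit
#'
#' Fits \code{activity = bottom + (top - bottom) / (1 + (conc / ic50)^hill)}
#' to residual-activity (%) data. The direction is checked: activity must
#' decrease with concentration.
#'
#' @param inhibitor_conc Concentrations (uM), at least 5 spanning the
#'   transition.
#' @param residual_activity Residual activities (%).
#' @return Object of class \code{"ic50_fit"}: list with \code{ic50},
#'   \code{hill}, \code{top}, \code{bottom}, \code{se} (IC50 standard
#'   error), \code{fit}.
#' @export
fit_ic50 <- function(inhibitor_conc, residual_activity) {
  stopifnot(length(inhibitor_conc) == length(residual_activity))
  if (length(unique(inhibitor_conc)) < 5)
    stop("need at least 5 concentrations")
  d <- data.frame(x = inhibitor_conc, y = residual_activity)
  dir <- cor(d$x, d$y, method = "spearman")
  if (is.na(dir) || dir >= 0)
    stop("activity does not decrease with concentration: IC50 not ",
         "determinable")
  top0 <- max(d$y); bot0 <- min(d$y)
  mid <- (top0 + bot0) / 2
  ic0 <- d$x[which.min(abs(d$y - mid))]
  if (ic0 <= 0) ic0 <- median(d$x[d$x > 0])
  pl4 <- function(p) p["bottom"] + (p["top"] - p["bottom"]) /
    (1 + (d$x / p["ic50"])^p["hill"])
  fit <- minpack.lm::nls.lm(
    par = c(top = top0, bottom = bot0, ic50 = ic0, hill = 1),
    fn = function(p) d$y - pl4(p),
    lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12, hill = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- fit$par
  if (cf["bottom"] >= cf["top"]) stop("degenerate logistic fit")
  se <- tryCatch(summary(fit)$coefficients["ic50", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 se = se, fit = fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g uM (hill %.3g, asymptotes %.3g-%.3g%%)\n",
              x$ic50, x$hill, x$bottom, x$top))
  invisible(x)
}

#' Substrate-selectivity ratio of two Km values
#'
#' @param km_a,km_b Positive Km values (uM); the ratio \code{km_a / km_b}
#'   compares the enzyme's handling of substrate a vs b.
#' @param digits Decimals at reporting time (default 2).
#' @return Rounded ratio.
#' @export
selectivity_ratio <- function(km_a, km_b, digits = 2) {
  if (any(km_b <= 0) || any(km_a <= 0)) stop("Km values must be positive")
  round(km_a / km_b, digits)
}

#' Kinetics comparison report for control vs inhibitors
#'
#' Fits plain Michaelis-Menten curves per (substrate, inhibitor) series and
#' lays out Km/Vmax, fold-change rows against the control and
#' cross-substrate selectivity ratios.
#'
#' @param data Data frame with columns \code{substrate}, \code{inhibitor},
#'   \code{substrate_conc_uM}, \code{inhibitor_conc_uM},
#'   \code{rate_uM_min}; the control series has \code{inhibitor == "control"}
#'   (or \code{inhibitor_conc_uM == 0}).
#' @param tol Fold-change tolerance for \code{\link{classify_inhibition}}.
#' @return List with \code{parameters} (per substrate/inhibitor Km, Vmax),
#'   \code{fold_changes} (with inhibition calls) and \code{selectivity}
#'   (per inhibitor Km and Vmax ratios across substrate pairs).
#' @export
kinetics_report <- function(data, tol = 0.15) {
  data$inhibitor[data$inhibitor_conc_uM == 0] <- "control"
  combos <- unique(data[, c("substrate", "inhibitor")])
  params <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    d <- data[data$substrate == combos$substrate[i] &
                data$inhibitor == combos$inhibitor[i], ]
    fit <- fit_michaelis_menten(d)
    data.frame(substrate = combos$substrate[i],
               inhibitor = combos$inhibitor[i],
               km_uM = fit$km, vmax_uM_min = fit$vmax,
               stringsAsFactors = FALSE)
  }))
  fold <- NULL
  for (s in unique(params$substrate)) {
    ctrl <- params[params$substrate == s & params$inhibitor == "control", ]
    if (!nrow(ctrl)) next
    for (inh in setdiff(params$inhibitor[params$substrate == s],
                        "control")) {
      p <- params[params$substrate == s & params$inhibitor == inh, ]
      kf <- fold_change(p$km_uM, ctrl$km_uM)
      vf <- fold_change(p$vmax_uM_min, ctrl$vmax_uM_min)
      call <- classify_inhibition(kf, vf, tol)
      fold <- rbind(fold, data.frame(substrate = s, inhibitor = inh,
                                     km_fold = kf, vmax_fold = vf,
                                     type = call$type,
                                     stringsAsFactors = FALSE))
    }
  }
  subs <- unique(params$substrate)
  sel <- NULL
  if (length(subs) >= 2) {
    for (inh in unique(params$inhibitor)) {
      p <- params[params$inhibitor == inh, ]
      if (nrow(p) < 2) next
      a <- p[p$substrate == subs[1], ]; b <- p[p$substrate == subs[2], ]
      if (!nrow(a) || !nrow(b)) next
      sel <- rbind(sel, data.frame(
        inhibitor = inh,
        ratio = paste0(subs[1], "/", subs[2]),
        km_ratio = selectivity_ratio(a$km_uM, b$km_uM),
        vmax_ratio = round(a$vmax_uM_min / b$vmax_uM_min, 2),
        stringsAsFactors = FALSE))
    }
  }
  list(parameters = params, fold_changes = fold, selectivity = sel)
}
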