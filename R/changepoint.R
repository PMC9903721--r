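## Piecewise linear regression with an estimated break point, and the
## m-value (motif-intrinsic score boundary) aggregated across element x cell
## combinations.

#' Fit a one-break piecewise linear regression
#'
#' Iterative linearization in the style of Muggeo's segmented regression: at
#' the current break `psi`, regress `y` on `{x, U = pmax(x - psi, 0),
#' V = -1[x > psi]}` and update `psi <- psi + coef(V) / coef(U)` until the
#' update falls below `tol`; the update is step-halved whenever it would
#' increase the segmented residual sum of squares, so the iteration settles
#' instead of oscillating. The break is kept strictly inside the observed
#' x-range. The slope-change p-value is the t-test of the `U` coefficient in
#' the final refit at the converged break.
#'
#' @param x predictor (e.g. motif log2-odds scores).
#' @param y response (e.g. motif contributions).
#' @param psi0 initial break point (default 20); must be spanned by `x`.
#' @param tol convergence tolerance on the break update.
#' @param max_iter maximum iterations.
#' @return an object of class `changepoint_fit`: `intercept`, `slope_below`,
#'   `slope_above`, `psi`, `psi_se`, `slope_change`, `slope_change_p`,
#'   `r_squared`, `converged`, `n_points`, `iterations`, `message`.
#' @export
fit_piecewise <- function(x, y, psi0 = 20, tol = 1e-6, max_iter = 100L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  bad_fit <- function(msg) {
    structure(list(intercept = NA_real_, slope_below = NA_real_,
                   slope_above = NA_real_, psi = NA_real_, psi_se = NA_real_,
                   slope_change = NA_real_, slope_change_p = NA_real_,
                   r_squared = NA_real_, converged = FALSE, n_points = n,
                   iterations = 0L, message = msg),
              class = "changepoint_fit")
  }
  if (n < 10L) return(bad_fit("fewer than 10 points"))
  eps <- 1e-8 * diff(range(x)) + 1e-12
  lo <- min(x) + eps; hi <- max(x) - eps
  ## grid-assisted start: seed the iteration from the best of psi0 and a
  ## coarse interior grid, so it settles in the global RSS basin
  cand <- unique(pmin(pmax(c(psi0, quantile(x, seq(0.05, 0.95, by = 0.05),
                                            names = FALSE)), lo), hi))
  rss0 <- vapply(cand, function(p) {
    sum(lm(y ~ x + pmax(x - p, 0))$residuals^2)
  }, numeric(1))
  psi <- cand[which.min(rss0)]
  converged <- FALSE
  psi_se <- NA_real_
  it <- 0L
  note <- NULL
  res <- tryCatch({
    for (it in seq_len(max_iter)) {
      U <- pmax(x - psi, 0)
      V <- -as.numeric(x > psi)
      fit <- suppressWarnings(lm(y ~ x + U + V))
      cf <- coef(fit)
      if (anyNA(cf) || abs(cf[["U"]]) < 1e-12) {
        ## no estimable slope change at this break: stop updating and let
        ## the final refit report the (near-zero) slope change honestly
        note <- "no slope change estimable at the current break"
        break
      }
      step <- cf[["V"]] / cf[["U"]]
      ## damp the update: halve the step until the segmented RSS does not
      ## increase, so the iteration cannot oscillate around the optimum
      rss_at <- function(p) {
        sum(lm(y ~ x + pmax(x - p, 0))$residuals^2)
      }
      cur_rss <- rss_at(psi)
      psi_new <- psi
      h <- step
      for (halving in seq_len(30L)) {
        cand <- min(max(psi + h, lo), hi)
        if (rss_at(cand) <= cur_rss + 1e-12) {
          psi_new <- cand
          break
        }
        h <- h / 2
      }
      done <- abs(psi_new - psi) < tol
      psi <- psi_new
      if (done) {
        converged <- TRUE
        vc <- suppressWarnings(vcov(fit))
        g <- cf[["V"]] / cf[["U"]]
        psi_se <- sqrt(max(0, (vc["V", "V"] + g^2 * vc["U", "U"] -
                                 2 * g * vc["U", "V"]))) / abs(cf[["U"]])
        break
      }
    }
    NULL
  }, error = function(e) bad_fit(conditionMessage(e)))
  if (!is.null(res)) return(res)

  ## final refit at the (possibly unconverged) break, without V
  U <- pmax(x - psi, 0)
  fit <- suppressWarnings(lm(y ~ x + U))
  sm <- suppressWarnings(summary(fit))
  cf <- coef(sm)
  if (!all(c("x", "U") %in% rownames(cf))) {
    return(bad_fit("regression terms dropped in final refit (degenerate design)"))
  }
  if (sm$sigma < 1e-10) {
    ## perfect fit: the data speak unequivocally about the break term
    cf["U", 4] <- if (abs(cf["U", 1]) < 1e-8) 1 else 0
  }
  structure(list(intercept = cf["(Intercept)", 1],
                 slope_below = cf["x", 1],
                 slope_above = cf["x", 1] + cf["U", 1],
                 psi = psi, psi_se = psi_se,
                 slope_change = cf["U", 1],
                 slope_change_p = cf["U", 4],
                 r_squared = sm$r.squared,
                 converged = converged, n_points = n,
                 iterations = it, x_range = range(x),
                 message = if (converged) "ok" else note %||% "max iterations reached"),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("changepoint_fit: psi = %.4f (se %.4f), slopes %.4f -> %.4f, slope-change p = %.3g, R2 = %.3f, %s (n = %d)\n",
              x$psi, x$psi_se, x$slope_below, x$slope_above,
              x$slope_change_p, x$r_squared,
              if (x$converged) "converged" else "NOT converged", x$n_points))
  invisible(x)
}

#' Aggregate break points into the m-value
#'
#' Fits are excluded when non-converged, when the slope change is not
#' positive, when the slope-change p-value is at or above `slope_p_max`
#' (the operational reading of requiring an obvious shift of the
#' correlation), when the break-point standard error reaches
#' `max_psi_se` (a break whose location is essentially unidentified
#' carries no information about the score boundary), or when the break sits
#' in the outer `edge_frac` of the fitted score range (break-free series
#' typically park their best kink at a range boundary, where almost no
#' points support one of the two slopes). The m-value is the arithmetic
#' mean of the remaining break points.
#'
#' @param fits named list of [fit_piecewise()] results, keyed by element x
#'   cell combination.
#' @param slope_p_max exclusion threshold on the slope-change p-value.
#' @param max_psi_se exclusion threshold on the break-point standard error,
#'   in score units (`NULL` disables).
#' @param edge_frac fraction of the score range treated as the edge
#'   (`NULL` disables).
#' @return list with `m_value`, `sd`, `included` (keys), `excluded`
#'   (named reasons).
#' @export
estimate_m_value <- function(fits, slope_p_max = 0.05, max_psi_se = 1,
                             edge_frac = 0.1) {
  stopifnot(length(fits) >= 2L)
  keys <- names(fits) %||% sprintf("fit%02d", seq_along(fits))
  reasons <- setNames(character(length(fits)), keys)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    reasons[i] <- if (!isTRUE(f$converged)) "not converged"
    else if (is.na(f$slope_change) || f$slope_change <= 0) "slope change not positive"
    else if (is.na(f$slope_change_p) || f$slope_change_p >= slope_p_max) "slope change not significant"
    else if (!is.null(max_psi_se) && isTRUE((f$psi_se %||% NA_real_) >= max_psi_se))
      "break point not identified"
    else if (!is.null(edge_frac) && !is.null(f$x_range) &&
             (f$psi < f$x_range[1] + edge_frac * diff(f$x_range) ||
                f$psi > f$x_range[2] - edge_frac * diff(f$x_range)))
      "break at the edge of the score range"
    else ""
  }
  keep <- reasons == ""
  if (!any(keep)) stop("all fits excluded by the m-value outlier rule")
  psis <- vapply(fits[keep], `[[`, numeric(1), "psi")
  list(m_value = mean(psis), sd = if (sum(keep) > 1L) sd(psis) else NA_real_,
       included = keys[keep], excluded = reasons[!keep])
}
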