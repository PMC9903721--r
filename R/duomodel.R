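## Log-additive interaction model relating single-library activities to duo
## activities: eDuo ~ beta0 + betaS*eS + betaE*eE + betaSE*eS*eE.

#' Fit the log-additive duo model
#'
#' Ordinary least squares of the duo activity on the two single activities
#' and their interaction.
#'
#' @param eS,eE,eDuo aligned log2 activities (n >= 10).
#' @param orientation label (`"ES"` or `"SE"`) carried into the fit object.
#' @param interaction include the `eS * eE` term (default TRUE); without it
#'   `betaSE` is fixed at 0 (ablation mode).
#' @return an object of class `duo_model_fit` with `beta0`, `betaS`, `betaE`,
#'   `betaSE`, `r_squared`, `n`, `orientation`.
#' @export
fit_log_additive <- function(eS, eE, eDuo, orientation = "ES",
                             interaction = TRUE) {
  stopifnot(length(eS) == length(eE), length(eE) == length(eDuo))
  ok <- complete.cases(eS, eE, eDuo)
  eS <- eS[ok]; eE <- eE[ok]; eDuo <- eDuo[ok]
  if (length(eDuo) < 10L) stop("need at least 10 aligned activity triples")
  fit <- if (interaction) lm(eDuo ~ eS * eE) else lm(eDuo ~ eS + eE)
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient design: coefficients not identifiable")
  structure(list(beta0 = unname(cf["(Intercept)"]),
                 betaS = unname(cf["eS"]), betaE = unname(cf["eE"]),
                 betaSE = if (interaction) unname(cf["eS:eE"]) else 0,
                 r_squared = summary(fit)$r.squared,
                 n = length(eDuo), orientation = orientation,
                 residuals = stats::resid(fit),
                 model = list(eS = eS, eE = eE)),
            class = "duo_model_fit")
}

#' @export
print.duo_model_fit <- function(x, ...) {
  cat(sprintf("duo_model_fit (%s): eDuo = %.2f + %.2f*eS + %.2f*eE + %.2f*eS*eE (R2 = %.2f, n = %d)\n",
              x$orientation, x$beta0, x$betaS, x$betaE, x$betaSE,
              x$r_squared, x$n))
  invisible(x)
}

#' Predict duo activity from single activities
#'
#' @param fit a [fit_log_additive()] result.
#' @param eS,eE single-element log2 activities.
#' @return predicted duo activity
#'   `beta0 + betaS*eS + betaE*eE + betaSE*eS*eE`.
#' @export
predict_duo <- function(fit, eS, eE) {
  stopifnot(inherits(fit, "duo_model_fit"))
  fit$beta0 + fit$betaS * eS + fit$betaE * eE + fit$betaSE * eS * eE
}
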