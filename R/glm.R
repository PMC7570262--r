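## Quasibinomial logit regression with Type III analysis of deviance.
## The fitter is iteratively reweighted least squares on the logit link;
## dispersion is the Pearson statistic over residual df; Type III tests
## compare the full model with models whose term columns are deleted,
## under sum-to-zero factor coding (Type III is ill-defined under
## treatment contrasts).

.irlsQuasibinomial <- function(X, y, w, epsilon = 1e-10, maxit = 100L) {
  devfun <- function(mu) sum(stats::binomial()$dev.resids(y, mu, w))
  mu <- (w * y + 0.5) / (w + 1)
  eta <- qlogis(mu)
  dev <- devfun(mu)
  trace <- numeric(0)  # deviances of model-space iterates only
  for (it in seq_len(maxit)) {
    varmu <- mu * (1 - mu)
    z <- eta + (y - mu) / varmu
    wls <- lm.wfit(X, z, w * varmu)
    beta <- wls$coefficients
    ok <- !is.na(beta)
    eta_new <- drop(X[, ok, drop = FALSE] %*% beta[ok])
    ## The starting values lie outside the model space (mu ~ y), so the
    ## first step is taken unguarded; from then on, step-halve toward the
    ## previous iterate if the deviance worsens, so the deviance path is
    ## non-increasing (also guards separation).
    for (h in 0:25) {
      eta_try <- if (h == 0) eta_new else (eta_try + eta) / 2
      mu_try <- plogis(eta_try)
      dev_try <- devfun(mu_try)
      if (it == 1L || (is.finite(dev_try) && dev_try <= dev + 1e-12))
        break
    }
    eta <- eta_try; mu <- mu_try
    dev_old <- dev; dev <- dev_try
    trace <- c(trace, dev)
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon) {
      return(list(coefficients = beta, eta = eta, fitted = mu,
                  deviance = dev, iter = it, converged = TRUE,
                  rank = wls$rank, pivot = wls$qr$pivot, trace = trace))
    }
  }
  stop("IRLS did not converge in ", maxit, " iterations; deviance trace: ",
       paste(sprintf("%.6g", utils::tail(trace, 8L)), collapse = " -> "),
       call. = FALSE)
}

#' Quasibinomial logit GLM with Type III deviance tests
#'
#' Fits a quasibinomial generalized linear model with logit link by
#' iteratively reweighted least squares (relative deviance change below
#' `1e-10` or 100 iterations), with the dispersion estimated as the
#' Pearson chi-squared statistic over the residual degrees of freedom.
#' Factors are coded sum-to-zero throughout; for each model term a
#' Type III F test compares the full model with the model whose columns
#' for that term are deleted, all other columns retained:
#' `F = (deviance difference / term df) / dispersion`.
#'
#' Typical uses on packet data: the retained seed pool model (response =
#' proportion of retained seed per merged packet row, weighted by the
#' number of seeds recovered) and the staining model (response = stain
#' presence on individual assayed seeds, unweighted Bernoulli rows).
#'
#' @param formula Model formula; the response is a proportion in \[0, 1\].
#'   All right-hand-side variables must be factors (or coercible) with at
#'   least 2 levels.
#' @param data data.frame holding response and predictors.
#' @param weights Numeric vector of prior weights (binomial totals, e.g.
#'   seeds recovered); default all 1.
#' @return An object of class `qbglm`: list with `coefficients`, `fitted`,
#'   `deviance`, `dispersion`, `df_residual`, `rank`, `iter`,
#'   `deviance_trace`, `separation` flag, and `table`, the Type III
#'   analysis-of-deviance data.frame (one row per term: `term`, `sum_sq`,
#'   `df`, `f_value`, `p_value`, plus a residual row). The table carries
#'   attributes `dispersion`, `family`, `link`, `weights_description` and
#'   `p_values_approximate` (set when dispersion > 2: quasibinomial
#'   scaling does not remove all overdispersion and p-values should be
#'   read as approximate).
#' @seealso [devianceTable()]
#' @examples
#' d <- expand.grid(f = c("a", "b"), g = c("u", "v", "w"),
#'                  rep = 1:10, KEEP.OUT.ATTRS = FALSE)
#' d$w <- 20
#' set.seed(1)
#' d$y <- rbinom(nrow(d), 20, ifelse(d$f == "a", 0.3, 0.5)) / 20
#' fit <- fitQuasibinomialGLM(y ~ f * g, d, weights = d$w)
#' devianceTable(fit)
#' @export
fitQuasibinomialGLM <- function(formula, data, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(weights)
  if (length(w) != nrow(data)) stop("weights must match rows of data",
                                    call. = FALSE)
  cc <- complete.cases(data[, all.vars(formula), drop = FALSE]) & !is.na(w)
  data <- data[cc, , drop = FALSE]
  w <- w[cc]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  mf <- model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (any(y < 0 | y > 1)) stop("response proportions must lie in [0, 1]",
                               call. = FALSE)
  n <- length(y)
  tt <- terms(mf)
  vars <- attr(tt, "term.labels")
  for (v in all.vars(stats::delete.response(tt))) {
    mf[[v]] <- as.factor(mf[[v]])
    if (nlevels(mf[[v]]) < 2L)
      stop("predictor '", v, "' needs at least 2 levels", call. = FALSE)
  }
  contrasts_arg <- setNames(
    rep(list("contr.sum"), length(all.vars(stats::delete.response(tt)))),
    all.vars(stats::delete.response(tt)))
  X <- model.matrix(tt, mf, contrasts.arg = contrasts_arg)
  asn <- attr(X, "assign")
  fit <- .irlsQuasibinomial(X, y, w)
  df_res <- n - fit$rank
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  pearson <- sum(w * (y - fit$fitted)^2 /
                   (fit$fitted * (1 - fit$fitted)))
  dispersion <- pearson / df_res
  separation <- any(abs(fit$eta) > 12) ||
    any(fit$fitted < 1e-8 | fit$fitted > 1 - 1e-8)
  if (separation)
    warning("possible separation: fitted proportions at the boundary; ",
            "coefficients reported but unreliable")
  nterms <- length(vars)
  sum_sq <- df <- f_value <- p_value <- numeric(nterms)
  for (t in seq_len(nterms)) {
    keep <- asn != t
    Xr <- X[, keep, drop = FALSE]
    fr <- .irlsQuasibinomial(Xr, y, w)
    sum_sq[t] <- fr$deviance - fit$deviance
    df[t] <- fit$rank - fr$rank
    f_value[t] <- if (df[t] > 0) (sum_sq[t] / df[t]) / dispersion else NA
    p_value[t] <- if (df[t] > 0)
      pf(f_value[t], df[t], df_res, lower.tail = FALSE) else NA
  }
  tab <- data.frame(
    term = c(vars, "residuals"),
    sum_sq = c(sum_sq, fit$deviance),
    df = c(df, df_res),
    f_value = c(f_value, NA),
    p_value = c(p_value, NA),
    stringsAsFactors = FALSE
  )
  attr(tab, "dispersion") <- dispersion
  attr(tab, "family") <- "quasibinomial"
  attr(tab, "link") <- "logit"
  attr(tab, "type") <- "III (sum-to-zero contrasts, column deletion)"
  attr(tab, "weights_description") <-
    if (is.null(weights)) "unweighted (all 1)" else
      "prior weights supplied (binomial totals)"
  attr(tab, "p_values_approximate") <- dispersion > 2
  structure(list(
    coefficients = fit$coefficients,
    fitted = fit$fitted,
    linear_predictor = fit$eta,
    deviance = fit$deviance,
    deviance_trace = fit$trace,
    dispersion = dispersion,
    df_residual = df_res,
    rank = fit$rank,
    n = n,
    iter = fit$iter,
    converged = fit$converged,
    separation = separation,
    table = tab,
    terms = tt
  ), class = "qbglm")
}

#' Type III analysis-of-deviance table of a fitted quasibinomial GLM
#'
#' @param fit A `qbglm` object from [fitQuasibinomialGLM()].
#' @return The deviance table data.frame (see [fitQuasibinomialGLM()]).
#' @export
devianceTable <- function(fit) {
  stopifnot(inherits(fit, "qbglm"))
  fit$table
}

#' @export
print.qbglm <- function(x, ...) {
  cat("Quasibinomial logit GLM (IRLS,", x$iter, "iterations)\n")
  cat(sprintf("  n = %d, rank = %d, residual df = %d\n",
              x$n, x$rank, x$df_residual))
  cat(sprintf("  residual deviance = %.4f, dispersion (Pearson) = %.4f\n",
              x$deviance, x$dispersion))
  if (attr(x$table, "p_values_approximate"))
    cat("  note: dispersion > 2; p-values are approximate\n")
  if (x$separation)
    cat("  warning: possible separation\n")
  cat("\nType III deviance tests (sum-to-zero contrasts):\n")
  tab <- x$table
  tab$sum_sq <- sprintf("%.3f", tab$sum_sq)
  tab$f_value <- ifelse(is.na(tab$f_value), "",
                        sprintf("%.3f", tab$f_value))
  tab$p_value <- ifelse(is.na(tab$p_value), "",
                        format.pval(tab$p_value, digits = 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
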