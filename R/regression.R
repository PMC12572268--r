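#' Fit the log-linear service-count model by OLS
#'
#' Ordinary least squares on the assembled design, with Gaussian
#' log-likelihood, AIC (parameter count includes the intercept and the error
#' variance), per-coefficient standard errors and two-sided t-test p-values.
#'
#' @param design An `anc_design`.
#' @param terms Model terms; defaults to the design's own term attribute.
#' @return A `fitted_model` object.
#' @export
fit_ols <- function(design, terms = attr(design, "terms")) {
  if (length(terms) == 0L) stop("no model terms supplied", call. = FALSE)
  missing_cols <- setdiff(terms, names(design))
  if (length(missing_cols) > 0L) {
    stop("design lacks term columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  dat <- design[, c("response", terms), drop = FALSE]
  n <- nrow(dat)
  if (n <= length(terms) + 1L) {
    stop("more parameters than observations (n = ", n, ")", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "response ~", paste(sprintf("`%s`", terms), collapse = " + ")
  ))
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(
      "design is rank deficient; linearly dependent columns: ",
      paste(gsub("`", "", aliased), collapse = ", "),
      call. = FALSE
    )
  }
  smry <- summary(fit)
  coefs <- smry$coefficients
  nm <- gsub("`", "", rownames(coefs))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L # + error variance
  structure(
    list(
      terms = terms,
      coefficients = stats::setNames(coefs[, 1L], nm),
      se = stats::setNames(coefs[, 2L], nm),
      p_values = stats::setNames(coefs[, 4L], nm),
      loglik = ll,
      aic = 2 * k - 2 * ll,
      n_obs = n,
      adj_r2 = smry$adj.r.squared,
      sigma = smry$sigma
    ),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(
    "fitted_model:", length(x$terms), "terms, n =", x$n_obs,
    ", AIC =", round(x$aic, 1), ", adj R^2 =", round(x$adj_r2, 4), "\n"
  )
  tab <- data.frame(
    estimate = signif(x$coefficients, 5),
    se = signif(x$se, 4),
    p = signif(x$p_values, 3)
  )
  print(tab)
  invisible(x)
}

#' Backward stepwise AIC selection over precipitation terms
#'
#' Starting from the full model (fixed plus candidate terms), repeatedly
#' removes the single candidate whose removal most decreases AIC, until no
#' removal decreases it. Fixed terms are never removed. Ties in AIC
#' improvement are broken by removing the candidate with the larger
#' coefficient p-value in the current model.
#'
#' @param design An `anc_design` containing all fixed and candidate columns.
#' @param fixed_terms Terms always retained (the non-climate covariates).
#' @param candidate_terms Terms eligible for removal (the precipitation
#'   indices).
#' @return List with `model` (the final refitted `fitted_model`), `path`
#'   (data.frame of the removal sequence with the AIC after each step), and
#'   `retained` (surviving candidates).
#' @export
backward_stepwise <- function(design, fixed_terms, candidate_terms) {
  stopifnot(length(fixed_terms) > 0L)
  current <- fit_ols(design, c(fixed_terms, candidate_terms))
  path <- data.frame(
    removed = NA_character_, aic = current$aic, stringsAsFactors = FALSE
  )
  candidates <- candidate_terms
  while (length(candidates) > 0L) {
    trial_aic <- vapply(candidates, function(tm) {
      fit_ols(design, setdiff(c(fixed_terms, candidates), tm))$aic
    }, numeric(1L))
    best <- min(trial_aic)
    if (best >= current$aic) break
    tied <- candidates[trial_aic == best]
    drop_term <- if (length(tied) > 1L) {
      tied[which.max(current$p_values[tied])]
    } else {
      tied
    }
    candidates <- setdiff(candidates, drop_term)
    current <- fit_ols(design, c(fixed_terms, candidates))
    path <- rbind(path, data.frame(removed = drop_term, aic = current$aic))
  }
  list(model = current, path = path, retained = candidates)
}

#' Likelihood-ratio test between nested fitted models
#'
#' @param m0 The restricted `fitted_model` (terms a subset of `m1`'s).
#' @param m1 The full `fitted_model`, fitted on the same observations.
#' @return An `lr_test` list: `statistic` (`2 * (loglik1 - loglik0)`), `df`
#'   (difference in estimated parameters), `p_value` (upper-tail chi-squared).
#' @export
likelihood_ratio_test <- function(m0, m1) {
  if (!all(m0$terms %in% m1$terms)) {
    stop("models are not nested: some m0 terms are absent from m1", call. = FALSE)
  }
  if (m0$n_obs != m1$n_obs) {
    stop(
      "models fitted on different observation counts: ",
      m0$n_obs, " vs ", m1$n_obs,
      call. = FALSE
    )
  }
  stat <- 2 * (m1$loglik - m0$loglik)
  df <- length(m1$coefficients) - length(m0$coefficients)
  structure(
    list(
      statistic = stat,
      df = df,
      p_value = if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    ),
    class = "lr_test"
  )
}

#' @export
print.lr_test <- function(x, ...) {
  cat(
    "Likelihood ratio test: LR =", round(x$statistic, 2), "on", x$df,
    "df, p =", signif(x$p_value, 3), "\n"
  )
  invisible(x)
}

#' Plain-text coefficient report for paired models
#'
#' A side-by-side table of coefficients and p-values for the
#' precipitation-free and precipitation models, significance-starred at
#' p < 0.05.
#'
#' @param m0,m1 `fitted_model` objects.
#' @return Character vector of report lines (also printed invisibly usable
#'   with `writeLines`).
#' @export
model_report <- function(m0, m1) {
  all_terms <- union(names(m0$coefficients), names(m1$coefficients))
  fmt <- function(m, tm) {
    if (!tm %in% names(m$coefficients)) return(c("", ""))
    star <- if (m$p_values[[tm]] < 0.05) "*" else ""
    c(signif(m$coefficients[[tm]], 4), paste0(signif(m$p_values[[tm]], 3), star))
  }
  rows <- vapply(all_terms, function(tm) c(fmt(m0, tm), fmt(m1, tm)), character(4L))
  tab <- cbind(term = all_terms, t(rows))
  colnames(tab) <- c("term", "M0", "p(M0)", "M1", "p(M1)")
  widths <- apply(nchar(rbind(colnames(tab), tab)), 2L, max)
  line <- function(v) paste(mapply(formatC, v, width = widths, flag = "-"), collapse = "  ")
  c(
    line(colnames(tab)),
    apply(tab, 1L, line),
    sprintf("M0: AIC %.1f, adj R^2 %.4f; M1: AIC %.1f, adj R^2 %.4f",
      m0$aic, m0$adj_r2, m1$aic, m1$adj_r2
    )
  )
}
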