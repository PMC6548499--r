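# Statistical layer: transform, simple tests, and the count mixed-model
# contract. Simple tests delegate to the base-R closed forms; the mixed
# model delegates the numerical fit to lme4 under a fixed contract (Poisson
# response with log link for counts, full-factorial fixed effects,
# by-subject uncorrelated random intercepts).

#' Square-root transform for proportion data
#'
#' Applied to proportion-with-approach measures before analysis to correct
#' positive skew. Undefined proportions (`NA`) pass through unchanged.
#'
#' @param values Numeric vector of proportions in `[0, 1]`.
#' @return `sqrt(values)`.
#' @export
sqrt_prop <- function(values) {
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("proportions must lie in [0, 1]",
          class = "operantmicro_parameter_error")
  }
  sqrt(values)
}

tidy_t <- function(ht) {
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate[1]))
}

#' Paired t test
#'
#' Two-sided one-sample t test on within-subject differences,
#' `df = n - 1`.
#'
#' @param x,y Equal-length numeric vectors paired by subject (`n >= 2`).
#' @return List with `t`, `df`, `p` and `estimate` (mean difference).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    # degenerate zero-variance differences: t is 0 (no effect) or signed
    # infinity (constant nonzero shift)
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1,
                p = if (t == 0) 1 else 0, estimate = mean(d)))
  }
  tidy_t(stats::t.test(x, y, paired = TRUE))
}

#' One-sample t test
#'
#' @param x Numeric vector (`n >= 2`).
#' @param mu Reference value (default 0).
#' @return List with `t`, `df`, `p` and `estimate` (sample mean).
#' @export
one_sample_t <- function(x, mu = 0) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) {
    t <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
    return(list(t = t, df = length(x) - 1,
                p = if (t == 0) 1 else 0, estimate = mean(x)))
  }
  tidy_t(stats::t.test(x, mu = mu))
}

#' Pearson correlation
#'
#' Product-moment correlation with a two-sided p value from the t transform
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`, both with nonzero
#'   variance).
#' @return List with `r`, `p`, `df`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("pearson_r requires nonzero variance in both variables",
          class = "operantmicro_parameter_error")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value,
       df = unname(ht$parameter), n = length(x))
}

#' Specify a count / proportion mixed model
#'
#' Fixes the model contract used for response counts and transformed
#' proportions: a named response, a family (`poisson_log` for counts,
#' `gaussian_identity` for sqrt-transformed proportions), the full factorial
#' of the named categorical fixed factors, and by-subject uncorrelated
#' random intercepts adjusted for the named within-subject factors (one
#' intercept term per subject plus one per `subject:factor` grouping).
#'
#' @param response Column name of the response.
#' @param family `"poisson_log"` or `"gaussian_identity"`.
#' @param fixed Character vector of fixed-factor column names; the full
#'   factorial (all main effects and interactions) is fitted.
#' @param random Character vector of within-subject factor names for the
#'   random-intercept structure; empty for a fixed-effects-only model.
#' @param subject Column name identifying subjects (default
#'   `"subject_id"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("poisson_log", "gaussian_identity"),
                       fixed, random = character(),
                       subject = "subject_id") {
  family <- match.arg(family)
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, subject = subject),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(spec$fixed, collapse = " * ")
  if (length(spec$random)) {
    rand <- c(sprintf("(1 | %s)", spec$subject),
              sprintf("(1 | %s:%s)", spec$subject, spec$random))
    rhs <- paste(c(rhs, rand), collapse = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit the count / proportion mixed model
#'
#' Fits the model defined by a [model_spec()] by (approximate) maximum
#' likelihood: [lme4::glmer()] with the Laplace approximation for Poisson
#' responses, [lme4::lmer()] (REML) for Gaussian responses, or the
#' corresponding [stats::glm()]/[stats::lm()] when no random factors are
#' named. Predictors are coerced to factors; all factor combinations should
#' be represented (unbalanced cells are flagged with a warning, not an
#' error). Reported coefficients are on the link scale (log scale for
#' Poisson). Factor and interaction tests come from [car::Anova()] (type
#' II): Wald chi-square for generalized models, F for Gaussian fits.
#'
#' @param spec A [model_spec()].
#' @param data Data frame (e.g. stacked [period_response_table()] rows)
#'   containing the response, fixed factors and subject column.
#' @return An object of class `model_fit`: list with `coefficients` (tibble
#'   `term, b, se, stat, p`), `f_tests` (tibble `term, statistic, df, p,
#'   method`), `converged`, `messages`, `formula`, and the underlying `fit`
#'   object. Non-convergence is reported via `converged = FALSE`, never
#'   silently.
#' @export
fit_count_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  for (f in c(spec$fixed, spec$random, spec$subject)) {
    if (!f %in% names(data)) {
      abort(sprintf("factor '%s' not present in data", f),
            class = "operantmicro_parameter_error")
    }
    data[[f]] <- factor(data[[f]])
  }
  if (length(unique(data[[spec$subject]])) < 2) {
    abort("fit_count_model requires at least 2 subjects",
          class = "operantmicro_parameter_error")
  }
  cells <- table(data[spec$fixed])
  if (any(cells == 0)) {
    warning("some fixed-factor combinations have no observations",
            call. = FALSE)
  }
  form <- spec_formula(spec)
  msgs <- character()
  fit <- withCallingHandlers(
    {
      if (length(spec$random)) {
        if (spec$family == "poisson_log") {
          lme4::glmer(form, data = data, family = stats::poisson("log"))
        } else {
          lme4::lmer(form, data = data)
        }
      } else {
        if (spec$family == "poisson_log") {
          stats::glm(form, data = data, family = stats::poisson("log"))
        } else {
          stats::lm(form, data = data)
        }
      }
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  mixed <- length(spec$random) > 0
  converged <- if (mixed) {
    # a boundary (singular) fit is converged: random-effect variances of
    # zero are a legitimate MLE, not an optimizer failure
    msgs_conv <- fit@optinfo$conv$lme4$messages
    msgs_conv <- msgs_conv[!grepl("boundary \\(singular\\)", msgs_conv)]
    length(msgs_conv) == 0 && isTRUE(fit@optinfo$conv$opt == 0)
  } else if (spec$family == "poisson_log") {
    isTRUE(fit$converged)
  } else TRUE

  cf <- if (mixed) summary(fit)$coefficients else summary(fit)$coefficients
  has_p <- ncol(cf) >= 4
  coefficients <- tibble::tibble(
    term = rownames(cf), b = unname(cf[, 1]), se = unname(cf[, 2]),
    stat = unname(cf[, 3]),
    p = if (has_p) unname(cf[, 4]) else NA_real_)

  f_tests <- tryCatch({
    an <- as.data.frame(car::Anova(fit, type = 2))
    stat_col <- intersect(c("Chisq", "F", "F value", "LR Chisq"), names(an))[1]
    df_col <- intersect(c("Df", "df"), names(an))[1]
    p_col <- grep("^Pr", names(an), value = TRUE)[1]
    keep <- !is.na(an[[stat_col]])
    tibble::tibble(term = rownames(an)[keep],
                   statistic = an[[stat_col]][keep],
                   df = an[[df_col]][keep],
                   p = an[[p_col]][keep],
                   method = stat_col)
  }, error = function(e) {
    tibble::tibble(term = character(), statistic = numeric(),
                   df = numeric(), p = numeric(), method = character())
  })

  structure(list(coefficients = coefficients, f_tests = f_tests,
                 converged = converged, messages = msgs,
                 formula = form, family = spec$family, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", deparse(x$formula), "\n")
  cat(sprintf("  family: %s, converged: %s\n", x$family, x$converged))
  print(as.data.frame(x$coefficients), digits = 4)
  if (nrow(x$f_tests)) {
    cat("  factor tests (", x$f_tests$method[1], "):\n", sep = "")
    print(as.data.frame(x$f_tests[, c("term", "statistic", "df", "p")]),
          digits = 4)
  }
  if (length(x$messages)) cat("  messages:", x$messages, sep = "\n   ")
  invisible(x)
}
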