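#' Two-level full factorial design with responses
#'
#' Holds a 2^k design in coded units (-1/+1 per factor) together with the
#' measured response, plus the affine map back to actual factor settings.
#' Every one of the 2^k level combinations must be present the same number
#' of times (replication allowed).
#'
#' @param runs `data.frame` with one column per factor holding coded levels
#'   (-1/+1) or actual settings (converted using `factors`), and one
#'   response column.
#' @param factors `data.frame` with columns `name`, `low`, `high` and
#'   optionally `units`; `low < high` per factor.
#' @param response name of the response column in `runs`.
#' @return Object of class `factorial_design` with elements `coded`
#'   (matrix of -1/+1), `response` (numeric), `factors`, `response_name`.
#' @examples
#' tab <- doe1_table()
#' d <- factorial_design(tab, doe1_factors(), response = "dg")
#' estimate_effects(d)
#' @export
factorial_design <- function(runs, factors, response) {
  need <- c("name", "low", "high")
  if (!all(need %in% names(factors)))
    stop_invalid("`factors` must have columns ", paste(need, collapse = ", "))
  if (!"units" %in% names(factors)) factors$units <- ""
  if (any(factors$low >= factors$high))
    stop_invalid("each factor needs low < high")
  if (!response %in% names(runs))
    stop_invalid("response column '", response, "' not found in `runs`")
  missing_f <- setdiff(factors$name, names(runs))
  if (length(missing_f))
    stop_invalid("factor column(s) missing from `runs`: ",
                 paste(missing_f, collapse = ", "))
  k <- nrow(factors)
  coded <- sapply(seq_len(k), function(j) {
    x <- runs[[factors$name[j]]]
    if (all(x %in% c(-1, 1))) return(as.numeric(x))
    lo <- factors$low[j]; hi <- factors$high[j]
    z <- (x - (lo + hi) / 2) / ((hi - lo) / 2)
    if (!all(abs(abs(z) - 1) < 1e-9))
      stop_invalid("factor '", factors$name[j],
                   "' has settings other than its declared low/high levels")
    round(z)
  })
  coded <- matrix(coded, ncol = k, dimnames = list(NULL, factors$name))
  key <- apply(coded, 1, paste, collapse = ",")
  counts <- table(key)
  expected <- apply(expand.grid(rep(list(c(-1, 1)), k)), 1, paste,
                    collapse = ",")
  absent <- setdiff(expected, names(counts))
  if (length(absent))
    stop_invalid("not a full factorial; missing combination(s): ",
                 paste(absent, collapse = " | "))
  if (length(unique(counts)) != 1L)
    stop_invalid("unbalanced replication: combinations appear ",
                 paste(sort(unique(counts)), collapse = "/"), " times")
  y <- runs[[response]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop_invalid("response '", response, "' must be finite numeric")
  structure(
    list(coded = coded, response = as.numeric(y), factors = factors,
         response_name = response, n_replicates = unname(counts[1])),
    class = "factorial_design"
  )
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("2^%d full factorial, response '%s', %d runs (%d replicate(s))\n",
              nrow(x$factors), x$response_name, length(x$response),
              x$n_replicates))
  print(cbind(as.data.frame(x$coded), setNames(
    data.frame(x$response), x$response_name)), row.names = FALSE)
  invisible(x)
}

# all main-effect and interaction terms of a 2^k design, in standard order
# (mains first, then 2-way, ..., up to the k-way term)
design_terms <- function(factor_names) {
  k <- length(factor_names)
  unlist(lapply(seq_len(k), function(ord)
    utils::combn(factor_names, ord, paste, collapse = ":")), use.names = FALSE)
}

# contrast column (+/-1) for a term like "A:B" given the coded matrix
term_contrast <- function(coded, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  bad <- setdiff(parts, colnames(coded))
  if (length(bad))
    stop_invalid("unknown factor(s) in term '", term, "': ",
                 paste(bad, collapse = ", "))
  apply(coded[, parts, drop = FALSE], 1, prod)
}

#' Estimate all effects of a two-level factorial
#'
#' The effect of a term is the mean response where its contrast is +1 minus
#' the mean where it is -1 (interaction contrasts are products of factor
#' columns); the regression coefficient on the coded scale is half the
#' effect. Equivalent to, and cross-checkable against, least squares on the
#' coded design matrix.
#'
#' @param design a [factorial_design()].
#' @return `data.frame` of class `factorial_effects` with columns `term`,
#'   `effect`, `coefficient`; attribute `"design"` retains the design.
#'   Main effects come first, then interactions of increasing order.
#' @export
estimate_effects <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  terms <- design_terms(colnames(design$coded))
  eff <- vapply(terms, function(tm) {
    cc <- term_contrast(design$coded, tm)
    mean(design$response[cc > 0]) - mean(design$response[cc < 0])
  }, numeric(1))
  out <- data.frame(term = terms, effect = unname(eff),
                    coefficient = unname(eff) / 2)
  class(out) <- c("factorial_effects", "data.frame")
  attr(out, "design") <- design
  out
}

#' Half-normal ranking of factorial effects
#'
#' Orders absolute effects ascending and attaches the half-normal plotting
#' positions `p_i = (i - 0.5) / m` and the corresponding half-normal
#' quantiles, the coordinates of the classic half-normal probability plot
#' used to pick the active effects by eye.
#'
#' @param effects a `factorial_effects` table (from [estimate_effects()]).
#' @return `data.frame` with columns `term`, `abs_effect`, `p`,
#'   `half_normal_quantile`, sorted ascending by `abs_effect`.
#' @export
half_normal_ranking <- function(effects) {
  stopifnot(inherits(effects, "factorial_effects"))
  if (nrow(effects) < 2L)
    stop_invalid("need at least 2 effects to rank")
  o <- order(abs(effects$effect))
  m <- nrow(effects)
  p <- (seq_len(m) - 0.5) / m
  data.frame(term = effects$term[o],
             abs_effect = abs(effects$effect[o]),
             p = p,
             half_normal_quantile = stats::qnorm((1 + p) / 2))
}

#' Lenth margin-of-error selection of active effects
#'
#' Optional automatic alternative to visual half-normal selection, using
#' Lenth's pseudo standard error: `s0 = 1.5 * median(|effect|)`,
#' `PSE = 1.5 * median(|effect| : |effect| < 2.5 s0)`, margin of error
#' `t(0.975, m/3) * PSE`. Effects exceeding the margin are flagged active.
#'
#' @param effects a `factorial_effects` table.
#' @return Character vector of terms whose `|effect|` exceeds the margin.
#' @export
select_effects_lenth <- function(effects) {
  stopifnot(inherits(effects, "factorial_effects"))
  ae <- abs(effects$effect)
  s0 <- 1.5 * stats::median(ae)
  pse <- 1.5 * stats::median(ae[ae < 2.5 * s0])
  me <- stats::qt(0.975, df = length(ae) / 3) * pse
  effects$term[ae > me]
}

#' ANOVA on a selected subset of factorial terms
#'
#' For balanced two-level designs the sum of squares of a term is
#' `N * effect^2 / 4` (N = total runs). Unselected terms are pooled into
#' the error together with any pure-error from replication, giving the
#' F-test behind the usual "select from the half-normal plot, then confirm
#' by ANOVA" workflow. Selecting every term of an unreplicated design
#' leaves no error degrees of freedom and is an error.
#'
#' @param design a [factorial_design()].
#' @param selected_terms character vector of terms to test (e.g.
#'   `c("n2_flow", "feed_conc:n2_flow")`).
#' @return `data.frame` with rows per selected term plus `residuals`:
#'   columns `term`, `sum_sq`, `df`, `mean_sq`, `F`, `p_value`.
#' @export
anova_selected <- function(design, selected_terms) {
  stopifnot(inherits(design, "factorial_design"))
  all_terms <- design_terms(colnames(design$coded))
  bad <- setdiff(selected_terms, all_terms)
  if (length(bad))
    stop_invalid("term(s) not estimable in this design: ",
                 paste(bad, collapse = ", "))
  if (length(selected_terms) == 0L)
    stop_invalid("select at least one term")
  y <- design$response
  n <- length(y)
  ss_term <- vapply(selected_terms, function(tm) {
    cc <- term_contrast(design$coded, tm)
    n * (mean(y[cc > 0]) - mean(y[cc < 0]))^2 / 4
  }, numeric(1))
  ss_total <- sum((y - mean(y))^2)
  df_err <- n - 1L - length(selected_terms)
  if (df_err <= 0L)
    stop_compute("no error degrees of freedom: saturated selection on an ",
                 "unreplicated design; deselect terms or add replicates")
  ss_err <- ss_total - sum(ss_term)
  ss_err <- max(ss_err, 0)   # guard tiny negative round-off
  ms_err <- ss_err / df_err
  fval <- (ss_term / 1) / ms_err
  pval <- stats::pf(fval, 1, df_err, lower.tail = FALSE)
  rbind(
    data.frame(term = selected_terms, sum_sq = unname(ss_term), df = 1L,
               mean_sq = unname(ss_term), F = unname(fval),
               p_value = unname(pval)),
    data.frame(term = "residuals", sum_sq = ss_err, df = df_err,
               mean_sq = ms_err, F = NA_real_, p_value = NA_real_)
  )
}

#' Prediction equation in coded and actual units
#'
#' Builds the fitted response model from the selected terms: on the coded
#' scale the intercept is the grand mean and each coefficient is half the
#' effect; the actual-units form is obtained by substituting the affine
#' coded-to-actual map per factor (so the two forms agree exactly at every
#' setting).
#'
#' @param design a [factorial_design()].
#' @param selected_terms terms to keep (default: all).
#' @return Object of class `prediction_equation` with `coded_coefficients`
#'   (named, including `(Intercept)`), `actual_coefficients`, and a
#'   `$predict(newdata)` function taking actual-unit factor settings.
#' @export
prediction_equation <- function(design, selected_terms = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  all_terms <- design_terms(colnames(design$coded))
  if (is.null(selected_terms)) selected_terms <- all_terms
  bad <- setdiff(selected_terms, all_terms)
  if (length(bad))
    stop_invalid("unknown term(s): ", paste(bad, collapse = ", "))
  eff <- estimate_effects(design)
  coefs <- c("(Intercept)" = mean(design$response),
             setNames(eff$coefficient[match(selected_terms, eff$term)],
                      selected_terms))
  fac <- design$factors
  center <- (fac$low + fac$high) / 2
  halfw <- (fac$high - fac$low) / 2
  names(center) <- names(halfw) <- fac$name

  code_newdata <- function(newdata) {
    sapply(fac$name, function(nm) {
      if (!nm %in% names(newdata))
        stop_invalid("prediction input missing factor '", nm, "'")
      (newdata[[nm]] - center[[nm]]) / halfw[[nm]]
    })
  }
  predict_fun <- function(newdata) {
    z <- code_newdata(newdata)
    if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, fac$name))
    out <- rep(coefs[["(Intercept)"]], nrow(z))
    for (tm in selected_terms) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
      out <- out + coefs[[tm]] * apply(z[, parts, drop = FALSE], 1, prod)
    }
    out
  }

  # actual-unit coefficients: a coded product term expands into all its
  # lower-order sub-terms in actual units (the affine shift generates them),
  # so refit exactly on the design corners over the hierarchical closure
  hier <- unique(unlist(lapply(selected_terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    unlist(lapply(seq_along(parts), function(ord)
      utils::combn(parts, ord, paste, collapse = ":")))
  })))
  hier <- hier[order(match(hier, design_terms(fac$name)))]
  corners_coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), nrow(fac))))
  colnames(corners_coded) <- fac$name
  corners_actual <- sweep(sweep(corners_coded, 2, halfw, "*"), 2, center, "+")
  yhat <- predict_fun(as.data.frame(corners_actual))
  X <- matrix(1, nrow(corners_actual), 1L,
              dimnames = list(NULL, "(Intercept)"))
  for (tm in hier) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    X <- cbind(X, apply(corners_actual[, parts, drop = FALSE], 1, prod))
    colnames(X)[ncol(X)] <- tm
  }
  actual_coefs <- drop(qr.solve(crossprod(X), crossprod(X, yhat)))
  names(actual_coefs) <- colnames(X)

  structure(
    list(response_name = design$response_name,
         selected_terms = selected_terms,
         coded_coefficients = coefs,
         actual_coefficients = actual_coefs,
         predict = predict_fun,
         factors = fac),
    class = "prediction_equation"
  )
}

#' @export
print.prediction_equation <- function(x, ...) {
  fmt <- function(coefs) paste(sprintf("%+.4g*%s", coefs[-1L],
                                       names(coefs)[-1L]), collapse = " ")
  cat(sprintf("%s = %.4g %s   [coded units]\n", x$response_name,
              x$coded_coefficients[1L], fmt(x$coded_coefficients)))
  cat(sprintf("%s = %.4g %s   [actual units]\n", x$response_name,
              x$actual_coefficients[1L], fmt(x$actual_coefficients)))
  invisible(x)
}
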