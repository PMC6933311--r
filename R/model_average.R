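#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`, with `k` the number
#' of estimated parameters (fixed effects + variance components).
#'
#' @param loglik maximized log-likelihood
#' @param k number of estimated parameters
#' @param n number of observations
#' @return AICc value
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model averaging
#'
#' Fits every main-effect subset of `effects` (including the
#' intercept-only model) for `response`, by maximum likelihood. With
#' `random` set, models are linear mixed models with that random
#' intercept ([lme4::lmer], `REML = FALSE` for cross-structure AICc
#' comparability); if *every* candidate estimates the random-intercept
#' variance at exactly zero the whole set is refitted as plain linear
#' models (with a message), mirroring the usual practice of dropping an
#' uninformative random effect.
#'
#' Akaike weights are computed over all candidates; the 95% confidence
#' set is the minimal weight-sorted prefix whose cumulative weight
#' reaches `conf_level`. Coefficients are conditionally ("naturally")
#' averaged over the confidence-set models that contain them, with
#' renormalized weights; the unconditional standard error follows
#' Burnham & Anderson,
#' `SE = sqrt(sum w (se_m^2 + (b_m - b_avg)^2))`, and 95% CIs are
#' normal-based (`+/- 1.96 SE`). Categorical effects enter or leave as a
#' whole term.
#'
#' @param data a `data.frame` (e.g. a `study_table`); rows incomplete on
#'   the response or any effect are dropped
#' @param response response column name
#' @param effects character vector of main-effect column names
#' @param random optional grouping column for a random intercept
#' @param conf_level cumulative-weight cutoff of the confidence set
#'   (default 0.95)
#' @param weight_set `"confidence"` (default: average over the confidence
#'   set) or `"all"` (average over every candidate)
#' @return object of class `candidate_set`: `models` (one row per
#'   candidate: terms, k, logLik, AICc, delta, weight, in_confidence_set),
#'   `averaged` (per coefficient: estimate, se, ci_lower, ci_upper,
#'   sum_weight), `n`, `response`, `random_dropped`
#' @export
fit_candidates <- function(data, response, effects, random = NULL,
                           conf_level = 0.95,
                           weight_set = c("confidence", "all")) {
  weight_set <- match.arg(weight_set)
  stopifnot(all(c(response, effects, random) %in% names(data)))
  d <- as.data.frame(data)
  d <- d[stats::complete.cases(d[, c(response, effects), drop = FALSE]), ,
         drop = FALSE]
  n <- nrow(d)
  p <- length(effects)
  subsets <- lapply(0:(2^p - 1), function(m)
    effects[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])

  fit_one <- function(terms, use_random) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    if (use_random) {
      f <- stats::as.formula(paste(response, "~", rhs,
                                   "+ (1|", random, ")"))
      m <- suppressWarnings(suppressMessages(
        lme4::lmer(f, data = d, REML = FALSE)))
      ll <- stats::logLik(m)
      list(terms = terms, coef = lme4::fixef(m),
           se = sqrt(diag(as.matrix(stats::vcov(m)))),
           loglik = as.numeric(ll), k = attr(ll, "df"),
           singular = lme4::isSingular(m, tol = 1e-6))
    } else {
      m <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = d)
      ll <- stats::logLik(m)
      list(terms = terms, coef = stats::coef(m),
           se = sqrt(diag(stats::vcov(m))),
           loglik = as.numeric(ll), k = attr(ll, "df"), singular = FALSE)
    }
  }

  use_random <- !is.null(random)
  fits <- lapply(subsets, fit_one, use_random = use_random)
  random_dropped <- FALSE
  if (use_random && all(vapply(fits, `[[`, TRUE, "singular"))) {
    message("random-intercept variance estimated at zero in every candidate; ",
            "refitting the set as plain linear models")
    fits <- lapply(subsets, fit_one, use_random = FALSE)
    random_dropped <- TRUE
  }

  a <- vapply(fits, function(f) aicc(f$loglik, f$k, n), 0)
  dropped <- is.na(a)
  if (any(dropped)) {
    warning(sum(dropped), " candidate model(s) dropped: n too small for AICc")
    fits <- fits[!dropped]; a <- a[!dropped]
  }
  delta <- a - min(a)
  w <- exp(-delta / 2); w <- w / sum(w)
  o <- order(w, decreasing = TRUE)
  conf_idx <- o[seq_len(which(cumsum(w[o]) >= conf_level)[1])]
  keep <- if (weight_set == "confidence") conf_idx else seq_along(fits)

  coefnames <- unique(unlist(lapply(fits, function(f) names(f$coef))))
  averaged <- do.call(rbind, lapply(coefnames, function(cn) {
    has <- keep[vapply(fits[keep], function(f) cn %in% names(f$coef), TRUE)]
    wr <- w[has] / sum(w[has])
    est <- vapply(fits[has], function(f) unname(f$coef[cn]), 0)
    ses <- vapply(fits[has], function(f) unname(f$se[cn]), 0)
    b <- sum(wr * est)
    se_u <- sqrt(sum(wr * (ses^2 + (est - b)^2)))
    data.frame(coefficient = cn, estimate = b, se = se_u,
               ci_lower = b - 1.96 * se_u, ci_upper = b + 1.96 * se_u,
               sum_weight = sum(w[has]))
  }))
  rownames(averaged) <- averaged$coefficient

  models <- data.frame(
    terms = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = "+") else "(intercept)",
      ""),
    k = vapply(fits, `[[`, 0, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    AICc = a, delta = delta, weight = w,
    in_confidence_set = seq_along(fits) %in% conf_idx)
  models <- models[order(models$AICc), ]
  rownames(models) <- NULL

  structure(list(models = models, averaged = averaged, n = n,
                 response = response, effects = effects,
                 random = if (random_dropped) NULL else random,
                 random_dropped = random_dropped,
                 conf_level = conf_level, weight_set = weight_set),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("All-subsets AICc averaging: %s ~ {%s}%s, n = %d\n",
              x$response, paste(x$effects, collapse = ", "),
              if (!is.null(x$random)) paste0(" + (1|", x$random, ")") else "",
              x$n))
  if (x$random_dropped)
    cat("(random intercept dropped: variance zero in every candidate)\n")
  cat(sprintf("%d candidate models; %d in the %.0f%% confidence set\n\n",
              nrow(x$models), sum(x$models$in_confidence_set),
              100 * x$conf_level))
  av <- x$averaged
  av[, -1] <- round(av[, -1], 4)
  print(av, row.names = FALSE)
  invisible(x)
}

#' Express an averaged effect as a percentage of the averaged intercept
#'
#' @param set a `candidate_set` from [fit_candidates()]
#' @param effect coefficient name (as it appears in `set$averaged`)
#' @return percent change per unit of the effect, `100 * b / intercept`
#'   (sign preserved)
#' @export
effect_as_percent <- function(set, effect) {
  av <- set$averaged
  if (!effect %in% av$coefficient)
    stop("no averaged coefficient named '", effect, "'", call. = FALSE)
  b0 <- av["(Intercept)", "estimate"]
  if (abs(b0) < 1e-12)
    stop("averaged intercept is (near) zero; percent effect undefined",
         call. = FALSE)
  100 * av[effect, "estimate"] / b0
}
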