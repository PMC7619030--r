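#' @importFrom stats as.formula coef model.matrix pchisq pf pnorm sd setNames
#'   terms vcov delete.response update logLik
NULL

# ---- internal helpers -------------------------------------------------------

# standardized coefficients: b * sd(x_col) / sd(y), per non-intercept column
standardized_betas <- function(b, X, y) {
  sds <- apply(X, 2L, sd)
  beta <- b * sds / sd(y)
  beta[sds == 0] <- NA_real_   # intercept column
  beta
}

# marginal (Type-III style) Wald tests on coefficient blocks
wald_blocks <- function(b, V, assign, labels, resid_df = NULL) {
  out <- lapply(seq_along(labels), function(t) {
    idx <- which(assign == t)
    bb <- b[idx]
    W <- drop(crossprod(bb, solve(V[idx, idx, drop = FALSE], bb)))
    q <- length(idx)
    if (is.null(resid_df)) {
      data.frame(term = labels[[t]], statistic = W, df = q, df2 = NA_real_,
                 stat_type = "chisq", p = pchisq(W, q, lower.tail = FALSE))
    } else {
      Fv <- W / q
      data.frame(term = labels[[t]], statistic = Fv, df = q, df2 = resid_df,
                 stat_type = "F", p = pf(Fv, q, resid_df, lower.tail = FALSE))
    }
  })
  do.call(rbind, out)
}

fixed_table <- function(b, V, X, y) {
  se <- sqrt(diag(V))
  data.frame(term = names(b), b = unname(b), se = unname(se),
             z = unname(b / se), beta = unname(standardized_betas(b, X, y)),
             row.names = NULL)
}

group_contrasts_arg <- function(contrasts) {
  list(.g = switch(contrasts, sum = "contr.sum", treatment = "contr.treatment"))
}

# ---- interaction linear model ----------------------------------------------

#' Fit the coordinate interaction linear model
#'
#' Ordinary least squares of a continuous response on a continuous predictor,
#' a grouping factor and their interaction (intercept, slope, group
#' contrasts, slope-by-group contrasts: `2 G` parameters for `G` groups, so
#' 1083 stations in 5 cities leave 1073 residual df). Term tests are marginal
#' F tests on coefficient blocks; under the default sum-to-zero contrasts
#' these are the usual Type-III tests. With a single group the model
#' degenerates to simple regression.
#'
#' @param y Numeric response (e.g. city-level z-scored geographic latitude).
#' @param x Numeric predictor (e.g. linguistic latitude).
#' @param g Grouping factor (e.g. city); may have one level.
#' @param contrasts `"sum"` (default, marginal tests) or `"treatment"`
#'   (coefficient-level replication).
#' @return A `lingmap_fit` with elements `fixed` (term, b, SE, z,
#'   standardized beta), `terms` (marginal F table), `fit` (sigma, r.squared,
#'   residual df), plus the underlying `lm` in `$model`.
#' @export
fit_lm_interaction <- function(y, x, g, contrasts = c("sum", "treatment")) {
  contrasts <- match.arg(contrasts)
  stopifnot(is.numeric(y), is.numeric(x), length(y) == length(x),
            length(g) == length(y))
  df <- data.frame(.y = y, .x = x, .g = factor(g))
  if (nlevels(df$.g) > 1L) {
    mod <- stats::lm(.y ~ .x * .g, data = df,
                     contrasts = group_contrasts_arg(contrasts))
  } else {
    mod <- stats::lm(.y ~ .x, data = df)
  }
  cf <- coef(mod)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  X <- model.matrix(mod)
  V <- vcov(mod)
  asg <- attr(X, "assign")
  labels <- attr(terms(mod), "term.labels")
  res <- structure(list(
    kind = "lm",
    fixed = fixed_table(cf, V, X, df$.y),
    varcomp = data.frame(component = "residual",
                         variance = summary(mod)$sigma^2),
    terms = wald_blocks(cf, V, asg, labels, resid_df = mod$df.residual),
    fit = list(sigma = summary(mod)$sigma,
               r_squared = summary(mod)$r.squared,
               df_residual = mod$df.residual,
               n = nrow(df), converged = TRUE, boundary = FALSE),
    model = mod, data = df, contrasts = contrasts
  ), class = "lingmap_fit")
  res
}

# ---- crossed random-intercept mixed model ----------------------------------

#' Fit a linear mixed model with two crossed random intercepts
#'
#' The pairwise-distance model: each observation is a station pair, and the
#' two stations of the pair enter as crossed random intercepts,
#' `y ~ x (* g) + (1 | id1) + (1 | id2)`. Variance components are estimated
#' by REML (profiled deviance, as in lme4); fixed effects are the
#' generalized-least-squares solution at the optimum. When both
#' random-intercept variances are estimated at the zero boundary the fixed
#' effects coincide with ordinary least squares; boundary fits are flagged
#' (`$fit$boundary`), never errored.
#'
#' @param y Numeric response (e.g. geographic distance in km).
#' @param x Numeric predictor (e.g. linguistic distance); `NULL` for an
#'   intercept-only fixed part.
#' @param id1,id2 Factors identifying the two crossed grouping factors
#'   (first and second station of the pair). `id2 = NULL` drops to a single
#'   random intercept.
#' @param g Optional grouping factor interacting with `x` (e.g. city).
#' @param contrasts Contrast coding for `g`.
#' @param reml Fit by REML (default) or ML.
#' @return A `lingmap_fit`: `fixed` (b, SE, Wald z, standardized beta),
#'   `varcomp` (id1, id2, residual variances), `terms` (Wald chi-square
#'   table), `fit` (REML/ML criterion, convergence and boundary flags), and
#'   the underlying `merMod` in `$model`.
#' @export
fit_crossed_lmm <- function(y, x, id1, id2 = NULL, g = NULL,
                            contrasts = c("sum", "treatment"), reml = TRUE) {
  contrasts <- match.arg(contrasts)
  stopifnot(is.numeric(y), length(id1) == length(y))
  df <- data.frame(.y = y, .id1 = factor(id1))
  if (!is.null(x)) {
    stopifnot(is.numeric(x), length(x) == length(y))
    df$.x <- x
  }
  re <- "(1 | .id1)"
  if (!is.null(id2)) {
    stopifnot(length(id2) == length(y))
    df$.id2 <- factor(id2)
    if (any(as.character(df$.id1) == as.character(df$.id2))) {
      stop("each row must reference two distinct ids", call. = FALSE)
    }
    re <- paste(re, "+ (1 | .id2)")
  }
  ctr <- NULL
  if (!is.null(g)) {
    if (is.null(x)) stop("a group factor requires a predictor x", call. = FALSE)
    df$.g <- factor(g)
    fixed <- ".y ~ .x * .g"
    ctr <- group_contrasts_arg(contrasts)
  } else {
    fixed <- if (is.null(x)) ".y ~ 1" else ".y ~ .x"
  }
  form <- as.formula(paste(fixed, "+", re))
  mod <- suppressMessages(lme4::lmer(
    form, data = df, REML = reml, contrasts = ctr,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                optCtrl = list(rhobeg = 0.2, rhoend = 2e-9),
                                check.conv.singular = "ignore",
                                check.scaleX = "ignore",
                                calc.derivs = FALSE)))
  b <- lme4::fixef(mod)
  V <- as.matrix(vcov(mod))
  X <- lme4::getME(mod, "X")
  asg <- attr(X, "assign")
  labels <- attr(terms(mod), "term.labels")
  vc <- as.data.frame(lme4::VarCorr(mod))
  comp <- vc$grp
  comp[comp == ".id1"] <- "id1"
  comp[comp == ".id2"] <- "id2"
  comp[comp == "Residual"] <- "residual"
  conv <- length(mod@optinfo$conv$lme4) == 0L
  res <- structure(list(
    kind = "lmm",
    fixed = fixed_table(b, V, X, df$.y),
    varcomp = data.frame(component = comp, variance = vc$vcov,
                         sd = vc$sdcor, row.names = NULL),
    terms = wald_blocks(b, V, asg, labels, resid_df = NULL),
    fit = list(criterion = if (reml) lme4::REMLcrit(mod) else stats::deviance(mod),
               reml = reml, n = nrow(df), converged = conv,
               boundary = lme4::isSingular(mod, tol = 1e-6)),
    model = mod, data = df, contrasts = contrasts
  ), class = "lingmap_fit")
  res
}

#' Fit a model given in tilde notation
#'
#' Accepts the field's string notation — `response ~ predictor × group`,
#' with `(1|factor)` terms for random intercepts — against a data frame, and
#' dispatches to [fit_lm_interaction()] or [fit_crossed_lmm()]. The first
#' numeric right-hand-side variable is the continuous predictor; a remaining
#' non-numeric variable, if any, is the interacting group factor.
#'
#' @param data Data frame holding all referenced columns.
#' @param spec Model string, e.g.
#'   `"geo_km ~ ling_dist * city + (1|station_i) + (1|station_j)"` (the
#'   multiplication sign may be `*` or the typographic cross).
#' @param ... Passed on to the fitting function (`contrasts`, `reml`).
#' @return A `lingmap_fit`.
#' @export
fit_model_spec <- function(data, spec, ...) {
  spec <- gsub("×", "*", spec)
  spec <- gsub("∣|│", "|", spec)
  re <- regmatches(spec, gregexpr("\\(\\s*1\\s*\\|\\s*([^)]+)\\)", spec))[[1]]
  re_vars <- trimws(sub("^\\(\\s*1\\s*\\|\\s*", "", sub("\\)$", "", re)))
  fixed <- spec
  for (r in re) fixed <- sub(r, "", fixed, fixed = TRUE)
  fixed <- gsub("\\+\\s*(\\+|$)", "\\1", fixed)
  fixed <- sub("[+[:space:]]+$", "", fixed)
  ff <- as.formula(fixed)
  response <- all.vars(ff[[2L]])
  rhs <- all.vars(ff[[3L]])
  missing_cols <- setdiff(c(response, rhs, re_vars), names(data))
  if (length(missing_cols)) {
    stop("model references missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_rhs <- rhs[vapply(rhs, function(v) is.numeric(data[[v]]), logical(1L))]
  factor_rhs <- setdiff(rhs, numeric_rhs)
  if (length(numeric_rhs) != 1L) {
    stop("model spec must name exactly one continuous predictor", call. = FALSE)
  }
  if (length(factor_rhs) > 1L) {
    stop("model spec supports at most one interacting factor", call. = FALSE)
  }
  g <- if (length(factor_rhs)) data[[factor_rhs]] else NULL
  if (length(re_vars) == 0L) {
    if (is.null(g)) {
      stop("a fixed-effects spec needs an interacting factor; use ",
           "fit_lm_interaction for simple regression", call. = FALSE)
    }
    fit_lm_interaction(data[[response]], data[[numeric_rhs]], g, ...)
  } else {
    if (length(re_vars) > 2L) {
      stop("at most two random-intercept factors are supported", call. = FALSE)
    }
    fit_crossed_lmm(data[[response]], data[[numeric_rhs]],
                    id1 = data[[re_vars[[1L]]]],
                    id2 = if (length(re_vars) > 1L) data[[re_vars[[2L]]]],
                    g = g, ...)
  }
}

#' @exportS3Method base::print
print.lingmap_fit <- function(x, ...) {
  cat(sprintf("<lingmap_fit> %s, n = %d%s\n", x$kind, x$fit$n,
              if (isTRUE(x$fit$boundary)) " (variance at boundary)" else ""))
  cat("Fixed effects:\n")
  print(x$fixed, digits = 4)
  if (x$kind == "lmm") {
    cat("Variance components:\n")
    print(x$varcomp, digits = 4)
  }
  cat("Term tests:\n")
  print(x$terms, digits = 4)
  invisible(x)
}

# ---- term tests -------------------------------------------------------------

#' Marginal term tests for a fitted model
#'
#' `method = "wald"` tests each term's coefficient block with a Wald
#' chi-square (mixed models) or the equivalent marginal F (linear models)
#' from the coefficient covariance. `method = "lrt"` refits without the
#' term's columns and compares maximized log-likelihoods; REML fits are
#' automatically refit by ML first (with a notice), since REML criteria are
#' not comparable across fixed-effect structures.
#'
#' @param object A `lingmap_fit`.
#' @param method `"wald"` or `"lrt"`.
#' @return Data frame `term, statistic, df, df2, stat_type, p`.
#' @export
term_tests <- function(object, method = c("wald", "lrt")) {
  stopifnot(inherits(object, "lingmap_fit"))
  method <- match.arg(method)
  if (method == "wald") return(object$terms)
  mod <- object$model
  df <- object$data
  if (object$kind == "lmm") {
    if (object$fit$reml) {
      message("LRT requested on a REML fit; refitting by ML")
      mod <- update(mod, REML = FALSE)
    }
    X <- lme4::getME(mod, "X")
  } else {
    X <- model.matrix(mod)
  }
  asg <- attr(X, "assign")
  labels <- attr(terms(mod), "term.labels")
  ll_full <- as.numeric(logLik(mod))
  re_part <- if (object$kind == "lmm") {
    if (".id2" %in% names(df)) "+ (1 | .id1) + (1 | .id2)" else "+ (1 | .id1)"
  } else ""
  out <- lapply(seq_along(labels), function(t) {
    keep <- asg != t
    dat <- df
    dat$.Xred <- X[, keep, drop = FALSE]
    form <- as.formula(paste(".y ~ 0 + .Xred", re_part))
    red <- if (object$kind == "lmm") {
      suppressMessages(lme4::lmer(
        form, data = dat, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
    } else {
      stats::lm(form, data = dat)
    }
    stat <- 2 * (ll_full - as.numeric(logLik(red)))
    q <- sum(!keep)
    data.frame(term = labels[[t]], statistic = stat, df = q, df2 = NA_real_,
               stat_type = "chisq", p = pchisq(max(stat, 0), q, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# ---- simple slopes ----------------------------------------------------------

#' Per-group simple slopes of the continuous predictor
#'
#' The slope of `x` within each level of the interacting factor, computed as
#' a linear contrast of the fixed effects (so the result is invariant to the
#' contrast coding and to which level is the reference), with the standard
#' error from the coefficient covariance and Wald `z = b / SE`. This is the
#' post-hoc decomposition of a significant slope-by-group interaction into
#' per-city slopes.
#'
#' @param object A `lingmap_fit` whose model contains an `x` by group
#'   interaction.
#' @return Data frame `group, b, se, z, p`, one row per group level.
#' @export
simple_slopes <- function(object) {
  stopifnot(inherits(object, "lingmap_fit"))
  df <- object$data
  mod <- object$model
  if (object$kind == "lmm") {
    b <- lme4::fixef(mod)
    X <- lme4::getME(mod, "X")
  } else {
    b <- coef(mod)
    X <- model.matrix(mod)
  }
  V <- as.matrix(vcov(mod))
  if (!".g" %in% names(df)) {
    slope <- b[[".x"]]
    se <- sqrt(V[".x", ".x"])
    return(data.frame(group = NA_character_, b = slope, se = se,
                      z = slope / se,
                      p = 2 * pnorm(-abs(slope / se)), row.names = NULL))
  }
  trm <- delete.response(terms(mod))
  ctr <- if (object$kind == "lmm") attr(X, "contrasts") else mod$contrasts
  lev <- levels(df$.g)
  out <- lapply(lev, function(l) {
    nd <- data.frame(.x = c(0, 1), .g = factor(c(l, l), levels = lev))
    M <- model.matrix(trm, nd, contrasts.arg = ctr)
    d <- M[2L, ] - M[1L, ]
    slope <- drop(d %*% b)
    se <- sqrt(drop(d %*% V %*% d))
    data.frame(group = l, b = slope, se = se, z = slope / se,
               p = 2 * pnorm(-abs(slope / se)))
  })
  do.call(rbind, out)
}
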