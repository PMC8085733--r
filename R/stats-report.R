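# Mixed-model effect tables and Bonferroni post-hoc contrasts. The
# contract here is the model *specification* (fixed terms, data grain,
# by-participant random intercept) plus standard REML fitting; exact
# replication of any particular GUI's numerics is out of scope.

#' Specify a mixed model for one dependent variable
#'
#' The standard structure: variability and volatility as simple fixed
#' factors, AQ as a continuous fixed effect, all interactions among the
#' fixed effects, plus DV-specific covariates, and a by-participant
#' random intercept.
#'
#' @param dependent Name of the DV column.
#' @param covariates Character vector of additional fixed covariates
#'   (e.g. `"accuracy"`, `"onset_s"`, `"n_turns"`).
#' @param fixed Character vector of crossed fixed effects; default
#'   `c("variability", "volatility", "aq_score")`.
#' @param grain `"trial"` or `"condition"` (bookkeeping only).
#' @param random Random-effects term (default by-participant intercept).
#' @return A `model_spec` list with the assembled formula.
#' @export
model_spec <- function(dependent,
                       covariates = character(0),
                       fixed = c("variability", "volatility", "aq_score"),
                       grain = c("trial", "condition"),
                       random = "(1 | participant)") {
  grain <- match.arg(grain)
  rhs <- paste(fixed, collapse = " * ")
  if (length(covariates) > 0L) {
    rhs <- paste(c(rhs, covariates), collapse = " + ")
  }
  fml <- stats::as.formula(paste(dependent, "~", rhs, "+", random))
  structure(list(dependent = dependent, fixed = fixed,
                 covariates = covariates, grain = grain,
                 random = random, formula = fml),
            class = "model_spec")
}

#' Model specifications matching the analysis plan
#'
#' One spec per dependent variable, with the DV-specific covariates used
#' in the analysis: accuracy (and its interactions) for average
#' prediction error, time-to-movement-onset for time spent moving, total
#' turn count for dominant-policy use, and time-bin plus condition-level
#' means for the hypothesis-switch ERPE. The agency-wise slope model
#' swaps the uncertainty factors for agency x accuracy x AQ.
#'
#' @return Named list of [model_spec()] objects.
#' @export
standard_model_specs <- function() {
  list(
    accuracy = model_spec("accuracy"),
    time_moving = model_spec("time_moving_s", covariates = "onset_s"),
    speed = model_spec("mean_speed"),
    acceleration = model_spec("mean_accel"),
    jerk = model_spec("mean_jerk"),
    turns = model_spec("n_turns"),
    dominant_policy = model_spec("n_dominant", covariates = "n_turns"),
    switches = model_spec("n_switches"),
    mean_pe = model_spec("mean_pe",
                         fixed = c("variability", "volatility",
                                   "aq_score", "accuracy")),
    condition_slope = model_spec("slope", grain = "condition"),
    agency_slope = model_spec("slope",
                              fixed = c("judged_agency", "accuracy",
                                        "aq_score"),
                              grain = "condition"),
    erpe = model_spec("pe_bin",
                      fixed = c("variability", "volatility", "aq_score",
                                "time_bin"),
                      covariates = c("cond_mean_pe", "cond_mean_switches"),
                      grain = "condition")
  )
}

#' Fit a linear mixed model and tabulate F tests
#'
#' Fits the spec by REML with `lme4::lmer` and reports an F statistic per
#' fixed term. Denominator degrees of freedom use a between/within
#' (containment) approximation: terms constant within participants are
#' tested against `n_participants - n_between_columns`, all others
#' against the residual df. If the random-intercept fit is singular the
#' model is refitted without it (flagged in the result).
#'
#' @param spec A [model_spec()].
#' @param data Data frame at the spec's grain.
#' @return An `effect_table` `data.frame` with columns term, F, df1, df2,
#'   p; attributes `fit` (the fitted model) and `singular`.
#' @export
fit_mixed_model <- function(spec, data) {
  miss <- setdiff(c(spec$dependent, spec$fixed, spec$covariates,
                    "participant"), names(data))
  if (length(miss) > 0L) {
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$participant)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  data <- data[stats::complete.cases(
    data[, c(spec$dependent, spec$fixed, spec$covariates, "participant")]
  ), , drop = FALSE]

  singular <- FALSE
  fit <- suppressMessages(
    lme4::lmer(spec$formula, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                 lme4::.makeCC(action = "ignore", tol = 1e-4)))
  )
  if (lme4::isSingular(fit, tol = 1e-4)) {
    singular <- TRUE
    fixed_fml <- stats::as.formula(
      paste(deparse(spec$formula[[2]]), "~",
            gsub("\\+\\s*\\(.*\\)\\s*$", "", deparse1(spec$formula[[3]])))
    )
    fit_lm <- stats::lm(fixed_fml, data = data)
    an <- stats::anova(fit_lm)
    terms <- rownames(an)[rownames(an) != "Residuals"]
    out <- data.frame(term = terms,
                      F = an$`F value`[seq_along(terms)],
                      df1 = an$Df[seq_along(terms)],
                      df2 = an$Df[nrow(an)],
                      p = an$`Pr(>F)`[seq_along(terms)])
    attr(out, "fit") <- fit_lm
    attr(out, "singular") <- TRUE
    class(out) <- c("effect_table", class(out))
    return(out)
  }

  an <- stats::anova(fit)
  terms <- rownames(an)
  X <- stats::model.matrix(fit)
  n <- nrow(X)
  p_rank <- qr(X)$rank
  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(fit), "term.labels")
  pid <- data$participant
  n_part <- length(unique(pid))
  # which model columns are constant within participants?
  col_between <- vapply(seq_len(ncol(X)), function(j) {
    all(tapply(X[, j], pid, function(v) max(v) - min(v)) < 1e-10)
  }, logical(1))
  n_between_cols <- sum(col_between)
  resid_df <- n - p_rank
  df2 <- vapply(terms, function(tm) {
    j <- which(term_labels == tm)
    cols <- which(asgn == j)
    if (length(cols) > 0L && all(col_between[cols])) {
      max(n_part - n_between_cols, 1L)
    } else {
      resid_df
    }
  }, numeric(1))
  out <- data.frame(term = terms,
                    F = an$`F value`,
                    df1 = an$npar,
                    df2 = df2,
                    p = stats::pf(an$`F value`, an$npar, df2,
                                  lower.tail = FALSE))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "singular") <- singular
  class(out) <- c("effect_table", class(out))
  out
}

#' AQ grouping at mean +/- 1 SD
#'
#' Splits AQ scores into low (< mean - 1 SD), mid, and high
#' (> mean + 1 SD) groups, with cut-points computed from the analysed
#' sample.
#'
#' @param aq Numeric AQ scores (one per observation or participant).
#' @return List with `cuts = c(low, high)` and `group` (factor
#'   low/mid/high per element).
#' @export
aq_groups <- function(aq) {
  mu <- mean(aq, na.rm = TRUE)
  sg <- stats::sd(aq, na.rm = TRUE)
  cuts <- c(low = mu - sg, high = mu + sg)
  group <- cut(aq, breaks = c(-Inf, cuts[1], cuts[2], Inf),
               labels = c("low", "mid", "high"), right = FALSE)
  group[aq == cuts[2]] <- "mid" # boundary: strict > for high
  list(cuts = cuts, group = group)
}

#' Bonferroni adjustment
#'
#' @param p Raw p values.
#' @param m Number of comparisons (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' Pairwise post-hoc contrasts for a factor term
#'
#' Builds a reference grid over the levels of the named factors (other
#' factors averaged over their observed levels, continuous covariates
#' held at their means), computes fixed-effect cell means `L beta`, and
#' tests all pairwise differences with z statistics from the fixed-effect
#' covariance, Bonferroni-adjusted. When `aq_by_group = TRUE` and
#' `aq_score` is a model covariate, contrasts are evaluated at the low /
#' mid / high AQ group means (cut at sample mean +/- 1 SD).
#'
#' @param effect_table Result of [fit_mixed_model()].
#' @param term Character vector of factor names to cross (e.g.
#'   `c("variability", "volatility")`).
#' @param data The model data.
#' @param aq_by_group Probe contrasts within AQ groups.
#' @return `data.frame` of contrasts: cells, estimate, se, z, p_raw,
#'   p_adj.
#' @export
posthoc_contrasts <- function(effect_table, term, data,
                              aq_by_group = FALSE) {
  fit <- attr(effect_table, "fit")
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else
    stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  tt <- stats::terms(fit)
  all_vars <- all.vars(stats::delete.response(tt))
  factors <- term
  others <- setdiff(all_vars, factors)

  lev <- lapply(factors, function(f) unique(as.character(data[[f]])))
  names(lev) <- factors
  aq_levels <- NULL
  if (aq_by_group && "aq_score" %in% others) {
    g <- aq_groups(data$aq_score)
    aq_levels <- tapply(data$aq_score, g$group, mean, na.rm = TRUE)
    others <- setdiff(others, "aq_score")
    lev$aq_group <- names(aq_levels)
  }
  grid <- expand.grid(lev, stringsAsFactors = FALSE)

  cell_rows <- lapply(seq_len(nrow(grid)), function(i) {
    nd <- data
    for (f in factors) nd[[f]] <- grid[[f]][i]
    if (!is.null(aq_levels)) {
      nd$aq_score <- as.numeric(aq_levels[[grid$aq_group[i]]])
    }
    for (o in others) {
      if (is.numeric(nd[[o]])) nd[[o]] <- mean(data[[o]], na.rm = TRUE)
    }
    # keep the fit's factor coding even when a column is set to one level
    for (v in intersect(all_vars, names(nd))) {
      if (!is.numeric(data[[v]])) {
        nd[[v]] <- factor(as.character(nd[[v]]),
                          levels = sort(unique(as.character(data[[v]]))))
      }
    }
    Xi <- stats::model.matrix(stats::delete.response(tt), nd)
    colMeans(Xi) # average over remaining factor distribution
  })
  L <- do.call(rbind, cell_rows)
  L <- L[, names(beta), drop = FALSE]
  est <- as.numeric(L %*% beta)

  pairs <- utils::combn(nrow(grid), 2L)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    l <- L[i, ] - L[j, ]
    d <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% V %*% l))
    z <- d / se
    lab <- function(r) paste(unlist(grid[r, , drop = FALSE]),
                             collapse = "/")
    data.frame(cell_a = lab(i), cell_b = lab(j), estimate = d,
               se = se, z = z,
               p_raw = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p_raw, m)
  out
}
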