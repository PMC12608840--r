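#' Candidate random-effects structures
#'
#' Labels of the participant random-effects structures the package fits,
#' in increasing complexity: random intercept only; plus a random CoP
#' slope; plus random direction offsets and CoP-by-direction slopes;
#' "maximal" adds random slopes for every CoP interaction present among
#' the fixed effects.
#'
#' @format character vector of structure labels.
#' @export
LMM_STRUCTURES <- c("(1)", "(1 + CoP)", "(1 + CoP + PR + CoP:PR)", "maximal")

#' Build the design for the SIP-CoP mixed-effects models
#'
#' Proportional pressure is the response; CoP magnitude is a continuous
#' fixed effect (centred on its grand mean by default); lean direction is a
#' categorical fixed effect with baseline `forward`; cushion (baseline
#' `air`), start position (baseline `backrest`) and participant group
#' (baseline `AB`) enter as additional fixed effects, each interacting with
#' CoP, when they vary in the data (or as requested). Participant is the
#' random-effect grouping factor.
#'
#' @param data data frame with columns `participant`, `direction`,
#'   `cop_mag`, `prop_pressure`, and optionally `cushion`,
#'   `start_position`, `group`.
#' @param center_cop centre CoP on its grand mean?
#' @param include_cushion,include_position,include_group `"auto"` (include
#'   when the factor has more than one level), `TRUE` (error if single
#'   level) or `FALSE`.
#' @return object of class `lmm_design`: list with `data` (factors coded,
#'   `cop` column ready), `fixed_formula` (character), `cop_mean`,
#'   `terms` (factor names in the design).
#' @export
build_lmm_design <- function(data, center_cop = TRUE,
                             include_cushion = "auto",
                             include_position = "auto",
                             include_group = "auto") {
  need <- c("participant", "direction", "cop_mag", "prop_pressure")
  stop_if_not(all(need %in% names(data)),
              paste("data needs columns:", paste(need, collapse = ", ")))
  stop_if_not(length(unique(data$participant)) >= 2,
              "need at least 2 participants")
  stop_if_not(all(data$cop_mag >= 0), "cop_mag must be nonnegative")
  stop_if_not(all(data$direction %in% DIRECTIONS),
              "direction outside the fixed vocabulary")

  d <- data.frame(
    participant = factor(data$participant),
    direction = factor(data$direction,
                       levels = intersect(DIRECTIONS,
                                          unique(data$direction))),
    prop_pressure = data$prop_pressure
  )
  cop_mean <- if (center_cop) mean(data$cop_mag) else 0
  d$cop <- data$cop_mag - cop_mean

  use_factor <- function(col, include, levels_all, baseline) {
    if (isFALSE(include)) return(NULL)
    present <- col %in% names(data)
    if (!present) {
      stop_if_not(!isTRUE(include), paste("column", col, "absent"))
      return(NULL)
    }
    n_lev <- length(unique(data[[col]]))
    if (n_lev < 2) {
      stop_if_not(!isTRUE(include),
                  paste("factor", col, "has a single level"))
      return(NULL)
    }
    lev <- c(baseline, setdiff(intersect(levels_all, unique(data[[col]])),
                               baseline))
    factor(data[[col]], levels = lev)
  }

  terms <- character(0)
  if (length(unique(d$direction)) > 1) {
    terms <- c(terms, "direction")
  } else {
    d$direction <- NULL
  }
  cu <- use_factor("cushion", include_cushion, CUSHIONS, "air")
  if (!is.null(cu)) { d$cushion <- cu; terms <- c(terms, "cushion") }
  po <- use_factor("start_position", include_position, START_POSITIONS,
                   "backrest")
  if (!is.null(po)) { d$start_position <- po
    terms <- c(terms, "start_position") }
  gr <- use_factor("group", include_group, c("AB", "MWU"), "AB")
  if (!is.null(gr)) { d$group <- gr; terms <- c(terms, "group") }

  fixed <- "prop_pressure ~ cop"
  for (tm in terms) fixed <- paste0(fixed, " + ", tm, " + cop:", tm)
  structure(
    list(data = d, fixed_formula = fixed, cop_mean = cop_mean,
         terms = terms, centered = center_cop),
    class = "lmm_design"
  )
}

random_terms_for <- function(structure_label, terms) {
  switch(
    structure_label,
    "(1)" = "(1 | participant)",
    "(1 + CoP)" = "(1 + cop | participant)",
    "(1 + CoP + PR + CoP:PR)" = {
      if ("direction" %in% terms) {
        "(1 + cop * direction | participant)"
      } else {
        "(1 + cop | participant)"
      }
    },
    "maximal" = {
      re <- "1 + cop"
      if ("direction" %in% terms) re <- paste(re, "* direction")
      for (tm in setdiff(terms, "direction")) {
        re <- paste0(re, " + cop:", tm)
      }
      paste0("(", re, " | participant)")
    },
    stop("unknown random structure label: ", structure_label,
         call. = FALSE)
  )
}

#' Fit one SIP-CoP linear mixed-effects model
#'
#' REML fit through `lmerTest::lmer()` with Satterthwaite degrees of
#' freedom for the fixed-effect tests. Wald 95% confidence intervals
#' (estimate +/- 1.96 SE) accompany the estimates. Non-convergence is
#' flagged on the result, not silently ignored.
#'
#' @param design an [build_lmm_design()] result.
#' @param random_structure one of `"(1)"`, `"(1 + CoP)"`,
#'   `"(1 + CoP + PR + CoP:PR)"`, `"maximal"`.
#' @param ci_multiplier Wald CI half-width in SEs.
#' @return object of class `sip_lmm`: list with `label`, `formula`,
#'   `fixed` (data frame: effect, estimate, std_error, df, t, p, ci_low,
#'   ci_high), `aic`, `bic`, `converged`, `singular` (boundary fit),
#'   `n_obs`, `n_participants`, `data_checksum`, and `fit` (the underlying
#'   `lmerModLmerTest`).
#' @export
fit_sip_lmm <- function(design, random_structure = LMM_STRUCTURES[3],
                        ci_multiplier = 1.96) {
  stop_if_not(inherits(design, "lmm_design"), "need an lmm_design")
  random_structure <- match.arg(random_structure, LMM_STRUCTURES)
  fml <- stats::as.formula(paste(design$fixed_formula, "+",
                                 random_terms_for(random_structure,
                                                  design$terms)))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = design$data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv_issues <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit)
  ## a singular (boundary) fit is flagged separately from a genuine
  ## optimizer failure
  failure <- any(grepl("failed to converge", c(msgs, conv_issues),
                       ignore.case = TRUE))
  converged <- !failure

  co <- stats::coef(summary(fit))
  fixed <- data.frame(
    effect = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    df = co[, "df"],
    t = co[, "t value"],
    p = co[, "Pr(>|t|)"],
    ci_low = co[, "Estimate"] - ci_multiplier * co[, "Std. Error"],
    ci_high = co[, "Estimate"] + ci_multiplier * co[, "Std. Error"],
    row.names = NULL
  )
  structure(
    list(label = random_structure, formula = deparse1(fml), fixed = fixed,
         aic = stats::AIC(fit), bic = stats::BIC(fit),
         converged = converged, singular = singular,
         messages = c(msgs, conv_issues),
         n_obs = nrow(design$data),
         n_participants = length(unique(design$data$participant)),
         data_checksum = sum(design$data$prop_pressure) +
           sum(design$data$cop),
         fit = fit),
    class = "sip_lmm"
  )
}

#' @export
print.sip_lmm <- function(x, ...) {
  cat(sprintf("SIP-CoP mixed model, random structure %s%s\n", x$label,
              if (x$converged) "" else " [convergence flagged]"))
  cat(sprintf("  AIC %.2f  BIC %.2f  n %d (%d participants)\n",
              x$aic, x$bic, x$n_obs, x$n_participants))
  print(x$fixed, digits = 4)
  invisible(x)
}

#' Compare mixed-model random-effects structures by AIC and BIC
#'
#' @param ... `sip_lmm` results fitted on identical data (or a single list
#'   of them).
#' @return data frame sorted by ascending AIC with columns `label`, `aic`,
#'   `bic`, `rank_aic`, `rank_bic`, `converged`; ties keep input order.
#' @export
compare_lmm_models <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "sip_lmm")) {
    results <- results[[1]]
  }
  stop_if_not(length(results) >= 2, "need at least 2 models to compare")
  stop_if_not(all(vapply(results, inherits, logical(1), "sip_lmm")),
              "all inputs must be sip_lmm results")
  n_obs <- vapply(results, `[[`, numeric(1), "n_obs")
  chk <- vapply(results, `[[`, numeric(1), "data_checksum")
  stop_if_not(length(unique(n_obs)) == 1 &&
                max(chk) - min(chk) < 1e-8 * max(1, abs(chk[1])),
              "models were fitted on differing datasets")
  tab <- data.frame(
    label = vapply(results, `[[`, character(1), "label"),
    aic = vapply(results, `[[`, numeric(1), "aic"),
    bic = vapply(results, `[[`, numeric(1), "bic"),
    converged = vapply(results, `[[`, logical(1), "converged")
  )
  tab$rank_aic <- rank(tab$aic, ties.method = "first")
  tab$rank_bic <- rank(tab$bic, ties.method = "first")
  tab <- tab[order(tab$rank_aic), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Direction-specific total SIP-CoP slope from a fitted model
#'
#' The forward slope is the CoP fixed effect; the leftward and rightward
#' slopes add the corresponding CoP-by-direction interaction estimate.
#' Pure arithmetic on the fixed-effect table.
#'
#' @param result a `sip_lmm`, or any data frame with columns `effect` and
#'   `estimate` (e.g. a published fixed-effect table).
#' @param direction `"forward"`, `"left"` or `"right"`.
#' @return total slope, proportional SIP per cm.
#' @examples
#' tab <- data.frame(effect = c("cop", "cop:directionleft"),
#'                   estimate = c(-0.0685, -0.0307))
#' total_slope(tab, "left") # -0.0992
#' @export
total_slope <- function(result, direction) {
  direction <- match_direction(direction)
  fixed <- if (inherits(result, "sip_lmm")) result$fixed else result
  stop_if_not(is.data.frame(fixed) &&
                all(c("effect", "estimate") %in% names(fixed)),
              "need a sip_lmm or a data frame with effect and estimate")
  get_est <- function(name) {
    i <- which(fixed$effect == name)
    stop_if_not(length(i) == 1L, paste("missing term:", name))
    fixed$estimate[i]
  }
  cop <- get_est("cop")
  if (direction == "forward") return(cop)
  cop + get_est(paste0("cop:direction", direction))
}
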