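#' Configure a synthetic two-group cohort
#'
#' The published external validation used 60 questionnaire patients (30
#' with DR, 30 without) that are not deposited; this generator provides a
#' synthetic stand-in. Each factor is drawn independently within group.
#' Controls use baseline exposure probabilities; cases use odds-tilted
#' probabilities so that the population odds ratio of each factor level
#' versus its baseline equals the target OR raised to `effect_scale`:
#' for a binary factor with control exposure probability q0,
#' q1 = OR^lambda * odds0 / (1 + OR^lambda * odds0) with
#' odds0 = q0 / (1 - q0). The three-level lipid-lowering duration factor
#' uses the multinomial analogue (each non-baseline level's odds versus
#' "none" multiplied by its OR^lambda), which preserves mutual
#' exclusivity.
#'
#' `effect_scale = 0` gives a null cohort (cases and controls exchangeable);
#' `effect_scale = 1` gives the evidence table's effects.
#'
#' @param evidence Evidence table supplying the target odds ratios;
#'   defaults to [dr_evidence_table()].
#' @param n_case,n_control Group sizes (published validation: 30 and 30).
#' @param control_marginals Named list: factor_id -> probability of
#'   "present" for binary factors, or a named probability vector over all
#'   levels for multi-level factors. Default: 0.3 exposure per factor
#'   (split evenly across non-baseline levels for multi-level factors).
#' @param effect_scale Multiplier lambda >= 0 on the log-OR scale.
#' @param seed Integer RNG seed.
#' @return A `cohort_config` list with a `case_marginals` element derived
#'   from the tilt.
#' @export
cohort_config <- function(evidence = dr_evidence_table(),
                          n_case = 30, n_control = 30,
                          control_marginals = NULL,
                          effect_scale = 1, seed = 7L) {
  evidence <- validate_evidence(evidence)
  stopifnot(n_case >= 1, n_control >= 1, effect_scale >= 0)
  factors <- unique(evidence$factor_id)

  marg <- list()
  for (f in factors) {
    rows <- evidence[evidence$factor_id == f, , drop = FALSE]
    base <- baseline_level(f)
    lv <- c(base, rows$level)
    m <- control_marginals[[f]]
    if (is.null(m)) {
      expose <- 0.3
      q <- c(1 - expose, rep(expose / nrow(rows), nrow(rows)))
      m <- stats::setNames(q, lv)
    } else if (length(m) == 1L && is.null(names(m))) {
      if (nrow(rows) > 1L) {
        stop("control marginal for multi-level factor '", f,
             "' must be a named probability vector over its levels")
      }
      m <- stats::setNames(c(1 - m, m), lv)
    } else {
      if (!setequal(names(m), lv)) {
        stop("control marginal for '", f, "' must name levels: ",
             paste(lv, collapse = ", "))
      }
      m <- m[lv]
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop("control marginal for '", f, "' must sum to 1")
    }
    if (effect_scale > 0 && m[base] %in% c(0, 1) &&
        any(rows$pooled_or != 1)) {
      stop("degenerate control marginal for '", f,
           "': baseline probability of 0 or 1 cannot be odds-tilted")
    }
    marg[[f]] <- m
  }

  case_marg <- lapply(factors, function(f) {
    rows <- evidence[evidence$factor_id == f, , drop = FALSE]
    m <- marg[[f]]
    tilt <- stats::setNames(rep(1, length(m)), names(m))
    tilt[rows$level] <- rows$pooled_or^effect_scale
    w <- m * tilt
    w / sum(w)
  })
  names(case_marg) <- factors

  structure(
    list(evidence = evidence, n_case = as.integer(n_case),
         n_control = as.integer(n_control),
         control_marginals = marg, case_marginals = case_marg,
         effect_scale = effect_scale, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_case` case rows and `n_control` control rows with independent
#' per-factor sampling from the group marginals in `config`. The result is
#' directly scoreable by [score_patients()].
#'
#' @param config A `cohort_config`.
#' @return data.frame with one level column per factor plus `label`
#'   (1 = DR case, 0 = control); cases first.
#' @export
#' @examples
#' cc <- cohort_config(n_case = 30, n_control = 30, seed = 7)
#' cohort <- generate_cohort(cc)
#' table(cohort$label)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  draw <- function(marginals, n) {
    cols <- lapply(marginals, function(m) {
      sample(names(m), n, replace = TRUE, prob = m)
    })
    as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  }
  cases <- draw(config$case_marginals, config$n_case)
  controls <- draw(config$control_marginals, config$n_control)
  out <- rbind(cases, controls)
  out$label <- rep(c(1L, 0L), c(config$n_case, config$n_control))
  out
}

#' Odds ratio from a 2x2 table
#'
#' Computes (a*d)/(b*c) for the exposure-by-label table with cells
#' a = exposed cases, b = unexposed cases, c = exposed controls,
#' d = unexposed controls. When any cell is zero the Haldane-Anscombe
#' correction (add 0.5 to every cell) is applied.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return The odds ratio estimate, with attributes `table` (the counts)
#'   and `corrected` (whether the 0.5 correction was used).
#' @export
or_from_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure((cells["a"] * cells["d"]) / (cells["b"] * cells["c"]),
            names = NULL, table = c(a = a, b = b, c = c, d = d),
            corrected = corrected)
}

#' Empirical odds ratio of a factor level in a labelled cohort
#'
#' Tabulates exposure (the given level) against the case/control label and
#' returns the sample odds ratio. For multi-level factors the comparison
#' is the level versus the factor's baseline, restricted to subjects at
#' either; other levels are excluded, matching the evidence table's
#' level-vs-baseline contrasts.
#'
#' @param cohort data.frame with factor columns and a `label` column
#'   (1 = case), as produced by [generate_cohort()]; or pass `labels`
#'   separately.
#' @param factor_id Column to tabulate.
#' @param level Exposure level; defaults to the factor's only non-baseline
#'   level for binary factors.
#' @param labels Optional label vector overriding `cohort$label`.
#' @return Odds ratio estimate with attributes `table`, `corrected`, and
#'   `se_log` (the usual sqrt(1/a + 1/b + 1/c + 1/d) on corrected cells).
#' @export
empirical_or <- function(cohort, factor_id, level = "present",
                         labels = cohort$label) {
  if (!factor_id %in% names(cohort)) {
    stop("factor '", factor_id, "' not present in cohort")
  }
  if (is.null(labels) || length(labels) != nrow(cohort)) {
    stop("labels must be supplied, one per cohort row")
  }
  x <- cohort[[factor_id]]
  base <- baseline_level(factor_id)
  keep <- x %in% c(level, base)
  x <- x[keep]
  y <- labels[keep]
  a <- sum(x == level & y == 1)
  b <- sum(x == base & y == 1)
  c_ <- sum(x == level & y == 0)
  d <- sum(x == base & y == 0)
  est <- or_from_table(a, b, c_, d)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  attr(est, "se_log") <- sqrt(sum(1 / cells))
  est
}

#' Write a cohort to CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path Destination file; columns are the factors plus `label`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
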