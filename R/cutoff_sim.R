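#' Configure the Monte Carlo cut-off simulation
#'
#' The dividing node between high and low DR risk is placed by drawing
#' random exposure profiles, scoring each with the model, and inspecting
#' the sorted probability curve. This constructor bundles the draw size,
#' the per-factor level marginals, the coefficient set and the RNG seed.
#'
#' Defaults emulate the published procedure: 1000 profiles with each
#' binary factor an even coin flip and the three lipid-lowering duration
#' levels uniform (the original marginals are unreported, so the
#' uninformative choice is made explicit and configurable).
#'
#' @param coeffs A `coefficient_set`.
#' @param n_profiles Number of profiles to draw (>= 1).
#' @param marginals Named list: factor_id -> named probability vector over
#'   that factor's levels (non-negative, summing to 1). Missing factors
#'   get the uniform default.
#' @param seed Integer RNG seed, recorded in the output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(coeffs, n_profiles = 1000,
                              marginals = NULL, seed = 42L) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (length(n_profiles) != 1L || is.na(n_profiles) || n_profiles < 1) {
    stop("n_profiles must be at least 1")
  }
  levels <- coef_levels(coeffs)
  full <- lapply(levels, function(lv) {
    stats::setNames(rep(1 / length(lv), length(lv)), lv)
  })
  if (!is.null(marginals)) {
    unknown <- setdiff(names(marginals), names(levels))
    if (length(unknown) > 0L) {
      stop("marginals given for unknown factor(s): ",
           paste(unknown, collapse = ", "))
    }
    for (f in names(marginals)) {
      m <- marginals[[f]]
      if (is.null(names(m)) || !setequal(names(m), levels[[f]])) {
        stop("marginal for '", f, "' must name exactly the levels: ",
             paste(levels[[f]], collapse = ", "))
      }
      if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
        stop("marginal for '", f,
             "' must be non-negative and sum to 1 within 1e-9")
      }
      full[[f]] <- m[levels[[f]]]
    }
  }
  structure(
    list(coeffs = coeffs, n_profiles = as.integer(n_profiles),
         marginals = full, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Draw random exposure profiles
#'
#' Samples `n_profiles` independent profiles, each factor's level drawn
#' from its marginal. Reproducible for a given seed.
#'
#' @param config A `simulation_config`.
#' @return data.frame of level strings, one column per factor, one row per
#'   profile.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_profiles
  cols <- lapply(config$marginals, function(m) {
    sample(names(m), n, replace = TRUE, prob = m)
  })
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

#' Sorted probability curve of a simulated population
#'
#' Scores every profile and sorts the predicted probabilities ascending;
#' the rank (1..n) is the abscissa and the probability the ordinate of the
#' joint-distribution plot on which the dividing node is read off.
#'
#' @param profiles data.frame of profiles (from [simulate_profiles()]).
#' @param coeffs A `coefficient_set`.
#' @return data.frame with columns `rank` and `probability`
#'   (non-decreasing).
#' @export
sorted_probability_curve <- function(profiles, coeffs) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
  scored <- score_patients(profiles, coeffs)
  p <- sort(scored$probability)
  data.frame(rank = seq_along(p), probability = p)
}

#' Locate the high/low-risk dividing node on a sorted curve
#'
#' Finds the first rank whose probability reaches `p_star` (default 0.5,
#' the published dividing node) and reports the LP score implied at that
#' node, `p_star / prevalence`. When the whole curve sits below `p_star`
#' the status is `"all-below"` and the rank is `NA`; when it sits entirely
#' at or above, the status is `"all-above"` with rank 1.
#'
#' @param curve data.frame from [sorted_probability_curve()].
#' @param p_star Probability cut point in (0, 1).
#' @param prevalence Local prevalence used for the LP equivalent.
#' @return list with `status` ("ok", "all-below" or "all-above"), `rank`,
#'   `probability` (at the node, NA if all-below), and `lp_equivalent`.
#' @export
find_cutoff_node <- function(curve, p_star = 0.5, prevalence = 0.278) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0L)
  if (p_star <= 0 || p_star >= 1) {
    stop("p_star must lie strictly inside (0, 1)")
  }
  lp_eq <- p_star / prevalence
  at_or_above <- curve$probability >= p_star
  if (!any(at_or_above)) {
    return(list(status = "all-below", rank = NA_integer_,
                probability = NA_real_, lp_equivalent = lp_eq))
  }
  idx <- which(at_or_above)[1L]
  status <- if (idx == 1L) "all-above" else "ok"
  list(status = status, rank = curve$rank[idx],
       probability = curve$probability[idx], lp_equivalent = lp_eq)
}

#' Run the full cut-off simulation
#'
#' Convenience wrapper: draw profiles, build the sorted curve, locate the
#' node. The seed and marginals are echoed in the result so a run is fully
#' reproducible from its own metadata.
#'
#' @inheritParams simulation_config
#' @inheritParams find_cutoff_node
#' @return list with `curve`, `node`, `config`.
#' @export
#' @examples
#' cs <- build_coefficient_set()
#' sim <- run_cutoff_simulation(cs, n_profiles = 200, seed = 1)
#' sim$node
run_cutoff_simulation <- function(coeffs, n_profiles = 1000,
                                  marginals = NULL, seed = 42L,
                                  p_star = 0.5) {
  config <- simulation_config(coeffs, n_profiles, marginals, seed)
  profiles <- simulate_profiles(config)
  curve <- sorted_probability_curve(profiles, coeffs)
  node <- find_cutoff_node(curve, p_star, coeffs$prevalence)
  list(curve = curve, node = node, config = config)
}

#' Export a sorted probability curve as CSV
#'
#' Columns `rank,probability`, suitable for plotting the joint
#' distribution externally.
#'
#' @param curve data.frame from [sorted_probability_curve()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(curve[, c("rank", "probability")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
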