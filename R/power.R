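#' Design of the paired non-inferiority power calculation
#'
#' Describes the paired detection model used to size the study: among
#' confirmed positives, both workflows detect with probability `p_both`,
#' routine alone with `p_routine_only`, the AI workflow alone with
#' `p_ai_only`, and the residual mass (`p_neither`) is detected by neither.
#' Defaults are the study's planning assumptions: 95.0% agreement, 1.9%
#' routine-only, 3.0% AI-only, 65 confirmed positives, one-sided alpha 0.05
#' and a 10% relative non-inferiority margin.
#'
#' @param p_both,p_routine_only,p_ai_only,p_neither four-cell multinomial
#'   probabilities; `p_neither` defaults to the residual so that they sum
#'   to 1.
#' @param n_positives confirmed positives per simulated study.
#' @param ni_margin_relative relative non-inferiority margin.
#' @param alpha_one_sided one-sided alpha of the non-inferiority decision.
#' @param n_sim Monte-Carlo study replicates.
#' @param n_boot_inner bootstrap resamples inside each replicate.
#' @param seed integer seed.
#' @param residual_to_both assign the residual probability mass to the
#'   `both` cell instead of `neither`.
#' @return Object of class `power_design`.
#' @export
power_design <- function(p_both = 0.950, p_routine_only = 0.019,
                         p_ai_only = 0.030, p_neither = NULL,
                         n_positives = 65L, ni_margin_relative = 0.1,
                         alpha_one_sided = 0.05, n_sim = 2000L,
                         n_boot_inner = 2000L, seed = 1L,
                         residual_to_both = FALSE) {
  if (is.null(p_neither)) {
    resid <- 1 - (p_both + p_routine_only + p_ai_only)
    if (resid < -1e-9) stop("cell probabilities exceed 1", call. = FALSE)
    resid <- max(resid, 0)
    if (residual_to_both) { p_both <- p_both + resid; p_neither <- 0 }
    else p_neither <- resid
  }
  p <- c(both = p_both, routine_only = p_routine_only, ai_only = p_ai_only,
         neither = p_neither)
  if (any(p < 0 | p > 1)) stop("cell probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("cell probabilities must sum to 1",
                                   call. = FALSE)
  stopifnot(n_positives >= 1, ni_margin_relative > 0,
            alpha_one_sided > 0, alpha_one_sided < 0.5,
            n_sim >= 1, n_boot_inner >= 2)
  structure(list(p = p, n_positives = as.integer(n_positives),
                 ni_margin_relative = ni_margin_relative,
                 alpha_one_sided = alpha_one_sided,
                 n_sim = as.integer(n_sim),
                 n_boot_inner = as.integer(n_boot_inner),
                 seed = as.integer(seed)),
            class = "power_design")
}

# Non-inferiority decision for one simulated study given its four observed
# cell counts: bootstrap the detected-proportion ratio AI/routine and require
# the lower bound of the two-sided percentile CI to clear 1 - margin. This
# is the same percentile-bootstrap decision as the comparative module,
# expressed on the four paired detection cells.
.ni_pass <- function(obs, design) {
  n <- design$n_positives
  if (obs[1] + obs[2] == 0L) return(NA)           # routine detects none
  B <- stats::rmultinom(design$n_boot_inner, n, obs / n)
  ratio <- (B[1, ] + B[3, ]) / (B[1, ] + B[2, ])
  bad <- !is.finite(ratio)
  for (i in seq_len(100L)) {
    if (!any(bad)) break
    B2 <- stats::rmultinom(sum(bad), n, obs / n)
    ratio[bad] <- (B2[1, ] + B2[3, ]) / (B2[1, ] + B2[2, ])
    bad <- !is.finite(ratio)
  }
  ratio <- ratio[is.finite(ratio)]
  lower <- stats::quantile(ratio, design$alpha_one_sided, type = 6,
                           names = FALSE)
  lower > 1 - design$ni_margin_relative
}

#' Monte-Carlo power of the paired non-inferiority design
#'
#' For each simulated study, draws `n_positives` outcomes from the four-cell
#' paired detection multinomial, bootstraps the detected-proportion ratio
#' AI/routine, and declares non-inferiority when the lower bound of the
#' two-sided percentile CI (at `2 * alpha_one_sided`) exceeds
#' `1 - ni_margin_relative`. Power is the passing fraction; a binomial
#' Monte-Carlo standard error is attached. Replicates in which routine
#' double reading detects no positives are redrawn (the ratio is undefined
#' there), mirroring the degeneracy rule of the comparative module.
#'
#' @param design [power_design()].
#' @return Object of class `power_estimate`: `power`, `se`, `n_sim`,
#'   `n_degenerate`, and the design.
#' @export
simulate_power <- function(design) {
  stopifnot(inherits(design, "power_design"))
  set.seed(design$seed)
  M <- stats::rmultinom(design$n_sim, design$n_positives, design$p)
  pass <- logical(design$n_sim)
  n_degenerate <- 0L
  for (i in seq_len(design$n_sim)) {
    res <- .ni_pass(M[, i], design)
    while (is.na(res)) {                          # routine detected none: redraw
      n_degenerate <- n_degenerate + 1L
      res <- .ni_pass(stats::rmultinom(1L, design$n_positives, design$p)[, 1],
                      design)
    }
    pass[i] <- res
  }
  power <- mean(pass)
  structure(list(power = power,
                 se = sqrt(power * (1 - power) / design$n_sim),
                 n_sim = design$n_sim, n_degenerate = n_degenerate,
                 design = design),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Estimated power: %.1f%% (MC SE %.1f pp) from %d simulated ",
              100 * x$power, 100 * x$se, x$n_sim))
  cat(sprintf("studies of %d positives\n", x$design$n_positives))
  invisible(x)
}

#' Smallest number of positives reaching a target power
#'
#' Monotone (bisection) search over `n_positives` using [simulate_power()]
#' with common random numbers: every candidate size reuses the design's
#' seed, so the power curve explored is a deterministic non-decreasing
#' function of `n` up to Monte-Carlo noise.
#'
#' @param design [power_design()]; its `n_positives` is ignored.
#' @param target_power target in (0, 1).
#' @param n_max search ceiling.
#' @return Smallest `n_positives` whose estimated power reaches the target.
#' @export
required_positives <- function(design, target_power, n_max = 500L) {
  stopifnot(target_power > 0, target_power < 1)
  power_at <- function(n) {
    d <- design
    d$n_positives <- as.integer(n)
    simulate_power(d)$power
  }
  if (power_at(n_max) < target_power) {
    stop("target power not reachable below the ceiling n = ", n_max,
         call. = FALSE)
  }
  lo <- 1L; hi <- as.integer(n_max)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid + 1L
  }
  lo
}
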