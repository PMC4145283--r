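# Analytic consequences of the Pareto-front solution: the degree distribution
# law p(x) ~ x^-gamma on [xmin, xmax], the exponent relation gamma(a, b), and
# the regime spectrum along the path-length constraint c.

#' Predicted degree-distribution exponent
#'
#' For edge-degree exponents `a`, `b` the Pareto-front degree distribution is
#' a power law with exponent \deqn{\gamma(a,b) = (a+b+1)/(a+b).} Anchors:
#' \eqn{\gamma = 2} at `(0, 1)`; \eqn{\gamma \to 1^+} as `a + b` grows (the
#' exponent-1 limit where networks become random); `a = b = 0` is degenerate
#' (`F2` equals `F1`, no power law is predicted).
#'
#' The relation is exposed through the `relation` argument so an alternative
#' formula can be swapped in without touching callers.
#'
#' @param a,b non-negative edge-degree exponents with `a + b > 0`.
#' @param relation function `(a, b) -> gamma`; default the relation above.
#' @return the exponent `gamma > 1`.
#' @examples
#' predicted_exponent(0, 1)  # 2
#' predicted_exponent(1, 1)  # 1.5
#' @export
predicted_exponent <- function(a, b, relation = NULL) {
  if (a < 0 || b < 0) stop("exponents a, b must be non-negative")
  if (a + b == 0) {
    stop("degenerate model: at a = b = 0, F2 reduces to F1 and no power law is predicted")
  }
  if (is.null(relation)) relation <- function(a, b) (a + b + 1) / (a + b)
  relation(a, b)
}

#' Truncated discrete power-law model
#'
#' \eqn{p(x) = C x^{-\gamma}} on the integer support `xmin..xmax`, with the
#' normalisation constant from the truncated zeta sum (degrees are integers
#' and are capped at `n - 1`, so the discrete truncated normalisation is the
#' natural one). A continuous-integral normalisation is available for
#' comparison via `normalization = "continuous"`.
#'
#' @param gamma exponent.
#' @param xmin,xmax integer support bounds, `1 <= xmin <= xmax`.
#' @param normalization `"discrete"` (default) or `"continuous"`.
#' @return an object of class `powerlaw_model`.
#' @export
powerlaw_model <- function(gamma, xmin, xmax,
                           normalization = c("discrete", "continuous")) {
  normalization <- match.arg(normalization)
  xmin <- as.integer(xmin); xmax <- as.integer(xmax)
  stopifnot(xmin >= 1L, xmax >= xmin, is.finite(gamma))
  norm_const <- if (normalization == "discrete") {
    1 / sum((xmin:xmax)^(-gamma))
  } else if (abs(gamma - 1) < 1e-12) {
    1 / (log(xmax) - log(xmin))
  } else {
    (1 - gamma) / (xmax^(1 - gamma) - xmin^(1 - gamma))
  }
  structure(list(gamma = gamma, xmin = xmin, xmax = xmax,
                 norm_const = norm_const, normalization = normalization),
            class = "powerlaw_model")
}

#' @export
print.powerlaw_model <- function(x, ...) {
  cat(sprintf("Power law p(x) = C x^-%g on [%d, %d], C = %.6g (%s normalisation)\n",
              x$gamma, x$xmin, x$xmax, x$norm_const, x$normalization))
  invisible(x)
}

#' Power-law probability mass
#'
#' @param model a [powerlaw_model()].
#' @param x degree value(s) within the model support.
#' @return `C * x^-gamma`.
#' @export
powerlaw_pdf <- function(model, x) {
  stopifnot(inherits(model, "powerlaw_model"))
  if (any(x < model$xmin) || any(x > model$xmax)) {
    stop(sprintf("x out of model support [%d, %d]", model$xmin, model$xmax))
  }
  model$norm_const * x^(-model$gamma)
}

#' Expected mean degree under a power-law model
#'
#' `sum(x * p(x))` over the support; strictly increasing in `xmin` at fixed
#' `gamma` and `xmax` — raising the degree floor means more edges and hence a
#' shorter reachable average path length.
#'
#' @param model a [powerlaw_model()].
#' @return the mean degree.
#' @export
expected_mean_degree <- function(model) {
  stopifnot(inherits(model, "powerlaw_model"))
  xs <- model$xmin:model$xmax
  sum(xs * powerlaw_pdf(model, xs))
}

#' Default regime breakpoints along the path-length spectrum
#'
#' The model pins only the endpoints (`c = 1` complete, `c = (n+1)/3` linear
#' regular) and the small-world anchor `c = ln n`; the inner boundaries
#' between Delta-distribution, compact, community and fractal regimes are not
#' sharply defined, so these are labelled heuristics. The scale
#' `L = ln(n)/sqrt(xmin)` shifts every breakpoint left as the degree floor
#' grows (a denser floor means shorter proper path lengths), matching e.g.
#' `c = ln N` being small-world at `xmin = 1` but already fractal at
#' `xmin = 3`.
#'
#' @param n node count.
#' @param xmin degree floor.
#' @return named list of breakpoints (all in hops) plus the regular-regime
#'   fraction of the maximum `c`.
#' @export
regime_breakpoints <- function(n, xmin = 1) {
  L <- log(n) / sqrt(xmin)
  list(delta = 0.5 * L, compact = 0.9 * L, fractal = 1.3 * L,
       regular_frac = 0.95, small_world_band = 0.10, ultra_kappa = 1.0)
}

#' Classify the network regime implied by a path-length constraint
#'
#' Deterministic label from ordered breakpoints along increasing `c`:
#' complete, delta_distribution, compact, community, fractal, regular.
#' Additional tags: `small_world` when `c` is within 10% of `ln n`,
#' `ultra_small_world` when `c <= kappa * ln(ln n)`.
#'
#' @param c target average shortest path length, in `[1, (n+1)/3]`.
#' @param n node count.
#' @param xmin degree floor (shifts all breakpoints left as it grows).
#' @param breakpoints optional list as returned by [regime_breakpoints()].
#' @return an object of class `regime_label` with fields `label`, `tags`,
#'   `breakpoints_used`.
#' @examples
#' classify_regime(1, 300, 1)$label          # "complete"
#' classify_regime(log(300), 300, 1)$tags    # tagged "small_world"
#' @export
classify_regime <- function(c, n, xmin = 1, breakpoints = NULL) {
  cmax <- (n + 1) / 3
  if (c < 1 - 1e-9 || c > cmax + 1e-9) {
    stop(sprintf("c = %g out of range [1, %g]", c, cmax))
  }
  bp <- if (is.null(breakpoints)) regime_breakpoints(n, xmin) else breakpoints
  label <- if (c <= 1 + 1e-9) {
    "complete"
  } else if (c >= bp$regular_frac * cmax) {
    "regular"
  } else if (c < bp$delta) {
    "delta_distribution"
  } else if (c < bp$compact) {
    "compact"
  } else if (c <= bp$fractal) {
    "community"
  } else {
    "fractal"
  }
  tags <- character(0)
  if (abs(c - log(n)) <= bp$small_world_band * log(n)) tags <- c(tags, "small_world")
  if (n > 3 && c <= bp$ultra_kappa * log(log(n))) tags <- c(tags, "ultra_small_world")
  structure(list(label = label, tags = tags, breakpoints_used = bp),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s%s\n", x$label,
              if (length(x$tags)) paste0(" [", paste(x$tags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Warn when the path-length constraint is not "proper"
#'
#' A constraint is proper when it does not itself distort the degree
#' distribution; heuristically, when it falls inside the compact-to-fractal
#' band of the spectrum. Qualitative only — a warning aid, never a hard rule.
#'
#' @inheritParams classify_regime
#' @return `TRUE` (proper) or `FALSE` (with a warning), invisibly.
#' @export
check_proper_c <- function(c, n, xmin = 1, breakpoints = NULL) {
  bp <- if (is.null(breakpoints)) regime_breakpoints(n, xmin) else breakpoints
  proper <- c >= bp$delta && c <= bp$fractal
  if (!proper) {
    warning(sprintf(
      "c = %g is outside the proper band [%.2f, %.2f] for n = %d, xmin = %d; the constraint itself may distort the degree distribution",
      c, bp$delta, bp$fractal, n, xmin))
  }
  invisible(proper)
}
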