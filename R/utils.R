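`%||%` <- function(a, b) if (is.null(a)) b else a

## reverse-complement lookup for allele strings (SNVs only)
.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

## palindromic = allele pair is its own reverse complement (A/T or C/G)
.is_palindromic <- function(a1, a2) {
  toupper(a1) == .complement(toupper(a2))
}

## clamp p-values into (0, 1]; underflowed tails are reported at the floor
.clamp_p <- function(p, floor = 1e-300) pmin(pmax(p, floor), 1)

.z2p <- function(z) .clamp_p(2 * stats::pnorm(-abs(z)))

#' Upper-tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(Q > q)` where `Q = sum_k lambda_k * X_k`, `X_k ~ chi^2_1`
#' independent. This is the null distribution of a quadratic form in
#' correlated standard normals with `lambda` the eigenvalues of their
#' correlation matrix; it is used for the HEIDI heterogeneity statistic.
#'
#' The default method is numerical inversion of the characteristic function
#' (Imhof's formula) via [stats::integrate()]. When the inversion fails or is
#' numerically unreliable (very small tails), a Satterthwaite moment-matched
#' scaled chi-square approximation is used instead. The method actually used
#' is recorded in the `"method"` attribute.
#'
#' @param q Observed statistic (scalar, `>= 0`).
#' @param lambda Numeric vector of weights (eigenvalues). Tiny negative
#'   values arising from floating-point eigendecompositions are clipped to 0.
#' @param method `"imhof"` (default, with fallback) or `"satterthwaite"`.
#' @return Upper-tail probability in `(0, 1]`, with attribute `method`.
#' @export
p_quadform <- function(q, lambda, method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  lambda <- lambda[is.finite(lambda)]
  lambda[lambda < 0 & lambda > -1e-8] <- 0
  lambda <- lambda[abs(lambda) > 1e-12]
  if (length(lambda) == 0L) {
    return(structure(1, method = "degenerate"))
  }
  if (q <= 0) {
    return(structure(1, method = "degenerate"))
  }
  satter <- function() {
    s1 <- sum(lambda)
    s2 <- sum(lambda^2)
    a <- s2 / s1
    nu <- s1^2 / s2
    .clamp_p(stats::pchisq(q / a, df = nu, lower.tail = FALSE))
  }
  if (method == "satterthwaite") {
    return(structure(satter(), method = "satterthwaite"))
  }
  if (length(lambda) == 1L && lambda[1] > 0) {
    ## single weight: exact scaled chi-square
    return(structure(
      .clamp_p(stats::pchisq(q / lambda[1], df = 1, lower.tail = FALSE)),
      method = "exact-chisq"))
  }
  integrand <- function(u) {
    ## Imhof (1961): theta(u) = 0.5 * sum(atan(lambda u)) - 0.5 q u
    ##               rho(u)   = prod (1 + lambda^2 u^2)^(1/4)
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    out <- sin(theta) / (u * exp(lrho))
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  ## integrate in chunks of a few oscillation periods; the infinite-range
  ## QUADPACK transform is unreliable on this oscillatory integrand
  L <- 8 * max(4 * pi / q, 4 * pi / (sum(lambda) + q))
  total <- 0
  small_run <- 0L
  ok <- TRUE
  for (m in seq_len(3000L)) {
    val <- tryCatch(
      stats::integrate(integrand, lower = (m - 1) * L, upper = m * L,
                       subdivisions = 300L, rel.tol = 1e-9,
                       abs.tol = 1e-12, stop.on.error = FALSE),
      error = function(e) NULL)
    if (is.null(val)) { ok <- FALSE; break }
    total <- total + val$value
    small_run <- if (abs(val$value) < 1e-9) small_run + 1L else 0L
    if (small_run >= 3L) break
  }
  p <- 0.5 + total / pi
  if (!ok || !is.finite(p) || p < 1e-7 || p > 1 + 1e-6 || small_run < 3L) {
    ## inversion failed or its noise floor dominates; use the moment match
    return(structure(satter(), method = "satterthwaite"))
  }
  structure(.clamp_p(min(p, 1)), method = "imhof")
}

## stable id for messages
.fmt_ids <- function(ids, max = 5L) {
  if (length(ids) <= max) paste(ids, collapse = ", ")
  else paste0(paste(head(ids, max), collapse = ", "), ", ... (", length(ids), " total)")
}
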