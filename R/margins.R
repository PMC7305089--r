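#' Combine two error components in quadrature
#'
#' Total systematic and random errors combine the inter- and intrafractional
#' components as Sigma = sqrt(Sigma_inter^2 + Sigma_intra^2) and likewise
#' for sigma.
#'
#' @param a,b non-negative error components (mm); vectorised.
#' @return sqrt(a^2 + b^2).
#' @export
combine_quadrature <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("error components must be >= 0")
  sqrt(a^2 + b^2)
}

#' Stroom CTV-to-PTV margin
#'
#' Population margin recipe `2.0 * Sigma + 0.7 * sigma`.
#' @param Sigma,sigma total systematic and random errors (mm, >= 0);
#'   vectorised.
#' @return margin in mm.
#' @export
stroom_margin <- function(Sigma, sigma) {
  if (any(Sigma < 0) || any(sigma < 0)) stop("inputs must be >= 0")
  2.0 * Sigma + 0.7 * sigma
}

#' van Herk CTV-to-PTV margin
#'
#' Population margin recipe `2.5 * Sigma + 0.7 * sigma`.
#' @inheritParams stroom_margin
#' @return margin in mm.
#' @export
van_herk_margin <- function(Sigma, sigma) {
  if (any(Sigma < 0) || any(sigma < 0)) stop("inputs must be >= 0")
  2.5 * Sigma + 0.7 * sigma
}

#' Per-axis margin report from inter- and intrafractional statistics
#'
#' Combines the Sigma and sigma rows of two [error_stats] objects in
#' quadrature and evaluates both margin recipes on the unrounded totals.
#'
#' @param inter,intra `error_stats` for the two components.
#' @return object of class `margin_table`: a data frame with columns `axis`,
#'   `sigma_sys_total`, `sigma_rand_total`, `margin_stroom_mm`,
#'   `margin_vanherk_mm` (all unrounded).
#' @export
margin_report <- function(inter, intra) {
  stopifnot(inherits(inter, "error_stats"), inherits(intra, "error_stats"))
  Sig <- combine_quadrature(inter$stats["Sigma", ], intra$stats["Sigma", ])
  sig <- combine_quadrature(inter$stats["sigma", ], intra$stats["sigma", ])
  out <- data.frame(axis = axis_names(),
                    sigma_sys_total = as.numeric(Sig),
                    sigma_rand_total = as.numeric(sig),
                    margin_stroom_mm = as.numeric(stroom_margin(Sig, sig)),
                    margin_vanherk_mm = as.numeric(van_herk_margin(Sig, sig)),
                    row.names = NULL)
  class(out) <- c("margin_table", "data.frame")
  out
}

#' @export
print.margin_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round_half_up, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used in the human-readable margin tables (2.375 -> 2.38),
#' as opposed to R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Margin table in display layout
#'
#' Reshapes a [margin_report()] result into the conventional block layout:
#' rows Sigma, sigma, Stroom, van Herk; columns LR, SI, AP; values rounded
#' half-up to `digits` decimals.
#'
#' @param x a `margin_table`.
#' @param digits decimal places for display.
#' @return 4 x 3 numeric matrix.
#' @export
format_margin_block <- function(x, digits = 2) {
  stopifnot(inherits(x, "margin_table"))
  m <- rbind(Sigma = x$sigma_sys_total, sigma = x$sigma_rand_total,
             Stroom = x$margin_stroom_mm, `van Herk` = x$margin_vanherk_mm)
  colnames(m) <- x$axis
  round_half_up(m, digits)
}
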