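# Closed-form companions to the damage simulator, and the standardized
# linear model relating damage parameters to placement error.

#' Theoretical median fragment length
#'
#' Under per-junction nicking with probability `nu`, interior fragment
#' lengths are geometric on `{1, 2, ...}` with success probability `nu`, so
#' the median fragment length is `floor(-ln 2 / ln(1 - nu))`, and infinite
#' when `nu = 0` (no nicks, one unbroken fragment).
#'
#' @param nu nick probability (vectorized) in `[0, 1]`.
#' @return numeric vector of median lengths (`Inf` at `nu = 0`).
#' @examples
#' theoretical_median_fragment_length(c(0, 0.001, 0.025, 0.03))
#' @export
theoretical_median_fragment_length <- function(nu) {
  if (any(!is.finite(nu)) || any(nu < 0 | nu > 1)) {
    stop("'nu' must be in [0, 1]")
  }
  out <- ifelse(nu == 0, Inf,
                ifelse(nu == 1, 1, floor(-log(2) / log1p(-nu))))
  out
}

#' Expected per-position misincorporation profile
#'
#' The closed-form damage profile over a population of reads of fixed
#' length: with a 5'/3' overhang assigned 50/50 and geometric overhang
#' length `L` (`P(L >= k) = (1 - lam)^k`), the expected probability that an
#' *eligible* base at 1-based position `p` from the 5' end carries a C->T
#' misincorporation is
#'
#'   `0.5 * ((1 - lam)^p * delta_ss + (1 - (1 - lam)^p) * delta_ds)`
#'
#' and the G->A profile mirrors it from the 3' end. The overhang-rate excess
#' (`delta_ss >> delta_ds`) concentrates damage at read ends, producing the
#' characteristic U-shaped curve.
#'
#' @param params a [damage_params()] object.
#' @param read_len read length (>= 1).
#' @return data.frame with columns `position` (1-based from the 5' end),
#'   `ct` (C->T probability), `ga` (G->A probability).
#' @export
expected_damage_profile <- function(params, read_len) {
  stopifnot(inherits(params, "damage_params"), read_len >= 1)
  p <- seq_len(read_len)
  in_overhang <- (1 - params$lam)^p                   # P(position in overhang)
  ct <- 0.5 * (in_overhang * params$delta_ss +
               (1 - in_overhang) * params$delta_ds)
  data.frame(position = p, ct = ct, ga = rev(ct))
}

#' Per-read misincorporation rate
#'
#' The fraction of non-gap sites in a read that differ from the source
#' sequence, i.e. the number of damage events divided by the non-gap length.
#'
#' @param read a damaged read.
#' @return a real in `[0, 1]`.
#' @export
per_read_error_rate <- function(read) {
  n <- nongap_length(read)
  if (n == 0) stop("read '", read$read_id, "' has zero non-gap length")
  nrow(read$events) / n
}

#' Crossover overhang length
#'
#' The smallest overhang length at which the expected number of
#' single-stranded deamination events exceeds the expected number of
#' double-stranded events over a whole read: the least integer `k` with
#' `k * delta_ss > read_len * delta_ds`. For typical ancient-DNA rates an
#' overhang of only a few bases already contributes more expected errors
#' than the entire protected region.
#'
#' @param read_len read length in bp.
#' @param delta_ss single-stranded deamination probability (> 0).
#' @param delta_ds double-stranded deamination probability.
#' @return positive integer.
#' @examples
#' crossover_overhang_length(100, 0.65, 0.015)  # 3
#' @export
crossover_overhang_length <- function(read_len, delta_ss, delta_ds) {
  if (delta_ss <= 0) stop("'delta_ss' must be > 0 (no crossover otherwise)")
  stopifnot(read_len >= 1, delta_ds >= 0)
  k <- floor(read_len * delta_ds / delta_ss) + 1L
  as.integer(k)
}

#' Standardized linear model of placement error
#'
#' Ordinary least squares of expected node distance on the four damage
#' parameters after z-scoring each predictor (mean 0, SD 1), so the
#' coefficients are directly comparable across parameters with different
#' native scales. Because standardization is affine-invariant, rescaling a
#' predictor's units leaves its standardized coefficient unchanged.
#'
#' @param table data.frame with numeric columns `nu`, `lam`, `delta_ds`,
#'   `delta_ss`, and the response `end`.
#' @return an object of class `std_lm_fit`: list with `coefficients` (named,
#'   one per predictor), `intercept`, `sigma2` (residual variance),
#'   `p_values`, `n`, and the underlying `lm` fit.
#' @export
standardized_linear_fit <- function(table) {
  predictors <- c("nu", "lam", "delta_ds", "delta_ss")
  need <- c(predictors, "end")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("expected a data.frame with columns ", paste(need, collapse = ", "))
  }
  if (nrow(table) < 6) stop("at least 6 rows are required")
  sds <- vapply(table[predictors], stats::sd, 0)
  constant <- predictors[sds == 0 | is.na(sds)]
  if (length(constant) == length(predictors)) {
    stop("all predictors are constant: ", paste(constant, collapse = ", "))
  }
  if (length(constant) > 0) {
    stop("constant (collinear) predictor(s): ",
         paste(constant, collapse = ", "))
  }
  z <- as.data.frame(lapply(table[predictors], function(x) {
    (x - mean(x)) / stats::sd(x)
  }))
  z$end <- table$end
  mm <- stats::model.matrix(end ~ nu + lam + delta_ds + delta_ss, data = z)
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    fit0 <- stats::lm(end ~ nu + lam + delta_ds + delta_ss, data = z)
    aliased <- names(which(is.na(stats::coef(fit0))))
    stop("rank-deficient design; collinear predictor(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(end ~ nu + lam + delta_ds + delta_ss, data = z)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  structure(list(coefficients = coefs[predictors],
                 intercept = unname(coefs["(Intercept)"]),
                 sigma2 = sm$sigma^2,
                 p_values = sm$coefficients[predictors, "Pr(>|t|)"],
                 n = nrow(table),
                 fit = fit),
            class = "std_lm_fit")
}

#' @export
print.std_lm_fit <- function(x, ...) {
  cat("Standardized linear model of eND on damage parameters (n =",
      x$n, ")\n")
  tab <- data.frame(coefficient = x$coefficients, p_value = x$p_values)
  print(tab, ...)
  cat(sprintf("intercept %.4g, residual variance %.4g\n",
              x$intercept, x$sigma2))
  invisible(x)
}
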