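#' Age-band schemes for discrete-time survival
#'
#' Child mortality over a multi-year age block is built from monthly
#' probabilities of dying that are constant within age bands. The under-5
#' scheme uses six bands -- [0,1) months to isolate neonatal mortality, then
#' [1,12) and four one-year bands up to exact age 5. The 5-14 scheme uses ten
#' one-year bands covering months [60,180).
#'
#' @param age_group `"u5"` or `"5to14"`.
#' @return An object of class `age_scheme`: a list with `age_group`,
#'   `start` / `end` (band boundaries in completed months, end exclusive),
#'   `width` (band widths in months) and `n_bands`.
#' @examples
#' age_scheme("u5")$width   # 1 11 12 12 12 12
#' @export
age_scheme <- function(age_group = c("u5", "5to14")) {
  age_group <- match.arg(age_group)
  if (age_group == "u5") {
    start <- c(0L, 1L, 12L, 24L, 36L, 48L)
    end   <- c(1L, 12L, 24L, 36L, 48L, 60L)
  } else {
    start <- seq(60L, 168L, by = 12L)
    end   <- start + 12L
  }
  structure(list(age_group = age_group, start = start, end = end,
                 width = end - start, n_bands = length(start)),
            class = "age_scheme")
}

#' @export
print.age_scheme <- function(x, ...) {
  cat(sprintf("<age_scheme %s: %d bands over months [%d,%d)>\n",
              x$age_group, x$n_bands, x$start[1], x$end[x$n_bands]))
  invisible(x)
}

#' Map an age in completed months to its band index
#'
#' @param age_months integer vector of ages in completed months.
#' @param scheme an [age_scheme()].
#' @return Integer band indices; `NA` outside the scheme's support.
#' @export
age_band_index <- function(age_months, scheme) {
  idx <- findInterval(age_months, scheme$start)
  idx[age_months < scheme$start[1] | age_months >= scheme$end[scheme$n_bands]] <- NA_integer_
  idx
}

#' Combine per-band monthly probabilities into a block probability
#'
#' The probability of dying across the whole age block is one minus the
#' product of band-level monthly survival probabilities, each raised to the
#' band width in months:
#' \deqn{q = 1 - \prod_a (1 - {}_1q_a)^{n_a}.}
#'
#' @param monthly_q numeric vector of per-band monthly probabilities of dying.
#' @param scheme an [age_scheme()] (supplies the band widths).
#' @return The block probability of dying (scalar).
#' @export
block_q_from_monthly <- function(monthly_q, scheme) {
  stopifnot(length(monthly_q) == scheme$n_bands)
  ## log-scale product for numerical stability at small q
  1 - exp(sum(scheme$width * log1p(-monthly_q)))
}

#' Derive per-band monthly probabilities from a block probability
#'
#' Inverts [block_q_from_monthly()]: given a target block probability and
#' relative band levels on the hazard scale, returns the monthly probability
#' schedule that reproduces the block probability exactly. Writing the
#' monthly hazard in band a as h_a = c * m_a (m the multipliers), the product
#' constraint is linear in c on the cumulative-hazard scale, so
#' c = -log(1 - q) / sum(m_a * n_a) in closed form.
#'
#' @param block_q target probability of dying over the block, in (0, 1).
#' @param scheme an [age_scheme()].
#' @param multipliers positive per-band relative hazard levels (default: flat).
#' @return An object of class `hazard_schedule`: list with `scheme`,
#'   `monthly_q` (per band) and `multipliers`.
#' @export
hazards_from_block_q <- function(block_q, scheme, multipliers = NULL) {
  if (!is.numeric(block_q) || length(block_q) != 1 || is.na(block_q) ||
      block_q <= 0 || block_q >= 1)
    stop("`block_q` must be a single probability strictly inside (0, 1)")
  if (is.null(multipliers)) multipliers <- rep(1, scheme$n_bands)
  stopifnot(length(multipliers) == scheme$n_bands, all(multipliers > 0))
  cons <- -log1p(-block_q) / sum(multipliers * scheme$width)
  monthly_q <- -expm1(-cons * multipliers)
  structure(list(scheme = scheme, monthly_q = monthly_q,
                 multipliers = multipliers),
            class = "hazard_schedule")
}

#' @export
print.hazard_schedule <- function(x, ...) {
  cat(sprintf("<hazard_schedule %s: block q = %.5f>\n", x$scheme$age_group,
              block_q_from_monthly(x$monthly_q, x$scheme)))
  print(round(x$monthly_q, 6))
  invisible(x)
}

#' Logit and inverse-logit
#' @param p probability in (0, 1).
#' @param x real value.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))
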