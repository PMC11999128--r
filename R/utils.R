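#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage labels of the four-state progression model
#'
#' The four disease stages are the cross of metabolic-goal status
#' (ON = HbA1c strictly below the personal goal, OUT = at or above it) and
#' chronic-complication status (NOT = none of retinopathy, cerebrovascular
#' disease, chronic kidney disease; YES = at least one). This ordering is
#' used for every transition-matrix row and column in the package.
#'
#' @return Character vector of the four stage labels, in canonical order.
#' @export
stage_levels <- function() c("ON-NOT", "OUT-NOT", "ON-YES", "OUT-YES")

is_complication_stage <- function(stage) stage %in% c("ON-YES", "OUT-YES")

is_on_goal_stage <- function(stage) stage %in% c("ON-NOT", "ON-YES")

## inverse-CDF draws from N(mean, sd) truncated to [lower, upper]; fully
## vectorised over mean/sd/bounds (recycled to length n)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  out <- pmin(pmax(mean, lower), upper)  # degenerate sd = 0 case
  ok <- sd > 0
  if (any(ok)) {
    plo <- stats::pnorm(lower[ok], mean[ok], sd[ok])
    phi <- stats::pnorm(upper[ok], mean[ok], sd[ok])
    u <- stats::runif(sum(ok), plo, pmax(phi, plo + 1e-12))
    x <- stats::qnorm(pmin(u, 1 - 1e-16), mean[ok], sd[ok])
    out[ok] <- pmin(pmax(x, lower[ok]), upper[ok])
  }
  out
}

## pack/unpack semicolon-separated list columns used in cohort tables
pack_list <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))

unpack_list <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
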