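# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x))) computed without overflow
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Round half away from zero
#'
#' Metric tables are reported on the percent scale with conventional half-up
#' rounding (`82.345 -> 82.35`), not IEEE round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

trignet_abort <- function(message, class = "trignet_error", ...) {
  rlang::abort(message, class = c(class, "trignet_error"), ...)
}

usage_abort <- function(message, ...) {
  trignet_abort(message, class = "trignet_usage_error", ...)
}

# Derive a reproducible child seed (kept below 2^31) from a base seed and tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563L) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Recursive walk over every numeric leaf of a nested parameter list.
# f(leaf, path) -> replacement leaf.  Non-numeric leaves are kept untouched.
map_param_leaves <- function(params, f, path = character()) {
  if (is.numeric(params)) return(f(params, path))
  if (is.list(params)) {
    out <- params
    for (nm in names(params)) {
      out[[nm]] <- map_param_leaves(params[[nm]], f, c(path, nm))
    }
    return(out)
  }
  params
}

# Combine two structurally identical nested parameter lists leafwise.
combine_param_leaves <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- combine_param_leaves(a[[nm]], b[[nm]], f)
    return(out)
  }
  a
}

# Reduce over numeric leaves: f(acc, leaf) -> acc.
reduce_param_leaves <- function(params, f, init) {
  acc <- init
  walk <- function(p) {
    if (is.numeric(p)) {
      acc <<- f(acc, p)
    } else if (is.list(p)) {
      for (el in p) walk(el)
    }
    invisible(NULL)
  }
  walk(params)
  acc
}

zeros_like <- function(params) {
  map_param_leaves(params, function(leaf, path) leaf * 0)
}
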