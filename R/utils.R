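#' @keywords internal
"_PACKAGE"

# Error helper: all package errors are classed conditions so callers (and the
# tests) can distinguish failure modes without matching message text.
pc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "paircomm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pc_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stage and per-draw seeds are derived by hashing a character label together
#' with the master seed, so results do not depend on the order in which
#' stochastic stages run. The hash is a plain polynomial rolling hash over the
#' UTF-8 bytes of the label, reduced modulo 2^31 - 1 (a Mersenne prime), which
#' keeps the result inside R's integer range.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stage or draw.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.double(master) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate an expression with a local RNG state seeded from (master, label),
# restoring the caller's RNG state afterwards.
with_seed <- function(master, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(derive_seed(master, label))
  expr
}

# Empirical two-tailed permutation p-value with add-one smoothing:
# p = min(1, 2 * min((#null >= obs) + 1, (#null <= obs) + 1) / (n + 1)).
perm_p_two_tailed <- function(obs, null_values) {
  n <- length(null_values)
  up <- sum(null_values >= obs)
  dn <- sum(null_values <= obs)
  min(1, 2 * (min(up, dn) + 1) / (n + 1))
}

# Empirical 95% expected set (2.5 and 97.5 percentiles) of a null sample.
expected_set_95 <- function(values) {
  q <- stats::quantile(values, probs = c(0.025, 0.975), names = FALSE,
                       type = 7)
  c(low = q[1], high = q[2])
}
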