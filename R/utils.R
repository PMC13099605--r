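# internal argument checks shared across modules

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop("'", name, "' must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(if (strict) x <= 0 else x < 0))
    stop("'", name, "' must be ", if (strict) "> 0" else ">= 0",
         call. = FALSE)
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer or NULL", call. = FALSE)
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# gas constant, kJ mol^-1 K^-1
.R_GAS <- 8.314462618e-3

celsius_to_kelvin <- function(t_c) t_c + 273.15

# lognormal multiplier with unit mean and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
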