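# Internal numeric helpers shared across modules.

# Round half away from zero, the convention the instrument tables use.
# base::round() rounds half to even, which turns 0.365 into 0.36.
round_half_up <- function(x, digits = 0) {
  scaled <- round(x * 10^digits, 9)  # shave float dust before the half test
  sign(x) * floor(abs(scaled) + 0.5) / 10^digits
}

# Ceiling at `digits` decimals; used only for the limit of detection, which is
# the smallest reportable concentration and so must never round downwards.
ceiling_digits <- function(x, digits = 0) {
  ceiling(round(x * 10^digits, 9)) / 10^digits
}

stop_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mosaicdpcr_error"))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("`%s` must be a single non-missing number.", name),
               "mosaicdpcr_domain_error")
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stop_input(sprintf("`%s` = %s is outside its allowed range.", name, format(x)),
               "mosaicdpcr_domain_error")
  }
  invisible(x)
}
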