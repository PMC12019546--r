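# Internal helpers shared across modules.

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

MONTH_LABELS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                  "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# Molar mass ratio CO2 : C and N2O : N2O-N.
CO2_PER_C <- 44 / 12
N2O_PER_N <- 44 / 28

abort_grazenet <- function(message, class) {
  rlang::abort(message, class = c(class, "grazenet_error"))
}

stop_param <- function(message) abort_grazenet(message, "grazenet_parameter_error")
stop_format <- function(message) abort_grazenet(message, "grazenet_format_error")
stop_alignment <- function(message) abort_grazenet(message, "grazenet_alignment_error")

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_param(sprintf("`%s` must be a single non-missing number", name))
  }
  if (x < min || x > max) {
    stop_param(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x))
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, min = 0, max = 1)

# Seeds derived for sub-stages stay well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
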