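# Small shared helpers.

# Round half away from zero, the convention used for all reported percentages.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest exponent for which 1 - exp(-eta) is still representable below 1.
# Beyond this the probability would silently print as 1.0, which the model
# forbids: Ln < 1 for every finite parameter set.
.max_eta <- function() -log(.Machine$double.eps / 2)
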