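#' @keywords internal
"_PACKAGE"

## Shared internal helpers.

# Order rows by (chrom, pos); chrom compared lexicographically so reruns are
# stable regardless of input order.
cpg_order <- function(chrom, pos) order(chrom, pos, method = "radix")

# Deterministic integer sub-seed derived from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97L + offset) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mm <- function(...) stop(sprintf(...), call. = FALSE)

notice <- function(...) message("[methylmark] ", sprintf(...))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
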