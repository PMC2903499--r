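`%||%` <- function(a, b) if (is.null(a)) b else a

## sample from the elements of x (safe for length-1 vectors, unlike
## base::sample's scalar special case)
.resample <- function(x, size = length(x)) x[sample.int(length(x), size)]
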