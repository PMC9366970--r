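# Condition helpers. Two error families are distinguished throughout:
# structural (malformed input) and degenerate (well-formed input on which the
# quantity is undefined, e.g. all-zero popularity).

pa_stop_structural <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("pa_structural_error", "pa_error")))
}

pa_stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("pa_degenerate_error", "pa_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

# squared euclidean distances between rows of a (n x 2) and rows of b (m x 2)
cross_dist <- function(ax, ay, bx, by) {
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  sqrt(dx * dx + dy * dy)
}
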