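#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp kmeans rnbinom rlnorm runif var sd
#' @importFrom utils write.csv read.csv head
#' @importFrom methods as is
NULL

# Deterministically derive a stage seed from a master seed. Keeps the result
# strictly inside 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(stage)) * 131L
  as.integer((abs(as.numeric(seed)) * 48271 + offs) %% 2147483629 + 1)
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`", name, "` must be a finite numeric scalar")
  if (x < lower || x > upper)
    stop_param("`", name, "` must be in [", lower, ", ", upper, "], got ", x)
  if (integerish && x != round(x))
    stop_param("`", name, "` must be a whole number, got ", x)
  invisible(x)
}

# Labels arrive as anything coercible to character; classes are mapped to
# integer codes in lexicographic order of their names so that the class
# order is reproducible across runs and input orderings.
as_condition_factor <- function(labels) {
  lab <- as.character(labels)
  factor(lab, levels = sort(unique(lab)))
}
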