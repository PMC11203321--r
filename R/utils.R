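#' @keywords internal
"_PACKAGE"

#' @importFrom stats var sd cor optimize rnorm runif rbinom rpois pt p.adjust
#'   prcomp model.matrix aggregate setNames complete.cases quantile
#' @importFrom utils read.table write.table head
#' @importFrom methods is
NULL

# stop() wrapper for argument validation; all user-facing precondition
# failures funnel through here so tests can match class "flowerGS_error"
.fail <- function(msg, class = "invalid_argument") {
  stop(structure(
    class = c(paste0("flowerGS_", class), "flowerGS_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    .fail(sprintf("`%s` must be a single integer >= %d (got %s)",
                  name, min, paste(x, collapse = ",")))
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi || (open_hi && x >= hi))
    .fail(sprintf("`%s` must be in [%g, %g%s (got %g)", name, lo, hi,
                  if (open_hi) ")" else "]", x))
  as.numeric(x)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
}

# deterministic child seed, kept well below 2^31
.child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2000000011L
}
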