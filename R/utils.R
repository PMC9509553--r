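# Shared constants and small helpers.

#' Timepoint vocabulary
#'
#' Ordered timepoint labels of the sampling scheme and their position in hours
#' after the first anti-TNF infusion. RNA was sampled at all seven timepoints;
#' methylation only at baseline, week 2 and week 6.
#'
#' @return `timepoint_levels()` returns the ordered character vector of labels;
#'   `timepoint_hours()` a named numeric vector mapping label to hours;
#'   `methylation_timepoints()` the subset of labels with methylation sampling.
#' @export
timepoint_levels <- function() {
  c("baseline", "4h", "24h", "72h", "2w", "6w", "14w")
}

#' @rdname timepoint_levels
#' @export
timepoint_hours <- function() {
  stats::setNames(c(0, 4, 24, 72, 336, 1008, 2352), timepoint_levels())
}

#' @rdname timepoint_levels
#' @export
methylation_timepoints <- function() {
  c("baseline", "2w", "6w")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result within 32-bit integer range.
child_seed <- function(seed, stream) {
  digits <- utf8ToInt(as.character(stream))
  as.integer((as.numeric(seed) * 1000003 + sum(digits * seq_along(digits))) %% 2147483629L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_tnf <- function(...) stop(sprintf(...), call. = FALSE)

# Logistic and logit, used on the methylation M-value scale and in the impulse
# model.
sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Canonical TSV writers/readers: tab separated, header, no quoting, no row
# names. A fixed dialect keeps pipeline reruns byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
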