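#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Consistent stop() with the calling function's name stripped from the call.
stop2 <- function(...) stop(..., call. = FALSE)

check_matrix_labels <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop2(what, " must have row and column names")
  }
  invisible(m)
}

## Benjamini-Hochberg within a grouping vector; NA p-values stay NA and do
## not count toward the denominator of their group.
adjust_within <- function(p, group) {
  out <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}
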