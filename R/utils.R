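#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a root seed
#'
#' All stochastic stages draw their seeds from a single root seed through this
#' deterministic map, so that one integer reproduces an entire pipeline while
#' distinct stages and replicate indices still see distinct streams.
#'
#' @param root integer root seed.
#' @param stage character stage label (e.g. `"simulate"`, `"fit"`).
#' @param index replicate index within the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stage = "stage", index = 1L) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- as.double(root) %% 2147483647
  for (ch in utf8ToInt(paste0(stage, ":", format(index)))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
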