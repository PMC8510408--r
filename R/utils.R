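#' @keywords internal
"_PACKAGE"

## Shared internal helpers: argument checks and seed scoping.

stop_domain <- function(...) {
  stop(structure(
    class = c("bilemix_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_schema <- function(...) {
  stop(structure(
    class = c("bilemix_schema_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}

check_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    bounds <- if (open) "(0, 1)" else "[0, 1]"
    stop_domain(sprintf("`%s` must lie in %s", name, bounds))
  }
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream.
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
    })
    set.seed(seed)
  }
  expr
}
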