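# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user-level streams.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_invalid(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(field, "must be a single number in [0, 1]")
  as.numeric(x)
}

# Largest-remainder apportionment of n into parts proportional to p.
# Ties broken by position order, optionally rotated by `rotate` positions
# (used by stratified splitting so remainder units spread across partitions
# rather than always favoring the same one).
largest_remainder <- function(n, p, rotate = 0) {
  raw <- n * p
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    tb <- (seq_along(p) - 1 - rotate) %% length(p)
    ord <- order(-rem, tb)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

CLASS_LEVELS <- c("AD", "PD", "HC")

check_label <- function(x, field = "label") {
  x <- as.character(x)
  bad <- !x %in% CLASS_LEVELS
  if (any(bad))
    stop_invalid(field, sprintf("must be one of %s (got '%s')",
                                paste(CLASS_LEVELS, collapse = "/"), x[which(bad)[1]]))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
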