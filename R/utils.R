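# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA strings
#' @param n number of strings
#' @param len string length
#' @keywords internal
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(DNA_BASES, n * len, replace = TRUE)
  dim(chars) <- c(len, n)
  do.call(paste0, as.data.frame(t(chars), stringsAsFactors = FALSE))
}

#' Generate n unique random DNA strings
#' @keywords internal
rand_dna_unique <- function(n, len) {
  out <- unique(rand_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, rand_dna(n - length(out) + 10L, len)))
  }
  out[seq_len(n)]
}

#' Apply one random substitution to each string
#' @keywords internal
corrupt_one_base <- function(x, len) {
  k <- length(x)
  if (k == 0L) return(x)
  pos <- sample.int(len, k, replace = TRUE)
  old <- substr(x, pos, pos)
  new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  substr(x, pos, pos) <- new
  x
}

#' Evaluate an expression under a temporary RNG seed, restoring caller state
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stop with a configuration error naming the offending field
#' @keywords internal
config_stop <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    config_stop(field, "must be a fraction in [0, 1]")
  invisible(x)
}
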