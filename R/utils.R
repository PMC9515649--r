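# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 20 standard amino-acid letters
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_protein <- function(seq, what = "protein sequence") {
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seq)
  if (any(bad)) {
    stop_bad("%s contains letters outside the 20 amino acids plus X", what)
  }
  invisible(seq)
}

# Largest-remainder (Hamilton) apportionment of n items to proportions p.
apportion_largest_remainder <- function(n, p) {
  stopifnot(all(p >= 0), sum(p) > 0, n >= 0)
  quota <- n * p / sum(p)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic TSV writer: no quoting surprises, "." decimal, NA as empty.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
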