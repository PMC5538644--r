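# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs `code` in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Write a headered, deterministic TSV table
#'
#' Writes a data frame as a tab-separated file with a header line, no
#' quoting, no row names and Unix line endings.  Double-precision columns
#' are printed with a fixed number of decimals (default 4) so that repeated
#' runs on identical inputs produce byte-identical files; integer and
#' character columns are written verbatim.
#'
#' @param x data frame.
#' @param path output file path.
#' @param digits decimal places for non-integer numeric columns.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, digits = 4) {
  stopifnot(is.data.frame(x))
  out <- x
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      fmt <- sprintf("%%.%df", digits)
      txt <- sprintf(fmt, col)
      txt[is.na(col)] <- "NA"
      out[[j]] <- txt
    }
  }
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Locale-independent sort (radix uses C collation); keeps output files and
# tie-breaks deterministic across machines.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
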