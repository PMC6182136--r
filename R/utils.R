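# Internal helpers: local RNG scoping, seed derivation, TSV/JSON output.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that consume a
#' `seed` argument never disturb the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a parent seed and a stream index
#'
#' Keeps derived seeds in the positive 31-bit range expected by both the
#' R and the C++ generators.
#' @noRd
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 16807 + 12345) %% 2147483647
  as.integer(max(1, s))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stopf("'%s' must be a numeric value of length %d", name, len)
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    stopf("'%s' must be %s %s", name, if (strict) ">" else ">=", format(lower))
  }
  invisible(x)
}

#' Write a table as TSV plus a JSON sidecar (config + seed + version)
#'
#' Every exported table is accompanied by `<path>.json` describing how it
#' was produced, so runs can be reproduced bit-identically.
#' @param tab data.frame to write
#' @param path output TSV path
#' @param config list serialized into the sidecar
#' @return invisibly, the two paths written
#' @export
write_table_tsv <- function(tab, path, config = list()) {
  stopifnot(is.data.frame(tab))
  fmt <- function(x) if (is.double(x)) signif(x, 9) else x
  out <- as.data.frame(lapply(tab, fmt), optional = TRUE)
  names(out) <- names(tab)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- list(
    package = "transokin",
    version = as.character(utils::packageVersion("transokin")),
    config = config
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(path, sidecar))
}

#' Read a TSV table written by [write_table_tsv()]
#' @param path TSV path
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
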