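# Internal helpers shared across modules.

#' Write a TSV atomically (temp file + rename)
#'
#' Consumers polling the output directory must never observe a partially
#' written statistics file, so every emission goes through a temporary file in
#' the same directory followed by an atomic rename.
#'
#' @param x data frame to write.
#' @param path destination path; its directory is created if needed.
#' @return `path`, invisibly.
#' @keywords internal
#' @noRd
write_tsv_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".porewatch-", tmpdir = dirname(path))
  readr::write_tsv(x, tmp, na = "NA", progress = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    abort(paste0("failed to atomically replace ", path),
          class = "porewatch_write_failure")
  }
  invisible(path)
}

# Read a TSV written by write_tsv_atomic() back with exact value round-trips.
# Doubles are parsed with strtod (via type.convert), which restores the
# shortest-round-trip representations bit-for-bit. `classes` maps known column
# names to R classes; columns absent from it are dropped.
read_tsv_exact <- function(path, classes) {
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t",
                     fixed = TRUE)[[1]]
  cc <- setNames(rep("NULL", length(header)), header)
  known <- intersect(header, names(classes))
  cc[known] <- classes[known]
  df <- utils::read.delim(path, sep = "\t", colClasses = cc, na.strings = "NA",
                          quote = "", comment.char = "", check.names = FALSE)
  as_tibble(df)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stop unless all values are finite and strictly positive.
check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive finite number"),
            class = "porewatch_invalid_config")
    }
  }
  invisible(TRUE)
}
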