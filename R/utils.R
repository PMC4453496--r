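#' Derive reproducible child seeds from a master seed
#'
#' A single master seed fans out to one seed per named pipeline stage so that
#' each stage (simulation, twin exclusion, sibship sampling for the
#' Hardy-Weinberg test, ...) is individually reproducible.
#'
#' @param master_seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of seeds, one per stage.
#' @export
#' @examples
#' fan_out_seeds(1L, c("simulate", "twins"))
fan_out_seeds <- function(master_seed, stages) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Write a data frame as a tab-separated table
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input file path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

## shared input checks -------------------------------------------------------

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

`%||%` <- function(a, b) if (is.null(a)) b else a
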