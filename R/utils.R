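`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' A master seed plus a stage label deterministically yields a sub-seed, so
#' every stage of a pipeline run is individually reproducible while stages
#' remain decorrelated. The result is always a positive integer below 2^31.
#'
#' @param seed Master seed (single integer-valued number).
#' @param label Character stage label, e.g. `"pool"` or `"screen1/fastq_gc"`.
#' @return A positive integer scalar.
#' @export
#' @examples
#' derive_seed(7, "pool")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147480009 # prime below 2^31; doubles stay exact throughout
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer((h + (abs(seed) %% m) * 1000003) %% m) + 1L
}

# Internal: fast reverse complement of a character vector assumed ACGT-only.
rc_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

is_dna_chr <- function(x) {
  is.character(x) & !is.na(x) & stringi::stri_detect_regex(x, "^[ACGT]*$")
}

# Half the smallest positive finite value; 0 for an all-zero input.
half_min_positive <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0L) 0 else min(pos) / 2
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
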