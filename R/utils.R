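# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

orthodyn_version <- function() as.character(utils::packageVersion("orthodyn"))

#' Write a tibble as TSV with a provenance header
#'
#' All orthodyn writers emit UTF-8, Unix newlines, and commented (`#`) header
#' lines recording the tool version and the parameters of the run, so output
#' files are self-describing and re-readable by the package's own readers
#' (which skip `#` lines).
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, params = list()) {
  hdr <- paste0("# orthodyn ", orthodyn_version())
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                      character(1)), sep = "=")
    hdr <- c(hdr, paste0("# ", paste(kv, collapse = " ")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n", useBytes = TRUE)
  readr::write_tsv(x, con, col_names = TRUE, append = TRUE, eol = "\n")
  invisible(path)
}

# deterministic RNG scope: everything stochastic in orthodyn flows through this
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  invisible(x)
}
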