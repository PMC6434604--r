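#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

#' Write a TSV with commented metadata header
#'
#' All tabular outputs carry their configuration and seeds as `#`-prefixed
#' header lines so a run can be reconstructed from its outputs.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param meta named list of scalar metadata recorded as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#' @param path file path.
#' @return data.frame (comment lines dropped).
#' @export
read_tsv_commented <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# derive a stream-specific 31-bit seed from a base seed and an index
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% .Machine$integer.max)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
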