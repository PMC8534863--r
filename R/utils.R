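# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so generators are pure functions of their seed and
#' never perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-subject seed derivation; kept below .Machine$integer.max.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 7919 + 104729 * as.double(index)) %%
               2147483587)
}

log_level_rank <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' @keywords internal
log_msg <- function(level, ..., file = NULL) {
  thr <- getOption("pdfftexture.log_level", "info")
  if (log_level_rank[[level]] < log_level_rank[[thr]]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s", toupper(level),
                  format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = ""))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(NULL)
}

stop_pdff <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "pdfftexture_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
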