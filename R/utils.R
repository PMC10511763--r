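#' @keywords internal
"_PACKAGE"

# Logging -----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. The default is "info".
#'
#' @param level One of "debug", "info", "warn", "quiet".
#' @return The previous level, invisibly.
#' @export
shmb_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- getOption("shambhala.log_level", "info")
  options(shambhala.log_level = level)
  invisible(old)
}

shmb_log <- function(msg, level = "info") {
  cur <- getOption("shambhala.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[cur]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), msg))
  }
  invisible(NULL)
}

# Seeding -----------------------------------------------------------------

# Deterministic per-sample seed derived from the master seed and the sample
# identifier (not its position in the batch), so that per-sample outputs do
# not depend on which other samples are processed alongside.
sample_seed <- function(master_seed, sample_id) {
  h <- sum(utf8ToInt(as.character(sample_id)) *
             seq_along(utf8ToInt(as.character(sample_id))))
  as.integer((as.numeric(master_seed) * 7919 + h * 131) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Small numeric helpers ---------------------------------------------------

row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("at least 2 columns required to compute per-gene sd")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}
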