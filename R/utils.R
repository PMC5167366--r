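# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# key separator for index environments; \x1f never occurs in identifiers
.SEP <- "\x1f"

idx_key <- function(...) paste(..., sep = .SEP)

# append values to a vector stored under `key` in environment `env`
idx_add <- function(env, key, value) {
  cur <- env[[key]]
  env[[key]] <- if (is.null(cur)) value else unique(c(cur, value))
  invisible(NULL)
}

idx_remove <- function(env, key, value) {
  cur <- env[[key]]
  if (is.null(cur)) return(invisible(NULL))
  cur <- setdiff(cur, value)
  if (length(cur) == 0) rm(list = key, envir = env) else env[[key]] <- cur
  invisible(NULL)
}

idx_get <- function(env, key) env[[key]] %||% integer(0)

stop_gsknet <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "gsknet_error", "error")))
}

meta_error  <- function(fmt, ...) stop_gsknet(fmt, ..., class = "gsknet_meta_error")
graph_error <- function(fmt, ...) stop_gsknet(fmt, ..., class = "gsknet_graph_error")
parse_error <- function(fmt, ...) stop_gsknet(fmt, ..., class = "gsknet_parse_error")
spec_error  <- function(fmt, ...) stop_gsknet(fmt, ..., class = "gsknet_spec_error")

# normalised name used by the name index and name-based mapping:
# case-folded, whitespace collapsed
norm_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# deterministic text connection (LF endings, UTF-8)
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# open plain or gzip transparently for line-oriented readers
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_all_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

fmt_num <- function(x) {
  # locale/scipen independent numeric formatting for deterministic output
  if (is.integer(x) || (is.numeric(x) && all(x == floor(x)) && all(abs(x) < 2^31))) {
    sprintf("%d", as.integer(x))
  } else {
    sub("\\.?0+$", "", sprintf("%.10f", x))
  }
}
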