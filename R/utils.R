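`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse runs of whitespace, trim, lower-case: the normal form used for
# alias lookup and hypothetical-protein detection
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

# 31-polynomial string hash on 31-bit integers; stable across platforms,
# used to derive per-gene RNG streams
str_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# combine two 31-bit values into one (order-sensitive)
hash_combine <- function(a, b) {
  as.integer((as.numeric(a) * 69069 + as.numeric(b) + 1) %% 2147483647)
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_rpc <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rpc_error")))
}

rpc_format_error <- function(msg) stop_rpc(msg, "rpc_format_error")
rpc_input_error <- function(msg) stop_rpc(msg, "rpc_input_error")
rpc_registry_error <- function(msg) stop_rpc(msg, "rpc_registry_error")

rpc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rpclustermap")
  if (!nzchar(path)) rpc_input_error(paste0("packaged data file not found: ", file))
  path
}
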