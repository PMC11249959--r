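# Shared pipeline utilities: seed expansion, hashing, logging.

STAGE_OFFSETS <- c(phantom = 1L, cohort = 2L, longitudinal = 3L,
                   dwi = 4L)

# Deterministic per-stage seed derived from the single global seed:
# stage_seed = (global * 10007 + 9973 * offset) mod (2^31 - 1), one fixed
# offset per stage, so stages are reproducible independently of each other.
stage_seed <- function(global_seed, stage) {
  offset <- STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(global_seed) * 10007 + 9973 * offset) %%
               (2^31 - 1))
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

# Canonical JSON used for config hashing: sorted keys, full precision.
config_hash <- function(config) {
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                            null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(level, msg, log_file = NULL) {
  line <- sprintf("[%s] %s", level, msg)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE,
                              sep = "")
  invisible(line)
}

write_json_file <- function(x, path) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  writeLines(js, path)
  invisible(path)
}
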