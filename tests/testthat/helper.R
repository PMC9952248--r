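# Shared test helpers.

# Fresh empty temporary directory with a recognizable prefix.
withr_like_tempdir <- function(prefix) {
  d <- file.path(tempdir(), paste0(prefix, "-", as.integer(stats::runif(1, 1, 1e8))))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# Count trainable parameters of a weight tree, excluding batch-norm running
# buffers (leaves named rm / rv).
count_trainable <- function(tr) {
  if (!is.list(tr)) return(length(tr))
  n <- 0
  for (nm in names(tr)) {
    if (nm %in% c("rm", "rv", "k", "cin", "cout")) next
    n <- n + count_trainable(tr[[nm]])
  }
  n
}
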