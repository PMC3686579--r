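# Shared fixtures, built in code.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute `k` random positions with a different base
mutate_seq <- function(x, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), "")
  paste(ch, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# random IUPAC primer without inosine
rand_primer <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  paste(sample(syms, len, replace = TRUE,
               prob = c(rep(4, 4), rep(2, 6), rep(1, 5))), collapse = "")
}

# small reference panel shared across read-QC / OTU tests
# (plain merge: modifyList would drop NULL-valued overrides like
# verdict_mix = c())
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(seed = 42, n_samples = 4, reads_per_sample = 60)
  do.call(sim_spec, c(args, defaults[!names(defaults) %in% names(args)]))
}
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_panel(small_spec())
    cache
  }
})
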