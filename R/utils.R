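# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL runs `code`
# against the ambient RNG stream.
withSeed <- function(seed, code) {
  if (is.null(seed))
    return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Draw n reproducible sub-seeds (to hand to independent stages) from the
# current RNG stream. Kept below 2^31 so they are valid R integers.
drawSeeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

# treatment state with three levels: "pre" for pretreatment samples, the
# arm ("control"/"antibiotic") for post samples.
treatmentState <- function(timepoint, treatment) {
  factor(ifelse(timepoint == "pre", "pre", as.character(treatment)),
         levels = c("pre", "control", "antibiotic"))
}

# Deterministic TSV writer used for every artifact the pipeline emits.
writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# dist -> labelled square data.frame (first column = id), and back.
distToFrame <- function(d) {
  m <- as.matrix(d)
  data.frame(id = rownames(m), m, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# At very small n the permutation machinery switches to complete
# enumeration and says so; the switch is expected and the p-value exact,
# so the notice is muffled.
muffleSmallPermSet <- function(code) {
  withCallingHandlers(
    code,
    warning = function(w) {
      if (grepl("complete enumeration|minperm", conditionMessage(w)))
        invokeRestart("muffleWarning")
    },
    message = function(m) {
      if (grepl("complete enumeration|minperm", conditionMessage(m)))
        invokeRestart("muffleMessage")
    })
}

stopIfNotDist <- function(d, arg = "dm") {
  if (!inherits(d, "dist"))
    stop("'", arg, "' must be a 'dist' object (see betaDiversity())")
  invisible(TRUE)
}
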