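# internal helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# validate a single DNA string (A/C/G/T/N), return uppercased
.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    .stopf("%s must be a single non-NA character string", what)
  s <- toupper(seq)
  if (!grepl("^[ACGTN]*$", s))
    .stopf("%s contains characters outside the A/C/G/T/N alphabet", what)
  s
}

.check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    .stopf("%s must be numeric in [0, 1]", what)
  x
}

.check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .stopf("%s must be a single integer >= %d", what, min)
  as.integer(x)
}

# reverse complement of a plain character DNA string; wildcards Y (C/T) and
# R (A/G) complement to each other
.revcomp <- function(seq) {
  s <- strsplit(chartr("ACGTNYRacgtnyr", "TGCANRYTGCANRY", seq), "",
                fixed = TRUE)[[1L]]
  paste(rev(s), collapse = "")
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- .check_count(seed, "seed", min = 0L)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# map stage labels to ordinal codes 0, 1, 2, ... in level order
.stage_codes <- function(stages, levels = c("normal", "adenoma", "CRC")) {
  if (is.factor(stages)) return(as.integer(stages) - 1L)
  if (is.numeric(stages)) {
    if (anyNA(stages)) .stopf("stage codes must not contain NA")
    return(as.integer(stages))
  }
  if (is.character(stages)) {
    m <- match(stages, levels)
    if (anyNA(m))
      .stopf("unknown stage label(s): %s",
             paste(unique(stages[is.na(m)]), collapse = ", "))
    return(m - 1L)
  }
  .stopf("stages must be a factor, numeric codes or character labels")
}

.stage_factor <- function(stages, levels = c("normal", "adenoma", "CRC")) {
  if (is.factor(stages)) {
    if (anyNA(stages)) .stopf("stage labels must not contain NA")
    return(droplevels(stages))
  }
  codes <- .stage_codes(stages, levels)
  if (is.character(stages)) return(factor(stages, levels = levels[sort(unique(codes)) + 1L]))
  factor(codes, levels = sort(unique(codes)))
}
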