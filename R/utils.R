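# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps every exported function a pure
# function of (inputs, seed) without clobbering the session RNG.
with_seed_ <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Binary label validation: coerces logicals/factors of two levels to 0/1.
check_binary_labels <- function(y, require_both = TRUE, arg = "y") {
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be binary (0/1) with no missing values", arg),
         call. = FALSE)
  }
  if (require_both && length(unique(y)) < 2) {
    stop(sprintf("`%s` contains a single class; both classes are required", arg),
         call. = FALSE)
  }
  y
}

# Feature matrix validation: data frame or matrix -> numeric matrix.
as_feature_matrix <- function(x, unit_interval = TRUE, arg = "x") {
  if (is.data.frame(x)) {
    id_like <- vapply(x, function(col) is.character(col) || is.factor(col),
                      logical(1))
    x <- x[!id_like]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (unit_interval && (min(x) < 0 || max(x) > 1)) {
    stop(sprintf("`%s` must be scaled to [0, 1]; see normalize_physchem()", arg),
         call. = FALSE)
  }
  x
}

# Stratified fold assignment; every fold receives >= 1 sample of each class.
make_folds <- function(y, k, seed) {
  y <- check_binary_labels(y)
  if (k < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (min(table(y)) < k) {
    stop("stratified folds infeasible: smallest class has fewer samples than folds",
         call. = FALSE)
  }
  with_seed_(seed, {
    fold <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}
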