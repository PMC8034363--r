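# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so generators never leak global state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# order node ids numerically when every id is an integer literal,
# lexicographically otherwise (ids are preserved verbatim from input)
.id_order <- function(ids) {
  if (length(ids) == 0L) return(integer(0))
  if (all(grepl("^-?[0-9]+$", ids))) order(as.numeric(ids), ids) else order(ids)
}

# rank used for ascending-id tie-breaks
.id_rank <- function(ids) {
  ord <- .id_order(ids)
  r <- integer(length(ids))
  r[ord] <- seq_along(ids)
  r
}

.round4 <- function(x) round(x, 4)
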